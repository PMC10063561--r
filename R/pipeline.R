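#' Per-beat features synchronized with reference pressures
#'
#' Runs the beat-level analysis chain on a conditioned waveform: segments
#' beats, extracts the 15-feature descriptor of every usable beat,
#' synchronizes the bioimpedance beat stream with the reference
#' beat-to-beat pressure stream by IBI matching, and returns one row per
#' matched usable beat.
#'
#' @param wave a `pulsatile_waveform`.
#' @param reference data.frame with per-beat `ibi`, `sbp`, `dbp` (the
#'   reference pressure stream, e.g. `$reference` of a simulated trial).
#' @param tolerance IBI-mismatch tolerance for [synchronize_beats()].
#' @return data.frame of matched beats: the 15 features plus `sbp`, `dbp`,
#'   `ibi`; attribute `sync` carries the [synchronize_beats()] result.
#'   Zero rows when the streams cannot be synchronized.
#' @export
match_beats_to_reference <- function(wave, reference, tolerance = 0.10) {
  stopifnot(all(c("ibi", "sbp", "dbp") %in% names(reference)))
  beats <- segment_beats(wave)
  if (nrow(beats) < 10L) stop("too few beats detected for synchronization")
  feats <- beat_features(wave, beats)
  sync <- synchronize_beats(beats$ibi, reference$ibi, tolerance = tolerance)
  if (!sync$synchronized) {
    out <- feats[0, c(bioz_feature_names()), drop = FALSE]
    out$sbp <- numeric(0); out$dbp <- numeric(0); out$ibi <- numeric(0)
    attr(out, "sync") <- sync
    return(out)
  }
  mp <- sync$matched_pairs
  keep <- feats$usable[mp[, "bioz"]]
  mp <- mp[keep, , drop = FALSE]
  out <- feats[mp[, "bioz"], bioz_feature_names(), drop = FALSE]
  out$sbp <- reference$sbp[mp[, "reference"]]
  out$dbp <- reference$dbp[mp[, "reference"]]
  out$ibi <- beats$ibi[mp[, "bioz"]]
  rownames(out) <- NULL
  attr(out, "sync") <- sync
  out
}

#' Simulate one subject's smoothed feature/pressure samples
#'
#' Convenience wrapper producing regression-ready data for one synthetic
#' subject: generates a cold-pressor pressure trajectory, synthesises the
#' pulsatile impedance waveform at the working rate, band-passes it,
#' extracts and synchronizes per-beat features against the (offset)
#' reference stream, and applies the 10-beat / 50%-overlap smoothing.
#'
#' @param protocol a [bp_protocol()].
#' @param seed integer seed (trajectory and sensor noise).
#' @param shape,compliance,sensor generator components.
#' @param noise_sd impedance noise at the working rate (ohm).
#' @param beat_offset injected reference-stream beat offset.
#' @param fs working rate (Hz).
#' @return data.frame of smoothed windows: 15 features plus `sbp`, `dbp`
#'   (see [smooth_windows()]).
#' @export
simulate_subject_samples <- function(protocol = bp_protocol(), seed = 1L,
                                     shape = beat_shape(),
                                     compliance = compliance_model(),
                                     sensor = sensor_model(),
                                     noise_sd = 0, beat_offset = 2L,
                                     fs = 250) {
  beats <- generate_bp_trajectory(protocol, seed)
  sim <- simulate_pulsatile(beats, fs = fs, shape = shape,
                            compliance = compliance, sensor = sensor,
                            seed = seed, beat_offset = beat_offset,
                            noise_sd = noise_sd)
  wave <- bandpass_waveform(sim$wave$delta_z, fs)
  matched <- match_beats_to_reference(wave, sim$reference)
  smooth_windows(matched[, bioz_feature_names(), drop = FALSE],
                 matched[, c("sbp", "dbp")])
}
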