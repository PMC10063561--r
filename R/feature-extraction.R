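#' Detect fiducial points of one bioimpedance beat
#'
#' Locates the four fiducials of the impedance pulse within a beat segment
#' delimited at diastolic peaks: the diastolic peak (segment start, the
#' impedance maximum), the systolic foot (global impedance minimum within
#' the first 60% of the beat), the maximum-slope point (most negative
#' first derivative between peak and foot, i.e. the steepest systolic
#' descent), and the inflection point (first zero crossing of the second
#' derivative after the foot, marking the reflection-wave arrival).
#'
#' Derivatives are taken on a lightly smoothed copy of the segment
#' (centred moving average of odd width `smooth_window`) so single-sample
#' noise does not masquerade as curvature sign changes.
#'
#' @param segment numeric vector: one beat of `delta_z` samples (from
#'   [beat_segment()]), first sample at the diastolic peak.
#' @param sample_rate waveform sampling rate (Hz).
#' @param smooth_window odd integer width of the derivative smoothing
#'   window (samples).
#' @return A list of class `bioz_fiducials`: indices `peak_idx`,
#'   `msp_idx`, `foot_idx`, `ip_idx` (1-based within the segment),
#'   `usable` (logical) and `reason` when unusable. The ordering invariant
#'   `peak < msp < foot < ip` holds on every usable beat.
#' @export
detect_fiducials <- function(segment, sample_rate, smooth_window = 5L) {
  stopifnot(is.numeric(segment), length(segment) >= 8L, sample_rate > 0)
  flag <- function(reason) structure(
    list(peak_idx = 1L, msp_idx = NA_integer_, foot_idx = NA_integer_,
         ip_idx = NA_integer_, usable = FALSE, reason = reason),
    class = "bioz_fiducials")

  n <- length(segment)
  sm <- smooth_ma(segment, smooth_window)
  lim <- max(2L, floor(0.6 * n))
  foot <- which.min(sm[seq_len(lim)])
  if (foot <= 2L || foot >= n - 2L) return(flag("no interior impedance minimum"))
  # the systolic bottom must be the deepest point of the whole beat; a
  # deeper excursion later in the cycle violates the four-phase morphology
  # (e.g. a time-reversed or otherwise malformed beat)
  if (which.min(sm) > lim)
    return(flag("global impedance minimum outside the systolic window"))
  d1 <- c(diff(sm), NA_real_) * sample_rate        # derivative at i -> i+1/2
  msp <- which.min(d1[seq_len(foot - 1L)])
  if (d1[msp] >= 0) return(flag("no descending systolic slope"))
  d2 <- c(diff(d1[-n]), NA_real_, NA_real_) * sample_rate
  ip <- NA_integer_
  for (j in seq(foot, n - 3L)) {
    if (!is.na(d2[j]) && !is.na(d2[j + 1L]) &&
        d2[j] > 0 && d2[j + 1L] <= 0) { ip <- j + 1L; break }
  }
  if (is.na(ip)) return(flag("no inflection after systolic foot"))
  if (!(1L < msp && msp < foot && foot < ip && ip < n))
    return(flag("fiducial ordering violated"))
  structure(list(peak_idx = 1L, msp_idx = msp, foot_idx = foot,
                 ip_idx = ip, usable = TRUE, reason = NULL),
            class = "bioz_fiducials")
}

# centred moving average with odd window; ends padded by replication
smooth_ma <- function(x, w = 5L) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

#' The 15 canonical per-beat bioimpedance features
#' @return Character vector of the 15 feature names in canonical order.
#' @export
bioz_feature_names <- function() {
  c("amp_peak", "amp_foot", "amp_ip",
    "t_stt", "t_peak_msp", "t_msp_foot", "t_peak_ip", "t_foot_ip",
    "t_msp_ip", "t_beat",
    "g_msp", "g_ip",
    "a_peak_foot", "a_foot_nextpeak", "a_total")
}

#' Extract the 15-feature descriptor of one beat
#'
#' Computes the canonical feature set of the bioimpedance pulse: three
#' amplitudes (diastolic peak, systolic foot and inflection point, each as
#' the absolute impedance difference to the maximum-slope point), seven
#' time intervals (slope transit time, peak-to-msp, msp-to-foot,
#' peak-to-ip, foot-to-ip, msp-to-ip, total beat duration), two gradients
#' (the first derivative at the maximum-slope and inflection points) and
#' three areas (peak-to-foot, foot-to-next-peak, total beat), integrated
#' by the trapezoidal rule with the impedance referenced to the systolic
#' foot value so all areas are non-negative. The slope transit time is the
#' beat depth divided by the maximum slope magnitude,
#' `(amp_peak + amp_foot) / |g_msp|`, the usual pulse-wave-velocity proxy.
#'
#' The total pulse amplitude `amp_peak + amp_foot` (the full peak-to-foot
#' excursion) is returned as a non-counted extra under `delta_bioz`.
#'
#' @param segment one beat of `delta_z` samples.
#' @param fiducials a usable [detect_fiducials()] result for `segment`.
#' @param sample_rate waveform sampling rate (Hz).
#' @return Named numeric vector: the 15 features of
#'   [bioz_feature_names()] followed by the extra `delta_bioz`, with
#'   attribute `usable`.
#' @export
extract_features <- function(segment, fiducials, sample_rate) {
  stopifnot(inherits(fiducials, "bioz_fiducials"))
  if (!isTRUE(fiducials$usable)) stop("fiducials are not usable for this beat")
  n <- length(segment)
  dt <- 1 / sample_rate
  pk <- fiducials$peak_idx; ms <- fiducials$msp_idx
  ft <- fiducials$foot_idx; ip <- fiducials$ip_idx

  sm <- smooth_ma(segment, 5L)
  d1 <- c(diff(sm), NA_real_) * sample_rate
  g_msp <- d1[ms]
  g_ip <- d1[ip]
  if (abs(g_msp) < .Machine$double.eps^0.5)
    stop("maximum slope is numerically zero; slope transit time undefined")

  amp_peak <- abs(segment[pk] - segment[ms])
  amp_foot <- abs(segment[ft] - segment[ms])
  amp_ip <- abs(segment[ip] - segment[ms])

  trap <- function(y) if (length(y) < 2L) 0 else
    sum((y[-1L] + y[-length(y)]) / 2) * dt
  base <- segment[ft]
  a_peak_foot <- trap(segment[pk:ft] - base)
  a_foot_nextpeak <- trap(segment[ft:n] - base)
  a_total <- trap(segment - base)

  out <- c(amp_peak = amp_peak, amp_foot = amp_foot, amp_ip = amp_ip,
           t_stt = (amp_peak + amp_foot) / abs(g_msp),
           t_peak_msp = (ms - pk) * dt,
           t_msp_foot = (ft - ms) * dt,
           t_peak_ip = (ip - pk) * dt,
           t_foot_ip = (ip - ft) * dt,
           t_msp_ip = (ip - ms) * dt,
           t_beat = n * dt,
           g_msp = g_msp, g_ip = g_ip,
           a_peak_foot = a_peak_foot,
           a_foot_nextpeak = a_foot_nextpeak,
           a_total = a_total,
           delta_bioz = amp_peak + amp_foot)
  attr(out, "usable") <- TRUE
  out
}

#' Feature table for every usable beat of a trial
#'
#' Runs [detect_fiducials()] and [extract_features()] over all beats of a
#' segmented waveform.
#'
#' @param wave a `pulsatile_waveform`.
#' @param beats a `beat_table` from [segment_beats()].
#' @param smooth_window passed to [detect_fiducials()].
#' @return data.frame with `beat`, `usable`, the 15 features and
#'   `delta_bioz`; unusable beats carry `NA` features.
#' @export
beat_features <- function(wave, beats, smooth_window = 5L) {
  fs <- wave$sample_rate
  nm <- c(bioz_feature_names(), "delta_bioz")
  out <- as.data.frame(matrix(NA_real_, nrow(beats), length(nm),
                              dimnames = list(NULL, nm)))
  usable <- logical(nrow(beats))
  for (i in seq_len(nrow(beats))) {
    seg <- beat_segment(wave, beats, i)
    fid <- detect_fiducials(seg, fs, smooth_window)
    if (!fid$usable) next
    fv <- tryCatch(extract_features(seg, fid, fs), error = function(e) NULL)
    if (is.null(fv)) next
    out[i, ] <- fv[nm]
    usable[i] <- TRUE
  }
  cbind(data.frame(beat = beats$beat, usable = usable), out)
}

#' 10-beat moving-average smoothing with 50% overlap
#'
#' Reduces measurement noise and inter-beat variability by averaging both
#' the feature set and the reference pressures over windows of
#' `window_beats` consecutive synchronized beats, advancing by half a
#' window (50% overlap): window w covers beats
#' `[(w-1)*step + 1, (w-1)*step + window_beats]`.
#'
#' @param features data.frame of per-beat features (one row per beat,
#'   numeric columns).
#' @param bp data.frame with per-beat `sbp` and `dbp` (mmHg), same row
#'   count as `features`.
#' @param window_beats beats per window.
#' @param overlap fractional window overlap; 0.5 advances by half a window.
#' @return data.frame: `window`, mean of every feature column, `sbp`,
#'   `dbp`. Zero rows (with a warning) when fewer than `window_beats`
#'   beats are supplied.
#' @export
smooth_windows <- function(features, bp, window_beats = 10L, overlap = 0.5) {
  stopifnot(is.data.frame(features), is.data.frame(bp),
            nrow(features) == nrow(bp),
            all(c("sbp", "dbp") %in% names(bp)))
  step <- max(1L, as.integer(round(window_beats * (1 - overlap))))
  n <- nrow(features)
  if (n < window_beats) {
    warning("fewer beats than one window; returning empty result")
    out <- cbind(data.frame(window = integer(0)),
                 features[0, , drop = FALSE],
                 data.frame(sbp = numeric(0), dbp = numeric(0)))
    return(out)
  }
  starts <- seq(1L, n - window_beats + 1L, by = step)
  rows <- lapply(seq_along(starts), function(w) {
    idx <- starts[w]:(starts[w] + window_beats - 1L)
    cbind(data.frame(window = w),
          as.data.frame(t(colMeans(features[idx, , drop = FALSE]))),
          data.frame(sbp = mean(bp$sbp[idx]), dbp = mean(bp$dbp[idx])))
  })
  do.call(rbind, rows)
}
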