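#' I-Q demodulation of a carrier-modulated bioimpedance record
#'
#' Lock-in style quadrature demodulation: the raw voltage is mixed with
#' in-phase and quadrature copies of the carrier, each product is low-pass
#' filtered, and the amplitude envelope is recovered as
#' `2 * sqrt(I^2 + Q^2)` — invariant to any carrier phase offset. The
#' envelope is decimated to a working rate suited to the 0.05-6 Hz
#' pulsatile band.
#'
#' The low-pass/decimation chain is applied in stages (factor at most 25
#' per stage, 4th-order zero-phase Butterworth anti-alias per stage, final
#' stage at `lp_cutoff`) so each digital filter keeps a well-conditioned
#' normalised cutoff.
#'
#' @param record a `raw_bioz_record` (see [modulate()]), or a list with
#'   `samples`, `sample_rate` and `carrier_freq`.
#' @param lp_cutoff demodulation low-pass cutoff (Hz); must be below the
#'   carrier frequency.
#' @param decimation integer overall decimation factor; the output rate is
#'   `sample_rate / decimation`.
#'
#' @return A list with `magnitude` (ohm-proportional envelope),
#'   `sample_rate` (post-decimation, Hz) and `time` (s).
#' @export
iq_demodulate <- function(record, lp_cutoff = 20, decimation = 375L) {
  stopifnot(is.list(record), !is.null(record$samples),
            record$sample_rate > 0, record$carrier_freq > 0)
  if (lp_cutoff >= record$carrier_freq)
    stop("lp_cutoff must be below the carrier frequency")
  decimation <- as.integer(decimation)
  stopifnot(decimation >= 1L)
  fs <- record$sample_rate
  fs_out <- fs / decimation
  if (fs_out < 4 * lp_cutoff)
    stop("decimated rate must be at least four times the low-pass cutoff")

  n <- length(record$samples)
  t <- record$start_time + (seq_len(n) - 1L) / fs
  ph <- 2 * pi * record$carrier_freq * t
  I <- record$samples * cos(ph)
  Q <- record$samples * sin(ph)

  # split the overall decimation into stages of at most 25
  stages <- integer(0)
  d <- decimation
  while (d > 25L) {
    divs <- which(d %% 2:25 == 0L) + 1L
    if (!length(divs))
      stop("decimation factor must be a product of integers <= 25")
    f <- max(divs)
    stages <- c(stages, f)
    d <- d %/% f
  }
  stages <- c(stages, d)

  decim_lp <- function(x, fs_in, factors) {
    for (k in seq_along(factors)) {
      f <- factors[k]
      fs_next <- fs_in / f
      cutoff <- if (k == length(factors)) lp_cutoff else 0.4 * fs_next
      bw <- signal::butter(4, cutoff / (fs_in / 2), type = "low")
      x <- signal::filtfilt(bw, x)
      if (f > 1L) x <- x[seq(1L, length(x), by = f)]
      fs_in <- fs_next
    }
    x
  }
  Id <- decim_lp(I, fs, stages)
  Qd <- decim_lp(Q, fs, stages)
  mag <- 2 * sqrt(Id^2 + Qd^2)
  # the low-pass startup/shutdown transient spans a few time constants of
  # the final stage; clamp those edge samples to the first/last settled
  # value so downstream (reflection-padded) filtering never sees them
  m <- min(length(mag) %/% 3L, ceiling(6 * fs_out / lp_cutoff))
  if (m >= 1L && length(mag) > 2L * m) {
    mag[seq_len(m)] <- mag[m + 1L]
    mag[(length(mag) - m + 1L):length(mag)] <- mag[length(mag) - m]
  }
  list(magnitude = mag, sample_rate = fs_out,
       time = record$start_time + (seq_along(mag) - 1L) / fs_out)
}

#' Band-pass conditioning of the demodulated envelope
#'
#' Applies a 2nd-order Butterworth band-pass (default 0.05-6 Hz, the
#' pulsatile blood-flow band) with zero-phase forward-backward filtering so
#' fiducial timings are not skewed. DC and sub-band drift are suppressed.
#'
#' @param x numeric series (ohm-proportional envelope), or the list
#'   returned by [iq_demodulate()].
#' @param sample_rate sampling rate of `x` (Hz); taken from `x` when it is
#'   an [iq_demodulate()] result.
#' @param low,high band edges (Hz), `0 < low < high < sample_rate/2`.
#' @param order filter order of the analog band-pass prototype.
#' @param settle_seconds length of the leading/trailing regions flagged as
#'   filter settling; stored on the result for downstream exclusion.
#'
#' @return An object of class `pulsatile_waveform`: list with `delta_z`,
#'   `sample_rate`, `band`, `settle_samples`.
#' @export
bandpass_waveform <- function(x, sample_rate = NULL, low = 0.05, high = 6,
                              order = 2, settle_seconds = 10) {
  if (is.list(x)) {
    if (is.null(sample_rate)) sample_rate <- x$sample_rate
    x <- x$magnitude
  }
  stopifnot(is.numeric(x), is.numeric(sample_rate), sample_rate > 0)
  if (!(low > 0 && low < high && high < sample_rate / 2))
    stop("band edges must satisfy 0 < low < high < sample_rate/2")
  bw <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  # remove the static level first: the band-pass kills DC anyway, but a
  # smaller input step keeps the forward-backward edge transient small;
  # odd-reflection padding absorbs the remaining transient of the slow
  # high-pass pole (time constant ~ 1/(2 pi low))
  y <- filtfilt_padded(bw, x - mean(x), pad = ceiling(2 * sample_rate / low))
  structure(list(delta_z = y, sample_rate = sample_rate,
                 band = c(low, high),
                 settle_samples = round(settle_seconds * sample_rate)),
            class = "pulsatile_waveform")
}

#' @export
print.pulsatile_waveform <- function(x, ...) {
  cat(sprintf("Pulsatile bioimpedance waveform: %d samples @ %g Hz",
              length(x$delta_z), x$sample_rate))
  if (!is.null(x$band))
    cat(sprintf(", band %g-%g Hz", x$band[1], x$band[2]))
  cat("\n")
  invisible(x)
}

#' Full conditioning chain: demodulate then band-pass
#'
#' @inheritParams iq_demodulate
#' @inheritParams bandpass_waveform
#' @return A `pulsatile_waveform` (see [bandpass_waveform()]).
#' @export
condition_record <- function(record, lp_cutoff = 20, decimation = 375L,
                             low = 0.05, high = 6, order = 2) {
  dem <- iq_demodulate(record, lp_cutoff = lp_cutoff, decimation = decimation)
  bandpass_waveform(dem, low = low, high = high, order = order)
}

# zero-phase filtering with odd-reflection end padding, the standard remedy
# for forward-backward transients when a pole sits close to DC
filtfilt_padded <- function(bw, x, pad) {
  n <- length(x)
  pad <- max(1L, min(n - 1L, as.integer(pad)))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  signal::filtfilt(bw, xp)[(pad + 1L):(pad + n)]
}
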