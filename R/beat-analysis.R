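#' Segment a pulsatile waveform into beats at diastolic peaks
#'
#' Beats are delimited at successive diastolic impedance peaks (local
#' maxima of the band-passed waveform): impedance is highest just before
#' the systolic inflow of blood. The dominant period is first estimated
#' from the autocorrelation of the waveform; local maxima closer together
#' than 0.4 of that period are suppressed. Leading/trailing partial beats
#' and any filter settle region are discarded.
#'
#' @param wave a `pulsatile_waveform` (see [bandpass_waveform()]).
#' @param min_period_frac minimum peak separation as a fraction of the
#'   estimated dominant period.
#' @param ac_threshold minimum autocorrelation at the dominant lag for the
#'   record to count as periodic; below it a zero-row beat table is
#'   returned rather than an error.
#'
#' @return A data.frame of class `beat_table` with columns `beat`, `start`,
#'   `end` (sample indices, half-open `[start, end)`), `time` (beat onset,
#'   s), `ibi` (s). Attribute `sample_rate` carries the waveform rate.
#' @export
segment_beats <- function(wave, min_period_frac = 0.4, ac_threshold = 0.2) {
  stopifnot(inherits(wave, "pulsatile_waveform") ||
              (is.list(wave) && !is.null(wave$delta_z)))
  x <- wave$delta_z
  fs <- wave$sample_rate
  if (length(x) < 5 * fs) stop("waveform must be at least 5 s long")
  settle <- wave$settle_samples
  if (is.null(settle)) settle <- 0L
  lo <- max(1L, settle + 1L)
  hi <- min(length(x), length(x) - settle)
  empty <- function() {
    out <- data.frame(beat = integer(0), start = integer(0),
                      end = integer(0), time = numeric(0), ibi = numeric(0))
    attr(out, "sample_rate") <- fs
    class(out) <- c("beat_table", "data.frame")
    out
  }
  if (hi - lo < 4 * fs) return(empty())
  xs <- x[lo:hi]
  if (stats::sd(xs) == 0) return(empty())

  # dominant period from autocorrelation in the 0.27-2 s lag range
  max_lag <- min(length(xs) - 1L, round(2 * fs))
  ac <- stats::acf(xs, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lag_min <- max(2L, round(0.27 * fs))
  if (lag_min >= max_lag) return(empty())
  cand <- lag_min:max_lag
  # first prominent local maximum of the autocorrelation
  acc <- ac[cand + 1L]
  locmax <- which(diff(sign(diff(acc))) < 0) + 1L
  locmax <- locmax[acc[locmax] >= ac_threshold]
  if (!length(locmax)) return(empty())
  period <- cand[locmax[1L]]

  min_sep <- max(1L, round(min_period_frac * period))
  # detrend with a one-period running mean so residual drift and filter
  # transients cannot bias the peak threshold
  xd <- xs - smooth_ma(xs, period + (period + 1L) %% 2L)
  # local maxima with minimum separation, greedy by amplitude
  is_peak <- c(FALSE, xd[2:(length(xd) - 1)] > xd[1:(length(xd) - 2)] &
                 xd[2:(length(xd) - 1)] >= xd[3:length(xd)], FALSE)
  pk <- which(is_peak)
  if (length(pk) < 2L) return(empty())
  # diastolic peaks sit atop the detrended cycle; secondary (reflection)
  # bumps fall below the detrended zero line
  thr <- 0.3 * stats::quantile(xd[pk], 0.9, names = FALSE)
  pk <- pk[xd[pk] > max(thr, 0)]
  if (length(pk) < 2L) return(empty())
  xs <- xd
  ord <- order(xs[pk], decreasing = TRUE)
  keep <- logical(length(pk))
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(pk[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, pk[i])
    }
  }
  pk <- sort(pk[keep])
  if (length(pk) < 2L) return(empty())
  # refine on the undetrended waveform: the detrending running mean can
  # tilt the cycle by a sample or two
  xs0 <- x[lo:hi]
  r <- max(1L, round(0.06 * period))
  pk <- vapply(pk, function(p) {
    a <- max(1L, p - r); b <- min(length(xs0), p + r)
    as.integer(a + which.max(xs0[a:b]) - 1L)
  }, integer(1))
  pk <- unique(pk)
  if (length(pk) < 2L) return(empty())

  start <- pk[-length(pk)] + lo - 1L
  end <- pk[-1L] + lo - 1L
  out <- data.frame(beat = seq_along(start), start = start, end = end,
                    time = (start - 1L) / fs, ibi = (end - start) / fs)
  attr(out, "sample_rate") <- fs
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Extract the raw sample segment of one beat
#'
#' @param wave a `pulsatile_waveform`.
#' @param beats a `beat_table` from [segment_beats()].
#' @param i beat index.
#' @return Numeric vector of `delta_z` samples for beat `i`, half-open.
#' @export
beat_segment <- function(wave, beats, i) {
  wave$delta_z[beats$start[i]:(beats$end[i] - 1L)]
}

#' Time- and amplitude-normalize one beat
#'
#' Resamples a beat segment to a fixed length (time normalization by the
#' beat's own inter-beat interval), subtracts the first sample so the
#' diastolic impedance peak sits at the origin, and divides by the
#' peak-to-foot depth so the systolic bottom sits at -1.
#'
#' @param segment numeric vector of one beat's samples (>= 8 samples).
#' @param L output length.
#' @param amplitude if `FALSE`, only time normalization and origin shift
#'   are applied (no depth scaling).
#' @return Numeric vector of length `L` with `out[1] == 0` and (when
#'   `amplitude = TRUE`) `min(out) == -1`.
#' @export
normalize_beat <- function(segment, L = 100L, amplitude = TRUE) {
  stopifnot(is.numeric(segment))
  if (length(segment) < 8L) stop("beat must have at least 8 samples")
  u <- seq(0, 1, length.out = length(segment))
  v <- stats::approx(u, segment, xout = seq(0, 1, length.out = L))$y
  v <- v - v[1L]
  if (amplitude) {
    depth <- -min(v)
    if (depth <= 0) stop("flat beat: peak-to-foot depth is zero")
    v <- v / depth
  }
  v
}

#' Ensemble morphology-consistency statistics for a trial
#'
#' Normalizes every beat, forms the ensemble mean waveform, and computes
#' the three quality metrics used to rank electrode configurations: the
#' positionwise across-beat standard deviation averaged over the cycle
#' (SD, lower is better), the spectral signal-to-noise ratio of the trial
#' (SNR, higher is better), and the mean dynamic-time-warping distance of
#' each beat to the ensemble mean (DTW, lower is better).
#'
#' @param wave a `pulsatile_waveform`.
#' @param beats a `beat_table`; when missing, [segment_beats()] is run.
#' @param L normalized beat length.
#' @param amplitude passed to [normalize_beat()]; the SD metric may be
#'   computed on amplitude-normalized (default) or only time-normalized
#'   beats.
#' @return A list of class `ensemble_stats`: `mean_waveform`, `sd`,
#'   `snr_db`, `dtw`, `per_beat_dtw`, `n_beats`.
#' @export
ensemble_stats <- function(wave, beats = NULL, L = 100L, amplitude = TRUE) {
  if (is.null(beats)) beats <- segment_beats(wave)
  if (nrow(beats) < 2L) stop("need at least 2 beats for ensemble statistics")
  mat <- matrix(NA_real_, nrow(beats), L)
  ok <- logical(nrow(beats))
  for (i in seq_len(nrow(beats))) {
    seg <- beat_segment(wave, beats, i)
    v <- tryCatch(normalize_beat(seg, L, amplitude), error = function(e) NULL)
    if (!is.null(v)) { mat[i, ] <- v; ok[i] <- TRUE }
  }
  if (sum(ok) < 2L) stop("fewer than 2 usable beats")
  mat <- mat[ok, , drop = FALSE]
  mw <- colMeans(mat)
  sdv <- mean(apply(mat, 2, stats::sd))
  dtws <- apply(mat, 1, function(b) dtw_distance(b, mw))
  snr <- tryCatch(snr_metric(wave), error = function(e) NA_real_)
  structure(list(mean_waveform = mw, sd = sdv, snr_db = snr,
                 dtw = mean(dtws), per_beat_dtw = dtws,
                 n_beats = sum(ok)),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("Ensemble of %d beats: SD = %.4f, SNR = %.1f dB, DTW = %.3f\n",
              x$n_beats, x$sd, x$snr_db, x$dtw))
  invisible(x)
}

#' Positionwise ensemble standard deviation
#'
#' For a matrix of normalized beats (rows), computes the sample standard
#' deviation across beats at each of the L cycle positions and averages
#' over positions.
#'
#' @param mat numeric matrix, one normalized beat per row.
#' @return Scalar SD metric (dimensionless).
#' @export
sd_metric <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("SD metric needs at least 2 beats")
  mean(apply(mat, 2, stats::sd))
}

#' Spectral signal-to-noise ratio of a trial
#'
#' Takes the periodogram of the full trial, locates the fundamental
#' heart-rate peak as the largest spectral peak in the 0.5-3 Hz band, and
#' reports `10 log10` of the summed power within `half_bw` of the
#' fundamental over the median per-bin power elsewhere in the 0.05-6 Hz
#' analysis band.
#'
#' @param wave a `pulsatile_waveform` (or list with `delta_z`,
#'   `sample_rate`).
#' @param search_band frequency band (Hz) searched for the fundamental.
#' @param half_bw half-width (Hz) of the signal band around the fundamental.
#' @param noise_band band (Hz) over which the median noise floor is taken.
#' @return A scalar SNR in dB, with attribute `fundamental_hz`.
#' @export
snr_metric <- function(wave, search_band = c(0.5, 3), half_bw = 0.05,
                       noise_band = c(0.05, 6)) {
  x <- wave$delta_z
  fs <- wave$sample_rate
  if (length(x) < 10 * fs) stop("trial must be at least 10 s long")
  x <- x - mean(x)
  n <- length(x)
  spec <- abs(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  spec <- spec[half]; f <- f[half]
  in_search <- f >= search_band[1] & f <= search_band[2]
  if (!any(in_search) || all(spec[in_search] == 0))
    stop("no spectral peak in the heart-rate band")
  f0 <- f[in_search][which.max(spec[in_search])]
  sig <- f >= f0 - half_bw & f <= f0 + half_bw
  noise <- f >= noise_band[1] & f <= noise_band[2] & !sig
  if (!any(noise)) stop("noise band empty")
  p_sig <- sum(spec[sig])
  p_noise <- stats::median(spec[noise])
  if (p_noise <= 0) p_noise <- .Machine$double.xmin
  out <- 10 * log10(p_sig / p_noise)
  attr(out, "fundamental_hz") <- f0
  out
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with absolute-difference local cost,
#' symmetric step set \{(1,0), (0,1), (1,1)\}, full alignment of both ends
#' and no warping window. Satisfies `dtw_distance(a, a) == 0`, symmetry,
#' and non-negativity.
#'
#' @param a,b numeric vectors (non-empty).
#' @return Non-negative scalar alignment cost.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
dtw_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("dtw inputs must be non-empty")
  # column-sweep DP; cost[i,j] = |a_i-b_j| + min(left, down, diag)
  prev <- cumsum(abs(a - b[1L]))           # column j = 1
  for (j in seq_len(m - 1L) + 1L) {
    cur <- numeric(n)
    cost1 <- abs(a[1L] - b[j])
    cur[1L] <- cost1 + prev[1L]
    for (i in seq_len(n - 1L) + 1L) {
      cur[i] <- abs(a[i] - b[j]) + min(prev[i], prev[i - 1L], cur[i - 1L])
    }
    prev <- cur
  }
  prev[n]
}

#' Synchronize bioimpedance and reference beat streams by IBI matching
#'
#' Finds the integer beat lag that maximizes the normalized
#' cross-correlation (Pearson) between the two inter-beat-interval series,
#' then pairs beats at that lag, dropping pairs whose relative IBI mismatch
#' exceeds `tolerance`. Reference pressure streams are typically offset by
#' a few beats from the bioimpedance stream because the two instruments
#' start independently.
#'
#' @param bioz_ibis numeric vector of bioimpedance inter-beat intervals (s).
#' @param reference_ibis numeric vector of reference-stream IBIs (s).
#' @param tolerance maximum relative IBI mismatch within a pair.
#' @param max_lag largest absolute lag searched (beats).
#' @param min_score minimum correlation for the result to count as
#'   synchronized.
#'
#' @return A list of class `sync_result`: `beat_lag` (reference index i
#'   matches bioz index `i + beat_lag`), `matched_pairs` (two-column matrix
#'   `bioz`, `reference`), `match_score`, `synchronized` (logical).
#' @export
synchronize_beats <- function(bioz_ibis, reference_ibis, tolerance = 0.10,
                              max_lag = 20L, min_score = 0.5) {
  stopifnot(length(bioz_ibis) >= 10L, length(reference_ibis) >= 10L)
  best_lag <- NA_integer_; best_r <- -Inf
  for (lag in -max_lag:max_lag) {
    # reference i aligns with bioz i + lag
    i_ref <- seq_along(reference_ibis)
    i_bio <- i_ref + lag
    ok <- i_bio >= 1L & i_bio <= length(bioz_ibis)
    if (sum(ok) < 8L) next
    r <- suppressWarnings(stats::cor(reference_ibis[ok], bioz_ibis[i_bio[ok]]))
    if (is.na(r)) next
    if (r > best_r) { best_r <- r; best_lag <- lag }
  }
  if (!is.finite(best_r) || best_r < min_score) {
    return(structure(list(beat_lag = NA_integer_,
                          matched_pairs = cbind(bioz = integer(0),
                                                reference = integer(0)),
                          match_score = if (is.finite(best_r)) best_r else NA_real_,
                          synchronized = FALSE),
                     class = "sync_result"))
  }
  i_ref <- seq_along(reference_ibis)
  i_bio <- i_ref + best_lag
  ok <- i_bio >= 1L & i_bio <= length(bioz_ibis)
  i_ref <- i_ref[ok]; i_bio <- i_bio[ok]
  rel <- abs(bioz_ibis[i_bio] - reference_ibis[i_ref]) /
    pmax(reference_ibis[i_ref], .Machine$double.eps)
  keep <- rel <= tolerance
  structure(list(beat_lag = best_lag,
                 matched_pairs = cbind(bioz = i_bio[keep],
                                       reference = i_ref[keep]),
                 match_score = best_r,
                 synchronized = TRUE),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  if (!x$synchronized) {
    cat("Beat streams could not be synchronized (best IBI correlation",
        sprintf("%.2f)\n", x$match_score))
  } else {
    cat(sprintf("Synchronized at lag %d beats, %d pairs, IBI correlation %.3f\n",
                x$beat_lag, nrow(x$matched_pairs), x$match_score))
  }
  invisible(x)
}
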