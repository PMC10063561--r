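test_that("segmentation finds no beats in aperiodic signals", {
  w <- structure(list(delta_z = rep(0.5, 2500), sample_rate = 250,
                      band = NULL, settle_samples = 0L),
                 class = "pulsatile_waveform")
  expect_equal(nrow(segment_beats(w)), 0L)
  set.seed(1)
  w$delta_z <- rnorm(2500)   # white noise: no autocorrelation peak
  expect_equal(nrow(segment_beats(w)), 0L)
})

test_that("segmentation recovers clean beats and their IBIs", {
  tr <- clean_trial(seed = 2, duration = 50, jitter = 0.03)
  bt <- segment_beats(tr$wave)
  truth <- tr$truth$beats
  fs <- tr$wave$sample_rate
  # interior truth beats (outside the settle regions)
  lo_t <- tr$wave$settle_samples / fs
  hi_t <- length(tr$wave$delta_z) / fs - lo_t
  interior <- which(truth$t_peak > lo_t + 0.3 &
                      truth$time + truth$ibi < hi_t)
  m <- vapply(bt$time, function(t) which.min(abs(truth$t_peak - t)), 1L)
  expect_gte(mean(interior %in% m), 0.95)
  # detected IBI vs interval between true (band-referenced) peaks
  ib_true <- truth$t_peak[m + 1L] - truth$t_peak[m]
  expect_lt(max(abs(bt$ibi - ib_true), na.rm = TRUE), 0.010)
  # 60 bpm, ~30 s analysed span: expected beat count
  expect_gt(nrow(bt), 25)
})

test_that("beat normalization pins the origin and unit depth", {
  seg <- 1 - sin(seq(0, pi, length.out = 60))^2 * 2
  v <- normalize_beat(seg, L = 100)
  expect_equal(v[1], 0)
  expect_equal(min(v), -1)
  # invariance to IBI (length) and amplitude scale
  seg2 <- 5 * (1 - sin(seq(0, pi, length.out = 93))^2 * 2)
  v2 <- normalize_beat(seg2, L = 100)
  expect_equal(v, v2, tolerance = 1e-3)
  expect_error(normalize_beat(rep(1, 50)), "flat")
  expect_error(normalize_beat(c(1, 2, 3)), "8 samples")
})

test_that("SD metric matches its two-beat closed form and ranks noise", {
  base <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(sd_metric(rbind(base, base)), 0)
  # two beats differing by +c everywhere: sample SD = c/sqrt(2)
  cshift <- 0.3
  expect_equal(sd_metric(rbind(base, base + cshift)), cshift / sqrt(2))
  # SD grows monotonically with iid noise level
  set.seed(7)
  sds <- vapply(c(0.01, 0.05, 0.2), function(s) {
    mat <- t(replicate(30, base + rnorm(100, 0, s)))
    sd_metric(mat)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("spectral SNR matches the analytic periodogram value", {
  fs <- 250; dur <- 30
  t <- (seq_len(dur * fs) - 1) / fs
  x <- sin(2 * pi * 1 * t)
  w <- list(delta_z = x, sample_rate = fs)
  expect_gt(as.numeric(snr_metric(w)), 40)
  # sinusoid + white noise: SNR ~ 10log10((n A^2/4)/(sigma^2 ln 2))
  set.seed(3)
  A <- 1; sigma <- 0.5; n <- length(t)
  xn <- A * sin(2 * pi * 1 * t) + rnorm(n, 0, sigma)
  got <- as.numeric(snr_metric(list(delta_z = xn, sample_rate = fs)))
  expected <- 10 * log10((n * A^2 / 4) / (sigma^2 * log(2)))
  expect_equal(got, expected, tolerance = 1)
  # doubling the noise sigma costs ~6 dB
  x2 <- A * sin(2 * pi * 1 * t) + rnorm(n, 0, 2 * sigma)
  got2 <- as.numeric(snr_metric(list(delta_z = x2, sample_rate = fs)))
  expect_equal(got - got2, 6.02, tolerance = 1.5)
})

test_that("DTW equals the exhaustive-path oracle", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  set.seed(11)
  for (k in 1:40) {
    a <- round(runif(sample(1:12, 1), 0, 5), 1)
    b <- round(runif(sample(1:12, 1), 0, 5), 1)
    expect_equal(dtw_distance(a, b), dtw_oracle_dijkstra(a, b))
    # symmetry and non-negativity
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
  # explicit enumeration double-check on tiny series
  for (k in 1:10) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    expect_equal(dtw_distance(a, b), dtw_oracle_enumerate(a, b))
  }
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
})

test_that("IBI synchronization recovers injected beat lags", {
  set.seed(5)
  ibis <- 1 + rnorm(60, 0, 0.05)
  s0 <- synchronize_beats(ibis, ibis)
  expect_equal(s0$beat_lag, 0L)
  expect_equal(s0$match_score, 1.0)
  # reference delayed by k beats
  for (k in c(2L, 5L)) {
    sk <- synchronize_beats(ibis, ibis[-seq_len(k)])
    expect_equal(sk$beat_lag, k)
  }
  # 5% dropout: >= 90% of remaining beats paired at the right positions
  ref <- ibis[-seq_len(2L)]
  keep <- runif(length(ref)) >= 0.05
  # dropout breaks index alignment downstream of the first gap, so pair
  # quality is judged by the IBI agreement of accepted pairs
  sd5 <- synchronize_beats(ibis, ref[keep])
  expect_true(sd5$synchronized)
  mp <- sd5$matched_pairs
  agree <- abs(ibis[mp[, "bioz"]] - ref[keep][mp[, "reference"]]) /
    ref[keep][mp[, "reference"]]
  expect_gte(mean(agree <= 0.10), 0.9)
  # unsynchronizable: independent IBI series long enough that no lag can
  # reach the correlation threshold by chance
  su <- synchronize_beats(1 + rnorm(120, 0, 0.08), 1 + rnorm(120, 0, 0.08))
  expect_false(su$synchronized)
})

test_that("quality metrics rank a clean trial above its noisy copy", {
  tr <- clean_trial(seed = 4, duration = 45)
  es_clean <- ensemble_stats(tr$wave)
  noisy <- tr$wave
  set.seed(9)
  noisy$delta_z <- noisy$delta_z + rnorm(length(noisy$delta_z),
                                         0, 0.4 * sd(noisy$delta_z))
  es_noisy <- ensemble_stats(noisy)
  expect_lt(es_clean$sd, es_noisy$sd)
  expect_gt(es_clean$snr_db, es_noisy$snr_db)
  expect_lt(es_clean$dtw, es_noisy$dtw)
})

test_that("segmentation and normalization are amplitude-scale invariant", {
  tr <- clean_trial(seed = 6, duration = 40)
  w2 <- tr$wave
  w2$delta_z <- 4 * w2$delta_z
  b1 <- segment_beats(tr$wave)
  b2 <- segment_beats(w2)
  expect_equal(b1$start, b2$start)
  v1 <- normalize_beat(beat_segment(tr$wave, b1, 3), 100)
  v2 <- normalize_beat(beat_segment(w2, b2, 3), 100)
  expect_equal(v1, v2, tolerance = 1e-9)
})
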