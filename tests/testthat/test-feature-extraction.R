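test_that("fiducials are recovered on clean conditioned beats", {
  tr <- clean_trial(seed = 3, duration = 50)
  bt <- segment_beats(tr$wave)
  truth <- tr$truth$beats
  fs <- tr$wave$sample_rate
  m <- vapply(bt$time, function(t) which.min(abs(truth$t_peak - t)), 1L)
  for (i in seq_len(nrow(bt))) {
    seg <- beat_segment(tr$wave, bt, i)
    fid <- detect_fiducials(seg, fs)
    expect_true(fid$usable)
    tb <- truth[m[i], ]
    t0 <- bt$time[i]
    expect_lte(abs(t0 - tb$t_peak) * fs, 1)
    expect_lte(abs(t0 + (fid$msp_idx - 0.5) / fs - tb$t_msp) * fs, 1)
    expect_lte(abs(t0 + (fid$foot_idx - 1) / fs - tb$t_foot) * fs, 1)
    expect_lte(abs(t0 + (fid$ip_idx - 1) / fs - tb$t_ip) * fs, 1)
    # ordering invariant
    expect_true(fid$peak_idx < fid$msp_idx && fid$msp_idx < fid$foot_idx &&
                  fid$foot_idx < fid$ip_idx)
  }
})

test_that("degenerate beats are flagged, scaling leaves indices unchanged", {
  tr <- clean_trial(seed = 3, duration = 40)
  bt <- segment_beats(tr$wave)
  seg <- beat_segment(tr$wave, bt, 2)
  fs <- tr$wave$sample_rate
  fid <- detect_fiducials(seg, fs)
  # time-reversed beat violates the morphology contract
  fr <- detect_fiducials(rev(seg), fs)
  expect_false(fr$usable)
  # monotone segment has no interior minimum
  fm <- detect_fiducials(seq(1, 0, length.out = 100), fs)
  expect_false(fm$usable)
  # amplitude scaling: identical fiducial indices
  f2 <- detect_fiducials(2.5 * seg, fs)
  expect_equal(fid[c("msp_idx", "foot_idx", "ip_idx")],
               f2[c("msp_idx", "foot_idx", "ip_idx")])
})

test_that("the feature vector has exactly 15 features, 7 of them times", {
  nm <- bioz_feature_names()
  expect_length(nm, 15L)
  expect_length(grep("^t_", nm), 7L)
  tr <- clean_trial(seed = 5, duration = 40)
  bt <- segment_beats(tr$wave)
  fs <- tr$wave$sample_rate
  seg <- beat_segment(tr$wave, bt, 3)
  fv <- extract_features(seg, detect_fiducials(seg, fs), fs)
  expect_setequal(setdiff(names(fv), "delta_bioz"), nm)
  expect_true(all(is.finite(fv)))
  expect_true(all(fv[grep("^t_", nm, value = TRUE)] > 0))
  expect_equal(unname(fv["t_beat"]), length(seg) / fs)
  expect_lte(fv["t_peak_msp"] + fv["t_msp_foot"], fv["t_beat"])
})

test_that("triangle beat features match closed-form geometry", {
  # linear descent over 40 samples, linear ascent over 60; depth 2
  fs <- 100
  seg <- c(seq(0, -2, length.out = 41), seq(-2, 0, length.out = 61)[-1])
  fid <- structure(list(peak_idx = 1L, msp_idx = 21L, foot_idx = 41L,
                        ip_idx = 71L, usable = TRUE, reason = NULL),
                   class = "bioz_fiducials")
  fv <- extract_features(seg, fid, fs)
  expect_equal(unname(fv["amp_peak"]), 1, tolerance = 1e-9)
  expect_equal(unname(fv["amp_foot"]), 1, tolerance = 1e-9)
  # total area above the foot value: triangle height 2 over (n-1) samples
  n <- length(seg)
  expect_equal(unname(fv["a_total"]), 0.5 * 2 * (n - 1) / fs,
               tolerance = 0.01)
  # slope transit time = depth / |max slope|; descent slope = 2/(40/fs)
  expect_equal(unname(fv["t_stt"]), 2 / (2 / 0.4), tolerance = 0.05)
})

test_that("features are homogeneous of the right degree in amplitude", {
  tr <- clean_trial(seed = 5, duration = 40)
  bt <- segment_beats(tr$wave)
  fs <- tr$wave$sample_rate
  seg <- beat_segment(tr$wave, bt, 4)
  fid <- detect_fiducials(seg, fs)
  f1 <- extract_features(seg, fid, fs)
  f2 <- extract_features(2 * seg, detect_fiducials(2 * seg, fs), fs)
  hom <- c("amp_peak", "amp_foot", "amp_ip", "g_msp", "g_ip",
           "a_peak_foot", "a_foot_nextpeak", "a_total", "delta_bioz")
  inv <- grep("^t_", bioz_feature_names(), value = TRUE)
  expect_equal(unname(f2[hom]), unname(2 * f1[hom]), tolerance = 1e-9)
  expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-9)
})

test_that("amplitude grows and slope transit time falls with pulse pressure", {
  # noise-free sweep of pulse pressure at fixed DBP and heart rate
  fs <- 250
  shape <- beat_shape()
  cm <- compliance_model()
  amps <- numeric(0); stts <- numeric(0)
  for (sbp in c(110, 125, 140, 155, 170)) {
    P <- pressure_waveform(sbp, 80, 1.0, shape)
    tt <- (0:249) / fs
    z <- -2 * compliance_transform(P(tt), cm)
    seg <- z - z[1]
    fid <- detect_fiducials(seg, fs)
    fv <- extract_features(seg, fid, fs)
    amps <- c(amps, fv["delta_bioz"])
    stts <- c(stts, fv["t_stt"])
  }
  expect_true(all(diff(amps) > 0))
  expect_true(all(diff(stts) < 0))
})

test_that("windowed smoothing follows the 10-beat 50%-overlap rule", {
  f <- data.frame(a = rep(2, 25), b = 1:25)
  bp <- data.frame(sbp = seq(100, 148, by = 2), dbp = seq(60, 108, by = 2))
  sm <- smooth_windows(f, bp)
  expect_equal(nrow(sm), 4L)              # beats 1-10, 6-15, 11-20, 16-25
  expect_true(all(sm$a == 2))
  expect_equal(sm$b, c(5.5, 10.5, 15.5, 20.5))
  # linear ramp: windowed means equal the ramp at window centres
  expect_equal(sm$sbp, 100 + 2 * (sm$b - 1))
  expect_warning(out <- smooth_windows(f[1:5, ], bp[1:5, ]), "fewer beats")
  expect_equal(nrow(out), 0L)
})
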