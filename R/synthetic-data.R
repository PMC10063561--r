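#' Exponential arterial compliance model
#'
#' The pressure-volume behaviour of an artery is summarised by the
#' differential relation \eqn{dV = C_0 e^{-\alpha P} dP}: the instantaneous
#' compliance \eqn{C(P) = C_0 e^{-\alpha P}} decreases with transmural
#' pressure because the arterial wall stiffens as it is stretched.
#'
#' @param C0 arterial compliance at rest (mL/mmHg), must be positive.
#' @param alpha degree of pressure dependence (1/mmHg), non-negative.
#'   `alpha = 0` gives a linear pressure-volume relation.
#' @param P_ref reference pressure (mmHg) at which volume is taken as zero.
#'
#' @return An object of class `compliance_model`.
#' @seealso [compliance_transform()]
#' @export
#' @examples
#' cm <- compliance_model(C0 = 0.05, alpha = 0.02)
#' compliance_transform(c(80, 120), cm)
compliance_model <- function(C0 = 0.05, alpha = 0.02, P_ref = 80) {
  stopifnot(is.numeric(C0), length(C0) == 1L, is.finite(C0), C0 > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  stopifnot(is.numeric(P_ref), length(P_ref) == 1L, is.finite(P_ref))
  structure(list(C0 = C0, alpha = alpha, P_ref = P_ref),
            class = "compliance_model")
}

#' @export
print.compliance_model <- function(x, ...) {
  cat("Arterial compliance model: C(P) = C0 * exp(-alpha * P)\n")
  cat(sprintf("  C0 = %g mL/mmHg, alpha = %g /mmHg, P_ref = %g mmHg\n",
              x$C0, x$alpha, x$P_ref))
  invisible(x)
}

#' Arterial volume from a pressure series
#'
#' Integrates the compliance relation \eqn{dV = C_0 e^{-\alpha P} dP} in
#' closed form. For `alpha > 0`,
#' \deqn{V(P) = V_{ref} + (C_0/\alpha)(e^{-\alpha P_{ref}} - e^{-\alpha P}),}
#' and for `alpha = 0` the linear limit \eqn{V = V_{ref} + C_0 (P - P_{ref})}.
#'
#' @param P numeric vector of pressures (mmHg).
#' @param model a [compliance_model()].
#' @param V_ref volume at the reference pressure (mL); only volume
#'   differences matter downstream, so the default is 0.
#'
#' @return Numeric vector of arterial volumes (mL), same length as `P`.
#' @export
compliance_transform <- function(P, model, V_ref = 0) {
  stopifnot(inherits(model, "compliance_model"), is.numeric(P))
  if (model$alpha == 0) {
    V_ref + model$C0 * (P - model$P_ref)
  } else {
    V_ref + (model$C0 / model$alpha) *
      (exp(-model$alpha * model$P_ref) - exp(-model$alpha * P))
  }
}

#' Beat-shape parameters for the arterial pressure pulse
#'
#' Parameterises one cardiac cycle of arterial pressure as a main
#' raised-cosine wave plus a delayed raised-cosine reflection wave. The
#' resulting impedance beat shows the four canonical phases: a fall from the
#' diastolic peak to the systolic bottom, a rise as blood leaves the sensing
#' volume, a secondary dip on arrival of the reflection wave, and a final
#' rise back to the diastolic level.
#'
#' @param systolic_upstroke_fraction fraction of the inter-beat interval
#'   taken by the systolic upstroke (0 < f < 1).
#' @param reflection_delay_fraction centre of the reflection wave, as a
#'   fraction of the inter-beat interval measured from beat onset.
#' @param reflection_amplitude_ratio reflection amplitude relative to pulse
#'   pressure, in [0, 1).
#' @param reflection_width_fraction full width of the reflection bump as a
#'   fraction of the inter-beat interval.
#' @param decay_completeness fraction of the raised-cosine decay phase
#'   completed when the next beat arrives, in (0, 1]. Values below 1 leave
#'   the late-diastolic pressure still falling when the next systolic
#'   upstroke truncates it — the sharp "foot corner" of real arterial
#'   pulses — which keeps the diastolic impedance peak localizable under
#'   band-limited acquisition. 1 gives a flat-topped pure raised cosine.
#'
#' @return An object of class `beat_shape`.
#' @export
beat_shape <- function(systolic_upstroke_fraction = 0.15,
                       reflection_delay_fraction = 0.45,
                       reflection_amplitude_ratio = 0.15,
                       reflection_width_fraction = 0.30,
                       decay_completeness = 0.85) {
  stopifnot(systolic_upstroke_fraction > 0, systolic_upstroke_fraction < 1,
            reflection_amplitude_ratio >= 0, reflection_amplitude_ratio < 1,
            reflection_delay_fraction > 0, reflection_delay_fraction < 1,
            reflection_width_fraction > 0, reflection_width_fraction < 1,
            decay_completeness > 0, decay_completeness <= 1)
  if (reflection_delay_fraction + reflection_width_fraction / 2 >= 1)
    stop("reflection wave must end before the beat does")
  if (reflection_delay_fraction - reflection_width_fraction / 2 <=
      systolic_upstroke_fraction)
    stop("reflection wave must start after the systolic peak")
  structure(list(systolic_upstroke_fraction = systolic_upstroke_fraction,
                 reflection_delay_fraction = reflection_delay_fraction,
                 reflection_amplitude_ratio = reflection_amplitude_ratio,
                 reflection_width_fraction = reflection_width_fraction,
                 decay_completeness = decay_completeness),
            class = "beat_shape")
}

#' Continuous arterial pressure over one beat
#'
#' Builds the pressure waveform P(t) for a single cardiac cycle. The shape
#' is a raised-cosine main wave peaking at the configured upstroke fraction
#' of the inter-beat interval, plus a delayed raised-cosine reflection wave;
#' the sum is rescaled so that min P = DBP and max P = SBP exactly, and
#' P(0) = P(ibi) = DBP.
#'
#' @param sbp,dbp systolic and diastolic pressure for the beat (mmHg),
#'   `sbp > dbp`.
#' @param ibi inter-beat interval (s).
#' @param shape a [beat_shape()].
#'
#' @return A vectorised function `P(t)` valid for `t` in `[0, ibi]`.
#' @export
#' @examples
#' P <- pressure_waveform(120, 80, 1.0)
#' t <- seq(0, 1, by = 0.002)
#' range(P(t))   # exactly c(80, 120)
pressure_waveform <- function(sbp, dbp, ibi, shape = beat_shape()) {
  stopifnot(inherits(shape, "beat_shape"), is.finite(sbp), is.finite(dbp),
            is.finite(ibi), ibi > 0)
  if (sbp <= dbp) stop("sbp must exceed dbp")
  t_up <- shape$systolic_upstroke_fraction * ibi
  d    <- shape$reflection_delay_fraction * ibi
  w    <- shape$reflection_width_fraction * ibi
  if (d >= ibi) stop("reflection delay must be smaller than the inter-beat interval")
  r    <- shape$reflection_amplitude_ratio
  g    <- shape$decay_completeness

  raw <- function(t) {
    u <- (t - t_up) / (ibi - t_up)            # decay-phase coordinate
    main <- ifelse(t <= t_up,
                   0.5 * (1 - cos(pi * t / t_up)),
                   (cos(pi * g * u) - cos(pi * g)) / (1 - cos(pi * g)))
    refl <- ifelse(abs(t - d) <= w / 2,
                   r * 0.5 * (1 + cos(2 * pi * (t - d) / w)),
                   0)
    main + refl
  }
  # normalize on a fine grid so min/max map exactly onto dbp/sbp
  tg <- seq(0, ibi, length.out = 4096L)
  sg <- raw(tg)
  s_min <- min(sg); s_max <- max(sg)
  # the systolic peak, not the reflection wave, must be the pressure
  # maximum; otherwise the four-phase morphology is violated
  if (abs(tg[which.max(sg)] - t_up) > 0.02 * ibi)
    stop("reflection wave exceeds the systolic peak; ",
         "reduce reflection_amplitude_ratio")
  function(t) {
    s <- (raw(t) - s_min) / (s_max - s_min)
    dbp + (sbp - dbp) * s
  }
}

#' Cold-pressor style measurement protocol
#'
#' Describes an ordered sequence of protocol segments (baseline rest,
#' cold-pressor pressure rise, recovery) with target systolic/diastolic
#' pressures, together with the heart-rate model used to lay out beats.
#'
#' @param segments a data.frame with columns `kind` (one of `"baseline"`,
#'   `"cold_pressor_rise"`, `"recovery"`), `duration` (s), `sbp`, `dbp`
#'   (target pressures, mmHg).
#' @param hr_base baseline heart rate (bpm), in (30, 220).
#' @param ibi_jitter_sd standard deviation of Gaussian beat-to-beat jitter
#'   added to the inter-beat interval (s).
#' @param respiratory_mod_depth fractional depth of the respiratory sinus
#'   arrhythmia modulation of the inter-beat interval.
#' @param respiratory_freq respiratory frequency (Hz).
#' @param bp_noise_sd standard deviation of per-beat Gaussian noise added to
#'   the systolic and diastolic targets (mmHg).
#'
#' @return An object of class `bp_protocol`.
#' @export
bp_protocol <- function(segments = data.frame(
                          kind = c("baseline", "cold_pressor_rise", "recovery"),
                          duration = c(60, 90, 120),
                          sbp = c(120, 160, 120),
                          dbp = c(80, 100, 80)),
                        hr_base = 60, ibi_jitter_sd = 0.02,
                        respiratory_mod_depth = 0.03,
                        respiratory_freq = 0.25,
                        bp_noise_sd = 1.5) {
  stopifnot(is.data.frame(segments),
            all(c("kind", "duration", "sbp", "dbp") %in% names(segments)),
            nrow(segments) >= 1L)
  if (!all(segments$kind %in% c("baseline", "cold_pressor_rise", "recovery")))
    stop("segment kind must be baseline, cold_pressor_rise or recovery")
  if (any(segments$duration <= 0)) stop("segment durations must be positive")
  if (any(segments$sbp <= segments$dbp))
    stop("every segment must have SBP > DBP")
  stopifnot(hr_base > 30, hr_base < 220, ibi_jitter_sd >= 0,
            respiratory_mod_depth >= 0, bp_noise_sd >= 0)
  structure(list(segments = segments, hr_base = hr_base,
                 ibi_jitter_sd = ibi_jitter_sd,
                 respiratory_mod_depth = respiratory_mod_depth,
                 respiratory_freq = respiratory_freq,
                 bp_noise_sd = bp_noise_sd),
            class = "bp_protocol")
}

# target SBP/DBP at absolute time t for a protocol: baseline holds the
# target, a cold-pressor rise moves sigmoidally from the previous segment's
# target to its own, recovery decays exponentially toward its target.
protocol_targets <- function(protocol, t) {
  seg <- protocol$segments
  ends <- cumsum(seg$duration)
  starts <- c(0, ends[-length(ends)])
  sbp <- numeric(length(t)); dbp <- numeric(length(t))
  prev_sbp <- seg$sbp[1L]; prev_dbp <- seg$dbp[1L]
  for (i in seq_len(nrow(seg))) {
    idx <- t >= starts[i] & (t < ends[i] | i == nrow(seg))
    if (any(idx)) {
      tt <- (t[idx] - starts[i]) / seg$duration[i]   # 0..1 within segment
      if (seg$kind[i] == "baseline") {
        sbp[idx] <- seg$sbp[i]; dbp[idx] <- seg$dbp[i]
      } else if (seg$kind[i] == "cold_pressor_rise") {
        s <- 1 / (1 + exp(-10 * (tt - 0.5)))         # sigmoid 0 -> 1
        sbp[idx] <- prev_sbp + (seg$sbp[i] - prev_sbp) * s
        dbp[idx] <- prev_dbp + (seg$dbp[i] - prev_dbp) * s
      } else {                                       # recovery
        e <- exp(-3 * tt)                            # ~95% settled at end
        sbp[idx] <- seg$sbp[i] + (prev_sbp - seg$sbp[i]) * e
        dbp[idx] <- seg$dbp[i] + (prev_dbp - seg$dbp[i]) * e
      }
    }
    prev_sbp <- seg$sbp[i]; prev_dbp <- seg$dbp[i]
  }
  list(sbp = sbp, dbp = dbp)
}

#' Generate a beat-to-beat blood-pressure trajectory
#'
#' Lays out beats over the protocol duration with inter-beat intervals
#' `60/hr_base` modulated by a respiratory sinusoid and Gaussian jitter,
#' then assigns each beat systolic/diastolic pressure from the protocol's
#' segment targets (sigmoid cold-pressor rises, exponential recoveries)
#' plus per-beat Gaussian noise.
#'
#' @param protocol a [bp_protocol()].
#' @param seed integer seed; the trajectory is a pure function of
#'   `(protocol, seed)`.
#'
#' @return A data.frame of class `bp_beat_series` with columns `beat`,
#'   `time` (beat onset, s), `ibi` (s), `sbp`, `dbp` (mmHg).
#' @export
generate_bp_trajectory <- function(protocol, seed = 1L) {
  stopifnot(inherits(protocol, "bp_protocol"))
  total <- sum(protocol$segments$duration)
  ibi0 <- 60 / protocol$hr_base
  n_max <- ceiling(total / ibi0 * 1.5) + 10L
  rng <- local({ set.seed(as.integer(seed)); list(
    jitter = stats::rnorm(n_max, 0, protocol$ibi_jitter_sd),
    sbp_n  = stats::rnorm(n_max, 0, protocol$bp_noise_sd),
    dbp_n  = stats::rnorm(n_max, 0, protocol$bp_noise_sd)) })

  times <- numeric(n_max); ibis <- numeric(n_max)
  t <- 0; k <- 0L
  while (k < n_max) {
    resp <- 1 + protocol$respiratory_mod_depth *
      sin(2 * pi * protocol$respiratory_freq * t)
    ibi <- ibi0 * resp + rng$jitter[k + 1L]
    ibi <- max(ibi, 0.25)                       # physiological floor
    if (t + ibi > total) break
    k <- k + 1L
    times[k] <- t; ibis[k] <- ibi
    t <- t + ibi
  }
  times <- times[seq_len(k)]; ibis <- ibis[seq_len(k)]
  tg <- protocol_targets(protocol, times)
  sbp <- tg$sbp + rng$sbp_n[seq_len(k)]
  dbp <- tg$dbp + rng$dbp_n[seq_len(k)]
  # keep the pulse pressure physical even under noise
  bad <- sbp - dbp < 5
  sbp[bad] <- dbp[bad] + 5
  out <- data.frame(beat = seq_len(k), time = times, ibi = ibis,
                    sbp = sbp, dbp = dbp)
  class(out) <- c("bp_beat_series", "data.frame")
  out
}

#' Bioimpedance sensor and acquisition model
#'
#' Forward model of the tetrapolar acquisition chain: the injected AC
#' carrier is amplitude-modulated by the tissue impedance, which couples
#' linearly (and negatively) to arterial volume, rides on a slow sinusoidal
#' baseline drift, and is sampled with additive white Gaussian noise.
#'
#' @param carrier_freq carrier (injection) frequency, Hz.
#' @param sample_rate ADC sampling rate, Hz; must exceed twice the carrier.
#' @param z_baseline static tissue impedance (ohm).
#' @param z_gain impedance change per mL of arterial volume (ohm/mL);
#'   applied with negative sign: impedance falls as volume rises.
#' @param noise_sd additive voltage noise standard deviation (V).
#' @param drift_amplitude amplitude of the sinusoidal baseline drift (ohm).
#' @param drift_period period of the baseline drift (s); keep the drift
#'   below the 0.05 Hz band edge so band-pass conditioning removes it.
#'
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(carrier_freq = 10e3, sample_rate = 93750,
                         z_baseline = 100, z_gain = 2,
                         noise_sd = 0.01, drift_amplitude = 0.5,
                         drift_period = 60) {
  stopifnot(sample_rate > 2 * carrier_freq, z_baseline > 0, noise_sd >= 0,
            drift_amplitude >= 0, drift_period > 0, z_gain >= 0)
  structure(list(carrier_freq = carrier_freq, sample_rate = sample_rate,
                 z_baseline = z_baseline, z_gain = z_gain,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period),
            class = "sensor_model")
}

# noiseless impedance z(t) (ohm, no drift) and pressure for a beat series;
# t is absolute time in seconds. Used for both the modulator and the
# ground-truth fiducials so the two can never disagree.
impedance_series <- function(t, beats, shape, compliance, sensor) {
  z <- rep(sensor$z_baseline, length(t))
  for (i in seq_len(nrow(beats))) {
    t0 <- beats$time[i]; ibi <- beats$ibi[i]
    idx <- which(t >= t0 & t < t0 + ibi)
    if (!length(idx)) next
    P <- pressure_waveform(beats$sbp[i], beats$dbp[i], ibi, shape)
    V <- compliance_transform(P(t[idx] - t0), compliance)
    z[idx] <- sensor$z_baseline - sensor$z_gain * V
  }
  z
}

#' Ground-truth fiducial times of a clean beat series
#'
#' Locates the four fiducials (diastolic peak, maximum-slope point,
#' systolic foot, inflection point) of every beat on a fine noise-free
#' grid of the generator's impedance waveform. When `band` is given, the
#' clean waveform is first band-limited (zero-phase 2nd-order Butterworth,
#' the canonical acquisition band): the resulting times are what an ideal
#' detector operating after the conditioning chain would report, so
#' detector accuracy can be scored separately from the (separately
#' bounded) band-limiting distortion of the chain itself.
#'
#' @param beats a `bp_beat_series`.
#' @param shape a [beat_shape()].
#' @param compliance a [compliance_model()].
#' @param band `NULL` for the unfiltered waveform, or `c(low, high)` Hz.
#' @param fs_ref fine reference rate (Hz).
#' @return data.frame with absolute times (s): `t_peak`, `t_msp`,
#'   `t_foot`, `t_ip`, one row per beat (`NA` where a fiducial is not
#'   resolvable, e.g. in filter edge regions).
#' @export
ground_truth_fiducials <- function(beats, shape = beat_shape(),
                                   compliance = compliance_model(),
                                   band = NULL, fs_ref = 1000) {
  total <- max(beats$time + beats$ibi)
  n <- floor(total * fs_ref)
  t <- (seq_len(n) - 1L) / fs_ref
  sen <- sensor_model()                      # gain/baseline cancel in times
  z <- impedance_series(t, beats, shape, compliance, sen)
  if (!is.null(band)) {
    bw <- signal::butter(2, band / (fs_ref / 2), type = "pass")
    z <- signal::filtfilt(bw, z - mean(z))
  }
  dt <- 1 / fs_ref
  out <- data.frame(t_peak = rep(NA_real_, nrow(beats)), t_msp = NA_real_,
                    t_foot = NA_real_, t_ip = NA_real_)
  for (i in seq_len(nrow(beats))) {
    t0 <- beats$time[i]; ibi <- beats$ibi[i]
    # diastolic peak: maximum within a quarter-beat of the nominal onset
    w0 <- max(1L, round((t0 - 0.25 * ibi) * fs_ref) + 1L)
    w1 <- min(n, round((t0 + 0.25 * ibi) * fs_ref) + 1L)
    if (w1 - w0 < 4L) next
    pk <- w0 + which.max(z[w0:w1]) - 1L
    b1 <- min(n, pk + round(ibi * fs_ref) - 1L)
    seg <- z[pk:b1]
    if (length(seg) < 16L) next
    lim <- max(2L, floor(0.6 * length(seg)))
    foot <- which.min(seg[seq_len(lim)])
    if (foot <= 2L || foot >= length(seg) - 2L) next
    d1 <- diff(seg) / dt
    msp <- which.min(d1[seq_len(foot - 1L)])
    d2 <- diff(d1) / dt
    ip <- NA_integer_
    for (j in seq(foot, length(d2) - 1L)) {
      if (d2[j] > 0 && d2[j + 1L] <= 0) { ip <- j + 1L; break }
    }
    out$t_peak[i] <- (pk - 1L) * dt
    out$t_msp[i]  <- (pk - 1L + msp - 0.5) * dt
    out$t_foot[i] <- (pk - 1L + foot - 1L) * dt
    # ip is the last sample with positive curvature before the crossing
    out$t_ip[i]   <- if (is.na(ip)) NA_real_ else (pk - 1L + ip - 1L) * dt
  }
  out
}

# ground-truth fiducial times for one beat, located on a fine noiseless
# grid with the same definitions the detector uses: diastolic peak at beat
# onset, systolic foot = impedance minimum in the first 60% of the beat,
# maximum-slope point = most negative dZ/dt before the foot, inflection
# point = first zero crossing of the second derivative after the foot.
beat_fiducials_truth <- function(sbp, dbp, ibi, shape, compliance,
                                 dt = 1e-3) {
  tt <- seq(0, ibi, by = dt)
  P <- pressure_waveform(sbp, dbp, ibi, shape)
  V <- compliance_transform(P(tt), compliance)
  z <- -V                                    # shape only; gain irrelevant
  lim <- max(which(tt <= 0.6 * ibi))
  foot <- which.min(z[seq_len(lim)])
  dz <- diff(z) / dt
  msp <- which.min(dz[seq_len(foot - 1L)])   # derivative at midpoints
  d2 <- diff(dz) / dt
  ip <- NA_real_
  for (j in seq(foot, length(d2) - 1L)) {
    if (d2[j] > 0 && d2[j + 1L] <= 0) { ip <- j + 1L; break }
    if (d2[j] == 0) { ip <- j; break }
  }
  c(peak = 0,
    msp = tt[msp] + dt / 2,
    foot = tt[foot],
    ip = if (is.na(ip)) NA_real_ else tt[ip])
}

#' Modulate arterial volume onto a carrier-borne sensor voltage
#'
#' Synthesises the raw acquisition-board record for a beat series:
#' `v(t) = (z_baseline + drift(t) - z_gain * V(t)) * cos(2 pi f_c t) + noise`,
#' sampled at the sensor's rate, together with the ground truth needed to
#' score every downstream stage (per-beat pressures, fiducial times, and
#' the injected integer beat offset of the reference-pressure stream).
#'
#' @param beats a `bp_beat_series` from [generate_bp_trajectory()].
#' @param sensor a [sensor_model()].
#' @param shape a [beat_shape()].
#' @param compliance a [compliance_model()].
#' @param seed integer seed for the sensor noise.
#' @param beat_offset integer: the reference-pressure stream starts this
#'   many beats after the bioimpedance stream (synchronisation exercise).
#' @param dropout_prob probability that a reference beat is missing.
#' @param truth_band band (Hz) the ground-truth fiducials are referenced
#'   to (see [ground_truth_fiducials()]); defaults to the canonical
#'   0.05-6 Hz pulsatile band of the conditioning chain. `NULL` references
#'   them to the unfiltered waveform.
#'
#' @return A list of class `bioz_trial` with elements `record` (class
#'   `raw_bioz_record`: `samples`, `sample_rate`, `carrier_freq`,
#'   `start_time`), `truth` (beat table with fiducial times and the
#'   injected offset), and `reference` (the offset reference-BP stream).
#' @export
modulate <- function(beats, sensor = sensor_model(),
                     shape = beat_shape(),
                     compliance = compliance_model(),
                     seed = 1L, beat_offset = 0L, dropout_prob = 0,
                     truth_band = c(0.05, 6)) {
  stopifnot(inherits(beats, "bp_beat_series"), inherits(sensor, "sensor_model"))
  if (sensor$sample_rate <= 2 * sensor$carrier_freq)
    stop("sample_rate must exceed twice the carrier frequency (aliasing)")
  total <- max(beats$time + beats$ibi)
  n <- floor(total * sensor$sample_rate)
  t <- (seq_len(n) - 1L) / sensor$sample_rate

  z <- impedance_series(t, beats, shape, compliance, sensor)
  drift <- if (sensor$drift_amplitude > 0)
    sensor$drift_amplitude * sin(2 * pi * t / sensor$drift_period) else 0
  set.seed(as.integer(seed))
  noise <- if (sensor$noise_sd > 0) stats::rnorm(n, 0, sensor$noise_sd) else 0
  v <- (z + drift) * cos(2 * pi * sensor$carrier_freq * t) + noise

  record <- structure(list(samples = v, sample_rate = sensor$sample_rate,
                           carrier_freq = sensor$carrier_freq,
                           start_time = 0),
                      class = "raw_bioz_record")

  fid <- ground_truth_fiducials(beats, shape, compliance, band = truth_band)
  truth <- cbind(beats, fid)

  ref <- beats[, c("beat", "time", "ibi", "sbp", "dbp")]
  if (beat_offset > 0L) ref <- ref[-seq_len(beat_offset), , drop = FALSE]
  if (dropout_prob > 0) {
    keep <- stats::runif(nrow(ref)) >= dropout_prob
    ref <- ref[keep, , drop = FALSE]
  }
  rownames(ref) <- NULL

  structure(list(record = record,
                 truth = list(beats = truth, beat_offset = beat_offset),
                 reference = ref),
            class = "bioz_trial")
}

#' @export
print.raw_bioz_record <- function(x, ...) {
  cat(sprintf("Raw bioimpedance record: %d samples @ %g Hz (%.1f s), carrier %g Hz\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$carrier_freq))
  invisible(x)
}

#' Simulate a pulsatile impedance waveform at the working rate
#'
#' Shortcut that skips the carrier stage: produces the noiseless (or
#' noise-added) pulsatile impedance change directly at the post-decimation
#' working rate, plus the same ground truth as [modulate()]. Useful for the
#' feature-extraction and regression stages, where simulating and
#' demodulating minutes of 93.75 kHz carrier would add nothing.
#'
#' @inheritParams modulate
#' @param fs working sample rate (Hz).
#' @param noise_sd additive impedance noise (ohm) at the working rate.
#'
#' @return A list of class `bioz_trial_wave` with `wave` (a
#'   `pulsatile_waveform`-compatible list: `delta_z`, `sample_rate`, `band
#'   = NULL`), `truth` and `reference` as in [modulate()].
#' @export
simulate_pulsatile <- function(beats, fs = 250,
                               shape = beat_shape(),
                               compliance = compliance_model(),
                               sensor = sensor_model(),
                               seed = 1L, beat_offset = 0L,
                               noise_sd = 0, dropout_prob = 0,
                               truth_band = NULL) {
  stopifnot(inherits(beats, "bp_beat_series"))
  total <- max(beats$time + beats$ibi)
  n <- floor(total * fs)
  t <- (seq_len(n) - 1L) / fs
  z <- impedance_series(t, beats, shape, compliance, sensor)
  set.seed(as.integer(seed))
  if (noise_sd > 0) z <- z + stats::rnorm(n, 0, noise_sd)

  fid <- ground_truth_fiducials(beats, shape, compliance, band = truth_band)
  truth <- cbind(beats, fid)

  ref <- beats[, c("beat", "time", "ibi", "sbp", "dbp")]
  if (beat_offset > 0L) ref <- ref[-seq_len(beat_offset), , drop = FALSE]
  if (dropout_prob > 0) {
    keep <- stats::runif(nrow(ref)) >= dropout_prob
    ref <- ref[keep, , drop = FALSE]
  }
  rownames(ref) <- NULL

  wave <- structure(list(delta_z = z - mean(z), sample_rate = fs,
                         band = NULL),
                    class = "pulsatile_waveform")
  structure(list(wave = wave,
                 truth = list(beats = truth, beat_offset = beat_offset),
                 reference = ref),
            class = "bioz_trial_wave")
}
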