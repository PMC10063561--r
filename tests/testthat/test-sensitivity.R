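test_that("half-space current density has the analytic structure", {
  a <- c(-5, 0, 0); b <- c(5, 0, 0)
  # on the perpendicular bisector plane, J is parallel to the a->b axis
  pts <- cbind(0, c(-4, 0, 3, 8), c(1, 2, 5, 10))
  J <- halfspace_current_density(a, b, pts)
  expect_true(all(abs(J[, 2]) < 1e-12 * abs(J[, 1])))
  expect_true(all(abs(J[, 3]) < 1e-12 * abs(J[, 1])))
  # linearity in the injected current
  J2 <- halfspace_current_density(a, b, pts, current = 2)
  expect_equal(J2, J * 2, ignore_attr = TRUE)
  # divergence-free away from the electrodes (central differences)
  h <- 1e-4  # mm
  p0 <- c(2, 3, 4)
  div <- 0
  for (k in 1:3) {
    e <- rep(0, 3); e[k] <- h
    Jp <- halfspace_current_density(a, b, rbind(p0 + e))[1, k]
    Jm <- halfspace_current_density(a, b, rbind(p0 - e))[1, k]
    div <- div + (Jp - Jm) / (2 * h / 1000)
  }
  J0 <- sqrt(sum(halfspace_current_density(a, b, rbind(p0))^2))
  expect_lt(abs(div) / (J0 / (1e-3)), 1e-6)
  # total current through a surface enclosing the source is I (sanity on
  # the image-doubled prefactor): flux through a small hemisphere around a
  th <- seq(1e-3, pi / 2 - 1e-3, length.out = 400)
  ph <- seq(0, 2 * pi, length.out = 400)
  r0 <- 0.5  # mm
  grid <- expand.grid(th = th, ph = ph)
  pts_h <- cbind(a[1] + r0 * sin(grid$th) * cos(grid$ph),
                 a[2] + r0 * sin(grid$th) * sin(grid$ph),
                 r0 * cos(grid$th))
  Jh <- halfspace_current_density(a, c(1e6, 0, 0), pts_h)  # isolate source
  nrm <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
               cos(grid$th))
  dA <- (r0 / 1000)^2 * sin(grid$th) * diff(th)[1] * diff(ph)[1]
  flux <- sum(rowSums(Jh * nrm) * dA)
  expect_equal(flux, 1, tolerance = 0.01)
})

test_that("VID obeys reciprocity and vanishes for orthogonal lead fields", {
  s <- tetrapolar_setup(inj_a = c(-15, 0, 0), inj_b = c(15, 0, 0),
                        sense_m = c(-5, 0, 0), sense_n = c(5, 0, 0),
                        rho = 2)
  pts <- cbind(runif(50, -20, 20), runif(50, -20, 20), runif(50, 1, 20))
  v1 <- vid_field(s, pts)$vid
  # swap injection and sensing pairs
  s2 <- tetrapolar_setup(inj_a = c(-5, 0, 0), inj_b = c(5, 0, 0),
                         sense_m = c(-15, 0, 0), sense_n = c(15, 0, 0),
                         rho = 2)
  v2 <- vid_field(s2, pts)$vid
  expect_equal(v1, v2, tolerance = 1e-12)
  # orthogonal fields: symmetric crossed pairs give J_v . J_s = 0 on the
  # vertical symmetry axis
  sx <- tetrapolar_setup(inj_a = c(-4, 0, 0), inj_b = c(4, 0, 0),
                         sense_m = c(0, -4, 0), sense_n = c(0, 4, 0))
  ax <- cbind(0, 0, c(1, 3, 7))
  expect_equal(vid_field(sx, ax)$vid, rep(0, 3), tolerance = 1e-15)
  # VID scales with rho and is invariant to the drive current
  s3 <- tetrapolar_setup(inj_a = c(-15, 0, 0), inj_b = c(15, 0, 0),
                         sense_m = c(-5, 0, 0), sense_n = c(5, 0, 0),
                         rho = 4, current = 3)
  expect_equal(vid_field(s3, pts)$vid, 2 * v1, tolerance = 1e-12)
})

test_that("closed-form tetrapolar impedance behaves algebraically", {
  s <- wenner_setup(10, rho = 1)
  expect_equal(tetrapolar_impedance(s), 1 / (2 * pi * 0.01), tolerance = 1e-12)
  # swapping M and N flips the sign
  sflip <- tetrapolar_setup(inj_a = c(-15, 0, 0), inj_b = c(15, 0, 0),
                            sense_m = c(5, 0, 0), sense_n = c(-5, 0, 0))
  expect_equal(tetrapolar_impedance(sflip), -tetrapolar_impedance(s))
  # linear in rho
  s2 <- wenner_setup(10, rho = 3.5)
  expect_equal(tetrapolar_impedance(s2), 3.5 * tetrapolar_impedance(s))
  expect_error(tetrapolar_setup(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                c(2, 0, 0)), "distinct")
})

test_that("the VID volume integral converges to the closed form", {
  s <- wenner_setup(10, rho = 1)
  Z <- tetrapolar_impedance(s)
  errs <- vapply(c(70L, 100L, 140L), function(n)
    abs(vid_volume_integral(s, n = n) - Z) / Z, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(min(errs), 0.01)
  # refinement does not diverge
  expect_lt(errs[3], errs[1] + 0.01)
})

test_that("configuration sweep reproduces the sensitivity orderings", {
  sw <- configuration_sweep(configs = c(1, 3),
                            separations_mm = c(2, 7, 12, 18))
  m1 <- sw[sw$config == 1, ]
  m3 <- sw[sw$config == 3, ]
  # in-line electrodes over the artery beat the orthogonal layout
  expect_gte(m1$max_vid[m1$sep_mm == 2], m3$max_vid[m3$sep_mm == 2])
  # sensitivity decays monotonically with pair separation
  expect_true(all(diff(m1$max_vid) < 0))
  # specificity: primary-artery share larger at 2 mm than at 12 mm
  expect_gt(m1$primary_pct[m1$sep_mm == 2], m1$primary_pct[m1$sep_mm == 12])
  expect_error(configuration_sweep(artery = artery_line(depth_mm = 0)))
})

test_that("Cole-Cole conductivity has the right limits", {
  # no dispersions: conductivity equals the static term at any frequency
  p0 <- list(eps_inf = 10, delta_eps = 0, tau = 1e-6, alpha = 0,
             sigma_i = 0.42)
  for (f in c(10, 1e4, 1e7))
    expect_equal(Re(cole_cole_conductivity(p0, f)), 0.42, tolerance = 1e-12)
  # alpha = 0 reduces to the Debye form
  pd <- list(eps_inf = 5, delta_eps = 400, tau = 2e-7, alpha = 0,
             sigma_i = 0.1)
  f <- 10^seq(2, 8, by = 0.5)
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * f
  debye <- 1i * w * eps0 *
    (5 + 400 / (1 + 1i * w * 2e-7) + 0.1 / (1i * w * eps0))
  expect_equal(cole_cole_conductivity(pd, f), debye, tolerance = 1e-12)
  # single dispersion: effective conductivity non-decreasing in frequency
  pc <- list(eps_inf = 5, delta_eps = 400, tau = 2e-7, alpha = 0.15,
             sigma_i = 0.1)
  sig <- Re(cole_cole_conductivity(pc, 10^seq(2, 9, by = 0.1)))
  expect_true(all(diff(sig) >= 0))
  pbad <- pc; pbad$alpha <- 1.2
  expect_error(cole_cole_conductivity(pbad, 1e4), "alpha")
  # packaged blood parameters give a plausible kHz conductivity
  sb <- Re(cole_cole_conductivity(cole_cole_blood(), 1e4))
  expect_gt(sb, 0.1); expect_lt(sb, 5)
})
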