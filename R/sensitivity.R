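#' Tetrapolar electrode setup on a conductive half-space
#'
#' Four point electrodes on the surface (z = 0 plane) of a homogeneous
#' half-space of resistivity `rho` occupying z > 0: a current-injection
#' pair (A source, B sink) and a voltage-sensing pair (M, N).
#'
#' @param inj_a,inj_b,sense_m,sense_n length-3 numeric positions (mm) with
#'   z component 0.
#' @param rho medium resistivity (ohm m).
#' @param current injected current amplitude (A).
#' @return An object of class `tetrapolar_setup`.
#' @export
tetrapolar_setup <- function(inj_a, inj_b, sense_m, sense_n,
                             rho = 1, current = 1) {
  el <- rbind(inj_a = inj_a, inj_b = inj_b,
              sense_m = sense_m, sense_n = sense_n)
  stopifnot(ncol(el) == 3L, all(is.finite(el)), rho > 0, current > 0)
  if (any(abs(el[, 3]) > 1e-9))
    stop("all electrodes must lie on the z = 0 surface")
  d <- as.matrix(stats::dist(el))
  if (any(d[upper.tri(d)] < 1e-9)) stop("electrode positions must be distinct")
  structure(list(electrodes = el, rho = rho, current = current),
            class = "tetrapolar_setup")
}

#' Current density of a surface source/sink pair on a half-space
#'
#' For a point current source at `a` and sink at `b` on the boundary of a
#' homogeneous half-space, the current density at an interior point r is
#' \deqn{J(r) = (I/2\pi)\,[(r-a)/|r-a|^3 - (r-b)/|r-b|^3]} (the image
#' charges double the free-space field of each monopole, and all current I
#' flows into the half-space). The field is independent of resistivity.
#'
#' @param a,b length-3 electrode positions (mm, z = 0).
#' @param points n x 3 matrix of field points (mm, z >= 0).
#' @param current injected current (A).
#' @param eps_mm exclusion radius (mm): points within it of either
#'   electrode get `NA` rows and are flagged.
#' @return n x 3 matrix of current density vectors (A/m^2), with a logical
#'   attribute `excluded`.
#' @export
halfspace_current_density <- function(a, b, points, current = 1,
                                      eps_mm = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (any(points[, 3] < -1e-12)) stop("field points must have z >= 0")
  pm <- points / 1000   # to metres
  am <- as.numeric(a) / 1000; bm <- as.numeric(b) / 1000
  ra <- sweep(pm, 2L, am)
  rb <- sweep(pm, 2L, bm)
  da <- sqrt(rowSums(ra^2)); db <- sqrt(rowSums(rb^2))
  excl <- da < eps_mm / 1000 | db < eps_mm / 1000
  J <- (current / (2 * pi)) * (ra / da^3 - rb / db^3)
  J[excl, ] <- NA_real_
  attr(J, "excluded") <- excl
  J
}

#' Volume impedance density field (reciprocity sensitivity)
#'
#' Local contribution of each tissue volume element to the measured
#' tetrapolar transfer impedance, computed by reciprocity:
#' \deqn{VID = \rho\, (J_v \cdot J_s) / I^2} where `J_s` is the current
#' density of the injection pair and `J_v` that of the sensing pair driven
#' reciprocally with the same current. VID may be negative; its volume
#' integral over the half-space equals the tetrapolar transfer impedance
#' (the Geselowitz relation).
#'
#' @param setup a [tetrapolar_setup()].
#' @param points n x 3 matrix of field points (mm, z >= 0).
#' @param eps_mm exclusion radius around electrodes (mm).
#' @return A list of class `vid_field`: `points`, `vid` (ohm/m^3),
#'   `excluded` (logical).
#' @export
vid_field <- function(setup, points, eps_mm = 1e-6) {
  stopifnot(inherits(setup, "tetrapolar_setup"))
  el <- setup$electrodes
  Js <- halfspace_current_density(el["inj_a", ], el["inj_b", ], points,
                                  setup$current, eps_mm)
  Jv <- halfspace_current_density(el["sense_m", ], el["sense_n", ], points,
                                  setup$current, eps_mm)
  excl <- attr(Js, "excluded") | attr(Jv, "excluded")
  vid <- setup$rho * rowSums(Js * Jv) / setup$current^2
  vid[excl] <- NA_real_
  structure(list(points = matrix(as.numeric(points), ncol = 3L),
                 vid = vid, excluded = excl),
            class = "vid_field")
}

#' Closed-form tetrapolar transfer impedance on a half-space
#'
#' Textbook geometric-factor result for four point electrodes on a
#' homogeneous half-space:
#' \deqn{Z = (\rho/2\pi)\,[1/d_{AM} - 1/d_{AN} - 1/d_{BM} + 1/d_{BN}].}
#' Serves as the independent oracle for the volume integral of the VID
#' field.
#'
#' @param setup a [tetrapolar_setup()].
#' @return Transfer impedance (ohm).
#' @export
#' @examples
#' # Wenner array, spacing a = 10 mm, rho = 1 ohm m: Z = rho/(2 pi a)
#' s <- wenner_setup(a_mm = 10, rho = 1)
#' tetrapolar_impedance(s)   # 15.915 ohm
tetrapolar_impedance <- function(setup) {
  stopifnot(inherits(setup, "tetrapolar_setup"))
  el <- setup$electrodes / 1000
  d <- function(i, j) sqrt(sum((el[i, ] - el[j, ])^2))
  (setup$rho / (2 * pi)) *
    (1 / d("inj_a", "sense_m") - 1 / d("inj_a", "sense_n") -
       1 / d("inj_b", "sense_m") + 1 / d("inj_b", "sense_n"))
}

#' Wenner (equispaced collinear) tetrapolar array
#'
#' @param a_mm electrode spacing (mm); layout A-M-N-B along x.
#' @param rho resistivity (ohm m).
#' @return A [tetrapolar_setup()].
#' @export
wenner_setup <- function(a_mm = 10, rho = 1) {
  tetrapolar_setup(inj_a = c(-1.5 * a_mm, 0, 0),
                   sense_m = c(-0.5 * a_mm, 0, 0),
                   sense_n = c(0.5 * a_mm, 0, 0),
                   inj_b = c(1.5 * a_mm, 0, 0),
                   rho = rho)
}

#' Numeric volume integral of the VID field (Geselowitz check)
#'
#' Integrates VID over the whole half-space with a midpoint rule on a
#' tan-mapped rectilinear grid (`x = s tan(u)` per axis): the mapping
#' compresses the infinite domain into a finite box with resolution
#' concentrated near the electrode array, so no truncation box is needed.
#' Points inside exclusion balls of radius `eps_mm` around the electrodes
#' are skipped; the excluded contribution is O(eps^2) because the
#' reciprocal lead field is tangential at the surface, where the injected
#' field is singular. Grid scales default to a fixed fraction of the
#' array extent so accuracy is geometry-independent; pass a larger `n`
#' to refine.
#'
#' @param setup a [tetrapolar_setup()].
#' @param n grid cells per axis (the z axis uses the same count over the
#'   half range).
#' @param scale_xy_mm,scale_z_mm tan-map scales (mm); default 0.4 and 0.2
#'   of the maximum electrode separation.
#' @param eps_mm electrode exclusion-ball radius (mm).
#' @return Approximate transfer impedance (ohm).
#' @export
vid_volume_integral <- function(setup, n = 140L, scale_xy_mm = NULL,
                                scale_z_mm = NULL, eps_mm = 0.5) {
  stopifnot(inherits(setup, "tetrapolar_setup"), n >= 10L)
  ext <- max(stats::dist(setup$electrodes))
  if (is.null(scale_xy_mm)) scale_xy_mm <- max(0.4 * ext, 2)
  if (is.null(scale_z_mm)) scale_z_mm <- max(0.2 * ext, 1)
  sxy <- scale_xy_mm / 1000                 # metres
  sz <- scale_z_mm / 1000
  hu <- pi / n
  u <- -pi / 2 + (seq_len(n) - 0.5) * hu    # x and y midpoints
  wv <- (pi / 2) / n
  v <- (seq_len(n) - 0.5) * wv              # z in (0, pi/2)
  xg <- sxy * tan(u); jx <- sxy / cos(u)^2 * hu  # coordinate, cell width (m)
  zg <- sz * tan(v);  jz <- sz / cos(v)^2 * wv
  w_xy <- rep(jx, times = n) * rep(jx, each = n)
  total <- 0
  # sweep z-slabs to bound memory
  for (k in seq_len(n)) {
    pts <- cbind(rep(xg, times = n), rep(xg, each = n), zg[k]) * 1000
    vf <- vid_field(setup, pts, eps_mm = eps_mm)
    total <- total + sum(vf$vid * w_xy * jz[k], na.rm = TRUE)
  }
  total
}

#' Straight artery line below the surface
#'
#' @param depth_mm artery depth below the skin surface (mm), > 0.
#' @param y_mm lateral offset of the artery (mm); the line runs along x.
#' @param half_length_mm half-length of the sampled segment (mm).
#' @param n_points number of sample points along the line.
#' @return Matrix of line points (mm) with attribute `spacing_mm`.
#' @export
artery_line <- function(depth_mm = 3, y_mm = 0, half_length_mm = 30,
                        n_points = 241L) {
  stopifnot(depth_mm > 0)
  x <- seq(-half_length_mm, half_length_mm, length.out = n_points)
  pts <- cbind(x, y_mm, depth_mm)
  attr(pts, "spacing_mm") <- diff(x[1:2])
  pts
}

#' Electrode layouts of the three ring configurations
#'
#' Builds the tetrapolar geometry for the three canonical ring electrode
#' configurations, with the primary artery running along x at y = 0:
#' \itemize{
#'   \item Config 1 (in-line): sensing pair over the artery (x = -1, +1
#'     mm), injection pair outside it along the same line at `sep_mm` from
#'     the nearest sensing electrode.
#'   \item Config 2 (split): same x layout but the injection pair is offset
#'     to y = +`lateral_mm` and the sensing pair to y = -`lateral_mm`,
#'     straddling the artery.
#'   \item Config 3 (orthogonal): both pairs oriented across the artery
#'     (along y, electrodes at y = -1, +1 mm), the pairs `sep_mm` apart
#'     along x.
#' }
#'
#' @param config 1, 2 or 3.
#' @param sep_mm separation between injection and sensing pairs (mm).
#' @param rho resistivity (ohm m).
#' @param pair_halfwidth_mm half the within-pair electrode spacing (mm).
#' @param lateral_mm lateral offset used by Config 2 (mm).
#' @return A [tetrapolar_setup()].
#' @export
ring_configuration <- function(config, sep_mm = 2, rho = 1,
                               pair_halfwidth_mm = 1, lateral_mm = 3) {
  h <- pair_halfwidth_mm
  if (config == 1) {
    tetrapolar_setup(inj_a = c(-h - sep_mm, 0, 0),
                     sense_m = c(-h, 0, 0), sense_n = c(h, 0, 0),
                     inj_b = c(h + sep_mm, 0, 0), rho = rho)
  } else if (config == 2) {
    tetrapolar_setup(inj_a = c(-h - sep_mm, lateral_mm, 0),
                     inj_b = c(h + sep_mm, lateral_mm, 0),
                     sense_m = c(-h, -lateral_mm, 0),
                     sense_n = c(h, -lateral_mm, 0), rho = rho)
  } else if (config == 3) {
    tetrapolar_setup(inj_a = c(-sep_mm / 2, -h, 0),
                     inj_b = c(-sep_mm / 2, h, 0),
                     sense_m = c(sep_mm / 2, -h, 0),
                     sense_n = c(sep_mm / 2, h, 0), rho = rho)
  } else stop("config must be 1, 2 or 3")
}

#' Sweep electrode configurations and separations over an artery
#'
#' Samples the VID profile along a primary artery line (and a parallel
#' secondary artery) for each configuration and separation, summarising the
#' maximum VID on the primary line and the percentage of the total
#' line-integrated |VID| attributable to the primary artery.
#'
#' @param configs integer vector of configurations (subset of 1:3).
#' @param separations_mm numeric vector of pair separations (mm).
#' @param artery primary artery line from [artery_line()].
#' @param secondary secondary artery line (parallel, offset); default 8 mm
#'   lateral at the same depth.
#' @param rho resistivity (ohm m).
#' @return A data.frame: `config`, `sep_mm`, `max_vid` (ohm/m^3 on the
#'   primary line), `primary_pct` (percent of |VID| line integral on the
#'   primary artery). Attribute `profiles` keeps the per-case VID profiles.
#' @export
configuration_sweep <- function(configs = 1:3, separations_mm = c(2, 7, 12, 18),
                                artery = artery_line(),
                                secondary = artery_line(y_mm = 8),
                                rho = 1) {
  if (attr(artery, "spacing_mm") <= 0) stop("invalid artery line")
  rows <- list(); profiles <- list()
  for (cfg in configs) {
    for (sep in separations_mm) {
      setup <- ring_configuration(cfg, sep_mm = sep, rho = rho)
      v1 <- vid_field(setup, artery)$vid
      v2 <- vid_field(setup, secondary)$vid
      ds <- attr(artery, "spacing_mm") / 1000
      i1 <- sum(abs(v1), na.rm = TRUE) * ds
      i2 <- sum(abs(v2), na.rm = TRUE) * ds
      key <- sprintf("config%d_sep%g", cfg, sep)
      profiles[[key]] <- v1
      rows[[key]] <- data.frame(config = cfg, sep_mm = sep,
                                max_vid = max(v1, na.rm = TRUE),
                                primary_pct = 100 * i1 / (i1 + i2))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  out
}

#' Cole-Cole complex conductivity of a tissue
#'
#' Evaluates the multi-dispersion Cole-Cole permittivity
#' \deqn{\hat\varepsilon(\omega) = \varepsilon_\infty +
#'   \sum_n \Delta\varepsilon_n / (1 + (j\omega\tau_n)^{1-\alpha_n}) +
#'   \sigma_i/(j\omega\varepsilon_0)}
#' and returns the complex conductivity
#' \eqn{\sigma(\omega) = j\omega\varepsilon_0\hat\varepsilon(\omega)};
#' `Re` of it is the effective conductivity at that frequency.
#'
#' @param params list with `eps_inf`, `delta_eps` (vector), `tau` (vector,
#'   s), `alpha` (vector in [0, 1)), `sigma_i` (S/m). The packaged
#'   `cole_cole_blood` parameters are literature-style placeholder values
#'   for whole blood.
#' @param freq frequency vector (Hz), > 0.
#' @return Complex conductivity (S/m), same length as `freq`.
#' @export
#' @examples
#' Re(cole_cole_conductivity(cole_cole_blood(), 10e3))
cole_cole_conductivity <- function(params, freq) {
  stopifnot(all(freq > 0),
            length(params$delta_eps) == length(params$tau),
            length(params$tau) == length(params$alpha))
  if (any(params$alpha < 0 | params$alpha >= 1))
    stop("Cole-Cole alpha exponents must lie in [0, 1)")
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * freq
  eps_hat <- rep(params$eps_inf + 0i, length(w))
  for (k in seq_along(params$tau)) {
    eps_hat <- eps_hat + params$delta_eps[k] /
      (1 + (1i * w * params$tau[k])^(1 - params$alpha[k]))
  }
  eps_hat <- eps_hat + params$sigma_i / (1i * w * eps0)
  1i * w * eps0 * eps_hat
}

#' Placeholder Cole-Cole parameters for whole blood
#'
#' Four-dispersion parameter set of the common literature form for whole
#' blood. These are synthetic placeholder values of realistic magnitude,
#' intended for exercising [cole_cole_conductivity()]; they are not a
#' fitted tissue database.
#'
#' @return Parameter list for [cole_cole_conductivity()].
#' @export
cole_cole_blood <- function() {
  list(eps_inf = 4,
       delta_eps = c(56, 5200, 0, 0),
       tau = c(8.38e-12, 132.6e-9, 159.2e-6, 15.92e-3),
       alpha = c(0.1, 0.1, 0.2, 0),
       sigma_i = 0.7)
}
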