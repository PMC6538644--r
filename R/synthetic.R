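#' Specification of a layered spherical skull phantom
#'
#' The phantom is a spherical shell with cortical-trabecular-cortical
#' layering (outer and inner tables around a diploe), water/brain at 0 HU
#' inside and outside, optionally thinned over lateral "temporal window"
#' patches. The default geometry is adult-scale: 85 mm inner radius and a
#' 2 + 3 + 2 mm sandwich at 1800 / 900 / 1800 HU, which yields a mid-range
#' skull density ratio near 0.5.
#'
#' @param inner_radius mm
#' @param cortical_thickness,trabecular_thickness layer thicknesses, mm
#' @param cortical_hu,trabecular_hu layer HU values (in `[0, 3000]`)
#' @param temporal_window list with `enabled`, `direction` (unit-ish vector,
#'   the window is applied on both +-direction sides), `thinning` (fraction
#'   of thickness removed at the window centre, in `[0, 1)`), `angular_sd_deg`
#'   (Gaussian angular width of the patch)
#' @param grid a [sim_grid()] the phantom is voxelised on (identity
#'   orientation)
#' @param center shell centre, mm world; default the geometric focus
#' @param seed integer, recorded for provenance (the phantom is analytic and
#'   fully deterministic)
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(inner_radius = 85, cortical_thickness = 2,
                         trabecular_thickness = 3, cortical_hu = 1800,
                         trabecular_hu = 900,
                         temporal_window = list(enabled = FALSE,
                                                direction = c(1, 0, 0),
                                                thinning = 0.6,
                                                angular_sd_deg = 30),
                         grid = sim_grid(c(192, 192, 192), 1),
                         center = c(0, 0, 0), seed = 1L) {
  stopifnot(inner_radius > 0, cortical_thickness >= 0,
            trabecular_thickness >= 0,
            cortical_hu >= 0, cortical_hu <= 3000,
            trabecular_hu >= 0, trabecular_hu <= 3000)
  tw <- modifyList(list(enabled = FALSE, direction = c(1, 0, 0),
                        thinning = 0.6, angular_sd_deg = 30),
                   temporal_window)
  stopifnot(tw$thinning >= 0, tw$thinning < 1)
  structure(list(inner_radius = inner_radius,
                 cortical_thickness = cortical_thickness,
                 trabecular_thickness = trabecular_thickness,
                 cortical_hu = cortical_hu, trabecular_hu = trabecular_hu,
                 temporal_window = tw, grid = grid, center = center,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' The reference phantom
#'
#' Convenience preset used throughout the tests and examples; pass
#' `temporal_window = TRUE` for the thin-temporal-bone variant.
#'
#' @param temporal_window logical
#' @param ... overrides forwarded to [phantom_spec()]
#' @return a `phantom_spec`
#' @export
reference_phantom <- function(temporal_window = FALSE, ...) {
  phantom_spec(temporal_window = list(enabled = temporal_window), ...)
}

#' Voxelise a skull phantom to an HU volume
#'
#' Layer boundaries are radii from the shell centre; under a temporal window
#' every layer thickness is scaled by
#' `1 - thinning * exp(-ang^2 / (2 sd^2))`, where `ang` is the angle between
#' the voxel direction and the +-window direction, so the shell thins
#' smoothly over the lateral patches while the inner surface stays put.
#'
#' @param spec a [phantom_spec()]
#' @return an [hu_volume()] on the spec's grid
#' @export
make_skull_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  check_rotation(g$orientation)
  if (max(abs(g$orientation - diag(3))) > 1e-9) {
    stop("phantom grids must have identity orientation")
  }
  thick_total <- 2 * spec$cortical_thickness + spec$trabecular_thickness
  ax <- grid_axis_coords(g)
  x <- ax[[1]] - spec$center[1]
  y <- ax[[2]] - spec$center[2]
  z <- ax[[3]] - spec$center[3]
  outer_r <- spec$inner_radius + thick_total
  if (thick_total > 0 &&
      (outer_r > max(abs(x)) || outer_r > max(abs(y)) || outer_r > max(abs(z)))) {
    stop("skull layers exceed the phantom grid")
  }
  d <- g$shape
  r <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  scale <- 1
  tw <- spec$temporal_window
  if (isTRUE(tw$enabled) && tw$thinning > 0) {
    dir <- tw$direction / sqrt(sum(tw$direction^2))
    dot <- outer(outer(x * dir[1], y * dir[2], `+`), z * dir[3], `+`)
    cosang <- pmin(1, abs(dot) / pmax(r, 1e-9))  # window on both +- sides
    ang <- acos(cosang)                          # angle to the window axis
    sd <- tw$angular_sd_deg * pi / 180
    scale <- 1 - tw$thinning * exp(-ang^2 / (2 * sd^2))
  }
  b0 <- spec$inner_radius
  b1 <- b0 + spec$cortical_thickness * scale
  b2 <- b0 + (spec$cortical_thickness + spec$trabecular_thickness) * scale
  b3 <- b0 + thick_total * scale
  hu <- array(0, d)
  hu[r >= b0 & r < b1] <- spec$cortical_hu
  hu[r >= b1 & r < b2] <- spec$trabecular_hu
  hu[r >= b2 & r < b3] <- spec$cortical_hu
  hu_volume(hu, spacing = g$spacing, origin = g$origin,
            orientation = g$orientation)
}

#' Generate a synthetic sonication log
#'
#' Emulates a treatment's temperature-rise-versus-power behaviour: peak
#' temperature rise at timepoint 3 follows the treatment efficiency line
#' `tr_eff_true * power` plus Gaussian noise; designated roll-off outliers
#' are suppressed below the line by `outlier_depth_sd` noise standard
#' deviations; the first sonication is flagged as an alignment sonication.
#' Fully seeded and deterministic.
#'
#' @param n number of sonications (>= 2)
#' @param tr_eff_true degC/W
#' @param powers applied powers, W (recycled to length `n`)
#' @param noise_sd degC
#' @param outlier_idx indices of roll-off outliers (may be empty)
#' @param outlier_depth_sd suppression depth in noise SDs
#' @param phase_encode per-record phase encode label (recycled)
#' @param seed integer
#' @return data.frame with columns `index`, `power`, `duration`,
#'   `peak_dT_tp3`, `is_alignment`, `phase_encode`
#' @export
make_sonication_log <- function(n, tr_eff_true, powers, noise_sd = 0,
                                outlier_idx = integer(0),
                                outlier_depth_sd = 5,
                                phase_encode = "RL", seed = 1L) {
  stopifnot(n >= 2, all(powers > 0), noise_sd >= 0,
            all(outlier_idx >= 1 & outlier_idx <= n))
  power <- rep_len(powers, n)
  with_seed(seed, {
    peak <- tr_eff_true * power + rnorm(n, 0, noise_sd)
  })
  peak[outlier_idx] <- tr_eff_true * power[outlier_idx] -
    outlier_depth_sd * noise_sd
  data.frame(index = seq_len(n), power = power, duration = 10,
             peak_dT_tp3 = peak,
             is_alignment = c(TRUE, rep(FALSE, n - 1)),
             phase_encode = rep_len(phase_encode, n))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate noisy PRF thermometry phase frames from temperature maps
#'
#' Each temperature frame is converted to phase with the PRF coefficient,
#' a planar background drift `a + b x + c y` is added, and complex-domain
#' Gaussian noise is applied (noise enters the complex MR signal, so the
#' phase noise standard deviation is TE- and B0-dependent as in real data):
#' `z = exp(i phi) + sigma (n1 + i n2)`, `phi' = Arg(z)` with
#' `sigma = |dphi/dT| * noise_sd`.
#'
#' @param temp_frames list of 2D temperature-rise images, degC
#' @param noise_sd apparent temperature noise SD, degC
#' @param drift planar phase drift coefficients `c(a, b, c)` in radians
#'   (absolute, per row pixel, per column pixel)
#' @param TE,B0 echo time (s) and field strength (T)
#' @param seed integer
#' @return list with `phase` (noisy phase frames), `truth` (input
#'   temperature frames), and the generation parameters
#' @export
make_thermometry_frames <- function(temp_frames, noise_sd = 0,
                                    drift = c(0, 0, 0), TE = 0.013, B0 = 3,
                                    seed = 1L) {
  stopifnot(is.list(temp_frames), length(temp_frames) >= 1)
  coeff <- prf_rad_per_degc(TE, B0)
  sigma <- abs(coeff) * noise_sd
  phase <- with_seed(seed, lapply(temp_frames, function(Tf) {
    phi <- Tf * coeff +
      drift[1] + drift[2] * row(Tf) + drift[3] * col(Tf)
    if (sigma > 0) {
      z <- exp(1i * phi) +
        sigma * (matrix(rnorm(length(Tf)), nrow(Tf)) +
                 1i * matrix(rnorm(length(Tf)), nrow(Tf)))
      phi <- Arg(z)
    }
    phi
  }))
  list(phase = phase, truth = temp_frames,
       params = list(noise_sd = noise_sd, drift = drift, TE = TE, B0 = B0,
                     seed = seed))
}
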