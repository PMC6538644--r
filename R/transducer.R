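#' Build the hemispherical phased-array transducer
#'
#' Elements are laid out on a spherical cap by a deterministic Fibonacci
#' spiral (quasi-uniform packing; the clinical array's proprietary layout is
#' not public, and focal-zone physics is insensitive to the exact packing).
#' The default geometry is the clinical 680 kHz system: 30 cm aperture
#' diameter, 15 cm radius of curvature, 1024 elements. Element normals point
#' at the centre of curvature (the geometric focus, the world origin); the
#' transducer pole sits on +z.
#'
#' @param n_elements number of elements
#' @param roc radius of curvature, mm
#' @param aperture aperture diameter, mm (must be <= 2 * roc)
#' @param frequency fundamental frequency, Hz
#' @param seed integer; sets the (deterministic) azimuthal registration of
#'   the spiral
#' @return object of class `transducer_array` with element centres (mm),
#'   unit normals, per-element areas (mm2) and geometry metadata; plate
#'   assignment is added by [partition_plates()]
#' @export
build_array <- function(n_elements = 1024, roc = 150, aperture = 300,
                        frequency = 680e3, seed = 1L) {
  stopifnot(n_elements >= 1, roc > 0, frequency > 0)
  if (aperture > 2 * roc + 1e-9 || aperture <= 0) {
    stop("infeasible geometry: need 0 < aperture <= 2 * roc")
  }
  half_angle <- asin(min(aperture / (2 * roc), 1))
  cos_max <- cos(half_angle)
  i <- seq_len(n_elements)
  # uniform in cos(theta) over the cap -> equal-area rings
  ct <- 1 - (i - 0.5) / n_elements * (1 - cos_max)
  st <- sqrt(pmax(0, 1 - ct^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + 2 * pi * (as.integer(seed) %% 997L) / 997
  centers <- roc * cbind(st * cos(phi), st * sin(phi), ct)
  normals <- -centers / roc
  cap_area <- 2 * pi * roc^2 * (1 - cos_max)
  structure(list(element_centers = centers, element_normals = normals,
                 element_area = rep(cap_area / n_elements, n_elements),
                 radius_of_curvature = roc, aperture_diameter = aperture,
                 frequency = frequency, n_elements = n_elements,
                 plate_id = NULL, plate_axes = NULL, seed = as.integer(seed)),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat("<transducer_array> ", x$n_elements, " elements, ROC ",
      x$radius_of_curvature, " mm, aperture ", x$aperture_diameter,
      " mm, ", x$frequency / 1e3, " kHz",
      if (!is.null(x$plate_id)) paste0(", ", ncol(x$plate_axes), " plates"),
      "\n", sep = "")
  invisible(x)
}

#' Partition the array into propagation plates
#'
#' The angular spectrum method marches planes perpendicular to a propagation
#' axis, so the cap is split into sub-apertures ("plates"), each with its own
#' axis. The default decomposition is one polar axis plus `n_plates - 1`
#' oblique axes at `inclination_deg` from the pole, evenly spaced in azimuth
#' (for 7 plates: 6 axes at 60 degree spacing). Each element joins the plate
#' whose axis is most aligned with the element direction; ties break to the
#' lowest plate index. Plates left empty are dropped with a warning.
#'
#' @param array a [build_array()] result
#' @param n_plates number of plates (>= 1)
#' @param inclination_deg polar angle of the oblique plate axes
#' @return the array with `plate_id` (1-based per element) and `plate_axes`
#'   (3 x P unit columns, pointing from the focus toward each plate)
#' @export
partition_plates <- function(array, n_plates = 7, inclination_deg = 40) {
  stopifnot(inherits(array, "transducer_array"), n_plates >= 1)
  if (n_plates == 1) {
    axes <- matrix(c(0, 0, 1), 3, 1)
  } else {
    inc <- inclination_deg * pi / 180
    az <- 2 * pi * (seq_len(n_plates - 1) - 1) / (n_plates - 1)
    axes <- cbind(c(0, 0, 1),
                  rbind(sin(inc) * cos(az), sin(inc) * sin(az),
                        rep(cos(inc), n_plates - 1)))
  }
  dirs <- array$element_centers / array$radius_of_curvature
  scores <- dirs %*% axes
  ids <- apply(scores, 1, which.max)
  present <- sort(unique(ids))
  if (length(present) < ncol(axes)) {
    warning("dropping ", ncol(axes) - length(present), " empty plate(s)")
    axes <- axes[, present, drop = FALSE]
    ids <- match(ids, present)
  }
  array$plate_id <- ids
  array$plate_axes <- axes
  array
}

#' Electronic steering phases
#'
#' Phase-conjugation steering in a homogeneous medium: element i is driven
#' with `-k * (|x_i - target| - ROC)` (wrapped to `[0, 2pi)`), which equalises
#' the acoustic path phase at the target. At the geometric focus all phases
#' are zero.
#'
#' @param array a `transducer_array`
#' @param target steering target, mm in the transducer frame
#' @param c_ref reference sound speed, m/s
#' @return numeric vector of per-element phases in `[0, 2pi)` (radians)
#' @export
steering_phases <- function(array, target = c(0, 0, 0), c_ref = 1500) {
  stopifnot(inherits(array, "transducer_array"), c_ref > 0)
  k <- 2 * pi * array$frequency / (c_ref * 1000)  # rad/mm
  d <- sqrt(rowSums(sweep(array$element_centers, 2, target)^2))
  wrap_phase(-k * (d - array$radius_of_curvature))
}

wrap_phase <- function(phi) phi %% (2 * pi)

#' Per-sonication element drive
#'
#' @param phases per-element phases (radians; wrapped to `[0, 2pi)`); scalar
#'   recycled
#' @param amplitudes per-element nonnegative relative amplitudes; scalar
#'   recycled
#' @param power applied acoustic power, W
#' @param duration sonication duration, s
#' @param n_elements element count used for recycling scalars
#' @return object of class `drive_settings`
#' @export
drive_settings <- function(phases = 0, amplitudes = 1, power = 100,
                           duration = 10, n_elements = NULL) {
  n <- max(length(phases), length(amplitudes), n_elements %||% 0L)
  phases <- wrap_phase(rep_len(as.numeric(phases), n))
  amplitudes <- rep_len(as.numeric(amplitudes), n)
  stopifnot(all(is.finite(phases)), all(amplitudes >= 0),
            is.finite(power), power >= 0, duration > 0)
  if (power > 0 && all(amplitudes == 0)) {
    stop("all amplitudes zero with positive power")
  }
  structure(list(phases = phases, amplitudes = amplitudes,
                 acoustic_power = power, duration = duration),
            class = "drive_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
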