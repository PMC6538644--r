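#' Plane specification for per-plate source projection
#'
#' Describes the starting plane of one plate's angular spectrum march:
#' perpendicular to the plate axis, centred on it at `offset_mm` from the
#' focus, with an `nx` x `ny` pixel grid at `spacing` mm.
#'
#' @param offset_mm distance of the plane centre from the focus along the
#'   plate axis (toward the transducer)
#' @param shape pixel counts `c(nx, ny)`
#' @param spacing pixel pitch, mm (must satisfy the half-wavelength sampling
#'   limit of the propagation frequency)
#' @return a `plane_spec` list
#' @export
plane_spec <- function(offset_mm, shape = c(128, 128), spacing = NULL) {
  structure(list(offset_mm = offset_mm, shape = as.integer(shape),
                 spacing = spacing), class = "plane_spec")
}

# Orthonormal in-plane axes for a plate axis; deterministic choice.
plate_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e3 <- -axis                      # propagation direction: toward the focus
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = e3, axis = axis)
}

# Subdivide the elements of one plate into point-like patches.
# Each element is treated as a flat disc of its area, perpendicular to its
# normal, sampled on a <= pitch grid; patch areas are renormalised so they
# sum to the element area. Returns positions (M x 3) and complex strengths.
element_patches <- function(array, drive, elements, pitch) {
  pos <- list(); amp <- list()
  for (ei in elements) {
    ctr <- array$element_centers[ei, ]
    nrm <- array$element_normals[ei, ]
    area <- array$element_area[ei]
    r <- sqrt(area / pi)
    b <- plate_basis(-nrm)         # tangent frame of the element
    g <- seq(-r, r, by = pitch)
    if (length(g) < 1) g <- 0
    uv <- expand.grid(u = g, v = g)
    uv <- uv[uv$u^2 + uv$v^2 <= r^2, , drop = FALSE]
    if (nrow(uv) == 0) uv <- data.frame(u = 0, v = 0)
    p <- matrix(ctr, nrow(uv), 3, byrow = TRUE) +
      outer(uv$u, b$e1) + outer(uv$v, b$e2)
    a_patch <- area / nrow(uv)
    drv <- drive$amplitudes[ei] * exp(1i * drive$phases[ei]) * a_patch
    pos[[length(pos) + 1]] <- p
    amp[[length(amp) + 1]] <- rep(drv, nrow(uv))
  }
  list(positions = do.call(rbind, pos), strengths = do.call(c, amp))
}

#' Project a plate's elements onto its source plane
#'
#' Evaluates the free-field (water) Rayleigh-Sommerfeld sum of every element
#' of the plate, discretised into patches no larger than a quarter
#' wavelength, on the plate's starting plane. Element phases and amplitudes
#' from `drive` are applied. Pressure is in relative units until
#' [normalize_power()] fixes the absolute scale.
#'
#' @param array a plate-partitioned `transducer_array`
#' @param plate plate index (1-based)
#' @param drive a [drive_settings()]
#' @param plane a [plane_spec()]
#' @param patch_pitch element discretisation pitch, mm; default a quarter
#'   wavelength in water
#' @param c_water projection sound speed, m/s
#' @return object of class `source_plane`: complex pressure matrix plus the
#'   plane frame (origin, axes with the third column the propagation
#'   direction, spacing)
#' @export
project_source_plane <- function(array, plate, drive, plane,
                                 patch_pitch = NULL, c_water = 1500) {
  stopifnot(inherits(array, "transducer_array"),
            !is.null(array$plate_id), inherits(drive, "drive_settings"))
  lam <- wavelength_mm(array$frequency, c_water)
  spacing <- plane$spacing %||% (lam / 3)
  if (spacing > lam / 2 + 1e-12) {
    stop("plane spacing ", spacing, " mm exceeds lambda/2 = ", lam / 2,
         " mm (aliasing)")
  }
  patch_pitch <- patch_pitch %||% (lam / 4)
  stopifnot(patch_pitch <= lam / 4 + 1e-12)
  b <- plate_basis(array$plate_axes[, plate])
  nx <- plane$shape[1]; ny <- plane$shape[2]
  origin <- plane$offset_mm * b$axis -
    ((nx - 1) / 2) * spacing * b$e1 - ((ny - 1) / 2) * spacing * b$e2
  elements <- which(array$plate_id == plate)
  k <- 2 * pi * array$frequency / (c_water * 1000)
  if (all(drive$amplitudes[elements] == 0)) {
    p <- matrix(0 + 0i, nx, ny)
  } else {
    pat <- element_patches(array, drive, elements, patch_pitch)
    p <- rs_project_cpp(pat$positions, pat$strengths, origin,
                        b$e1, b$e2, nx, ny, spacing, spacing, k)
  }
  structure(list(pressure = p, origin = origin,
                 axes = cbind(b$e1, b$e2, b$e3), spacing = c(spacing, spacing),
                 frequency = array$frequency, plate = plate,
                 offset_mm = plane$offset_mm),
            class = "source_plane")
}

#' Scale source planes to a target acoustic power
#'
#' All planes are multiplied by one common factor so that the summed
#' plane-integrated intensity flux, `sum |p|^2 / (2 rho c) dA`, equals
#' `target_power`. With the peak-amplitude pressure convention used
#' throughout, intensity is `|p|^2 / (2 rho c)`.
#'
#' @param planes list of `source_plane`s (or a single one)
#' @param target_power W (>= 0)
#' @param rho,c water density (kg/m3) and sound speed (m/s) at the planes
#' @return the planes, scaled; the applied factor is in attribute `"scale"`
#' @export
normalize_power <- function(planes, target_power, rho = 1000, c = 1500) {
  single <- inherits(planes, "source_plane")
  if (single) planes <- list(planes)
  stopifnot(target_power >= 0)
  flux <- vapply(planes, function(pl) {
    dA <- prod(pl$spacing) * 1e-6                       # mm2 -> m2
    sum(Mod(pl$pressure)^2) / (2 * rho * c) * dA
  }, numeric(1))
  total <- sum(flux)
  if (target_power == 0) {
    s <- 0
  } else if (total <= 0) {
    stop("zero total flux with positive target power")
  } else {
    s <- sqrt(target_power / total)
  }
  out <- lapply(planes, function(pl) { pl$pressure <- pl$pressure * s; pl })
  if (single) out <- out[[1]]
  attr(out, "scale") <- s
  out
}
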