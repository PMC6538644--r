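#' Steady-state complex pressure volume
#' @keywords internal
pressure_volume <- function(pressure, spacing, origin, orientation,
                            frequency, meta = list()) {
  structure(list(pressure = pressure, spacing = spacing, origin = origin,
                 orientation = orientation, frequency = frequency,
                 meta = meta),
            class = "pressure_volume")
}

#' @export
print.pressure_volume <- function(x, ...) {
  cat("<pressure_volume> ", paste(dim(x$pressure), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; peak |p| = ", signif(max(Mod(x$pressure)), 4), " Pa\n", sep = "")
  invisible(x)
}

#' One hybrid angular spectrum propagation step (reference implementation)
#'
#' Split-step update of a complex pressure plane across one slab of thickness
#' `dz`: (a) a spatial-domain factor `exp(i k0 (n - 1) dz - alpha dz)` with
#' `n = c_background / c(x, y)`; (b) 2D FFT; (c) the angular spectrum
#' diffraction factor `exp(i dz (sqrt(k_avg^2 - kx^2 - ky^2) - k_avg)) *
#' exp(i k0 dz)` with `k_avg` taken at the slab's mean speed, evanescent
#' components decayed via the imaginary axial wavenumber (never amplified);
#' (d) inverse FFT. This plain-R step is the readable reference; volume
#' marches use the compiled equivalent in [simulate_plate()].
#'
#' @param plane a `source_plane`
#' @param slab list with `velocity` (m/s matrix) and `attenuation` (Np/cm
#'   matrix) matching the plane's pixel grid
#' @param dz step, mm (> 0)
#' @param background list with water `velocity` (m/s)
#' @param pad_frac zero-padding per side before the transforms, as a fraction
#'   of the plane size (suppresses periodic wraparound); 0 disables padding
#' @param mean_speed `"slab"` (arithmetic mean of the slab speed) or
#'   `"background"` for the diffraction reference speed
#' @return the propagated `source_plane`, origin advanced by `dz`
#' @export
propagate_plane <- function(plane, slab, dz,
                            background = list(velocity = 1500),
                            pad_frac = 0.25,
                            mean_speed = c("slab", "background")) {
  mean_speed <- match.arg(mean_speed)
  stopifnot(inherits(plane, "source_plane"), dz > 0)
  p <- plane$pressure
  vel <- slab$velocity; att <- slab$attenuation
  if (!all(dim(vel) == dim(p)) || !all(dim(att) == dim(p))) {
    stop("slab shape does not match plane")
  }
  if (anyNA(vel) || anyNA(att)) stop("NaN in slab properties")
  c_bg <- background$velocity
  k0 <- 2 * pi * plane$frequency / (c_bg * 1000)   # rad/mm
  # (a) refraction and attenuation in the spatial domain
  p <- p * exp(1i * k0 * (c_bg / vel - 1) * dz - (att / 10) * dz)
  nx <- nrow(p); ny <- ncol(p)
  px <- ceiling(pad_frac * nx); py <- ceiling(pad_frac * ny)
  P <- matrix(0 + 0i, nx + 2 * px, ny + 2 * py)
  P[px + seq_len(nx), py + seq_len(ny)] <- p
  c_mean <- if (mean_speed == "slab") mean(vel) else c_bg
  k_avg <- k0 * c_bg / c_mean
  kx <- fft_freq(nrow(P), plane$spacing[1])
  ky <- fft_freq(ncol(P), plane$spacing[2])
  kz <- sqrt(as.complex(outer(kx^2, ky^2, function(a, b) k_avg^2 - a - b)))
  dim(kz) <- dim(P)
  H <- exp(1i * (dz * (kz - k_avg) + k0 * dz))
  P <- fft(fft(P) * H, inverse = TRUE) / length(P)
  plane$pressure <- P[px + seq_len(nx), py + seq_len(ny)]
  plane$origin <- plane$origin + dz * plane$axes[, 3]
  plane
}

fft_freq <- function(n, d) {
  i <- 0:(n - 1)
  i[i >= (n + 1) %/% 2] <- i[i >= (n + 1) %/% 2] - n
  2 * pi * i / (n * d)
}

#' March a source plane through a property volume (one plate)
#'
#' Marches the plane slice by slice through plate-frame property cubes with
#' the compiled split-step kernel; slice `j` of the result is the plane after
#' `j` propagation steps (slice 1 is the source plane itself). Property slab
#' `j` governs the step onto slice `j`.
#'
#' @param source a `source_plane` coinciding with the first grid slice
#' @param velocity,attenuation 3D arrays on the plate marching grid (m/s and
#'   Np/cm); pass `NULL` for a uniform water volume
#' @param nz number of slices (required if property cubes are `NULL`)
#' @param dz slice spacing, mm
#' @inheritParams propagate_plane
#' @return a `pressure_volume` in the plate frame
#' @export
simulate_plate <- function(source, velocity = NULL, attenuation = NULL,
                           nz = NULL, dz, background = list(velocity = 1500),
                           pad_frac = 0.25, mean_speed = c("slab", "background")) {
  mean_speed <- match.arg(mean_speed)
  stopifnot(inherits(source, "source_plane"), dz > 0)
  p0 <- source$pressure
  if (is.null(velocity)) {
    stopifnot(!is.null(nz))
    velocity <- array(background$velocity, c(dim(p0), nz))
    attenuation <- array(0, c(dim(p0), nz))
  }
  stopifnot(all(dim(velocity)[1:2] == dim(p0)),
            all(dim(attenuation) == dim(velocity)))
  if (anyNA(velocity) || anyNA(attenuation)) stop("NaN in properties")
  nx <- nrow(p0); ny <- ncol(p0)
  k0 <- 2 * pi * source$frequency / (background$velocity * 1000)
  out <- has_march_cpp(p0, velocity, attenuation / 10,
                       source$spacing[1], source$spacing[2], dz, k0,
                       background$velocity,
                       ceiling(pad_frac * nx), ceiling(pad_frac * ny),
                       mean_speed == "background")
  if (!all(is.finite(Re(out)) & is.finite(Im(out)))) {
    stop("propagation instability: non-finite pressure (peak |p0| = ",
         signif(max(Mod(p0)), 3), ", dz = ", dz, " mm, ", dim(velocity)[3],
         " slices)")
  }
  pressure_volume(out, spacing = c(source$spacing, dz),
                  origin = source$origin,
                  orientation = source$axes,
                  frequency = source$frequency,
                  meta = list(plate = source$plate))
}

#' Fuse per-plate pressure volumes onto a common grid
#'
#' Complex trilinear resampling of each plate-frame volume into the target
#' grid, followed by a complex sum. Target voxels outside a plate's coverage
#' receive zero from that plate.
#'
#' @param plate_volumes list of `pressure_volume`s (plate frames)
#' @param target a [sim_grid()]
#' @return a `pressure_volume` on the target grid
#' @export
fuse_volumes <- function(plate_volumes, target) {
  stopifnot(length(plate_volumes) >= 1, inherits(target, "sim_grid"))
  acc <- array(0 + 0i, target$shape)
  for (pv in plate_volumes) {
    A <- affine_index_map(geom_of(pv), target)
    acc <- acc + resample_complex_cpp(pv$pressure, A, target$shape[1],
                                      target$shape[2], target$shape[3])
  }
  pressure_volume(acc, spacing = target$spacing, origin = target$origin,
                  orientation = target$orientation,
                  frequency = plate_volumes[[1]]$frequency,
                  meta = list(n_plates = length(plate_volumes)))
}

#' Marching-grid settings for the per-plate HAS solve
#'
#' @param shape in-plane pixel counts and slice count, `c(nx, ny, nz)`
#' @param spacing `c(in_plane, dz)` mm; default one third of the water
#'   wavelength for both
#' @param pad_frac transform zero-padding per side (fraction)
#' @param patch_pitch element discretisation, mm (default lambda/4)
#' @param focus_margin minimum marching distance past the focus, mm
#' @param mean_speed diffraction reference speed, `"slab"` or `"background"`
#' @return a `march_spec` list
#' @export
march_spec <- function(shape = c(128, 128, 192), spacing = NULL,
                       pad_frac = 0.25, patch_pitch = NULL,
                       focus_margin = 15, mean_speed = "slab") {
  structure(list(shape = as.integer(shape), spacing = spacing,
                 pad_frac = pad_frac, patch_pitch = patch_pitch,
                 focus_margin = focus_margin, mean_speed = mean_speed),
            class = "march_spec")
}

#' Simulate one sonication end to end
#'
#' Full acoustic composition: HU volume -> property volumes -> per-plate
#' source projection -> power normalisation -> per-plate HAS march -> fusion
#' onto the target grid. With `skull = NULL` the medium is a water bath.
#'
#' Each plate's starting plane is placed perpendicular to its axis, beyond
#' the skull's extent along that axis (2 mm clearance) and behind the plate's
#' elements where the marching length allows; grazing elements that end up in
#' front of a plane contribute only approximately and are counted in the
#' returned metadata.
#'
#' @param array a `transducer_array` (plate-partitioned, or it will be
#'   partitioned with defaults)
#' @param drive a [drive_settings()]; its phases/amplitudes are per element
#' @param skull an [hu_volume()] or `NULL` for water
#' @param pset property set (name or object)
#' @param target a [sim_grid()] for the fused result
#' @param march a [march_spec()]
#' @param velocity_scale passed to the velocity map (sensitivity sweeps)
#' @param soft_hu_max soft-tissue HU threshold for property building
#' @return a `pressure_volume` on `target`; `meta` holds per-plate plane
#'   offsets, element counts and peak amplitudes
#' @export
simulate_sonication <- function(array, drive, skull = NULL, pset = "study",
                                target = grid_preset("desk"),
                                march = march_spec(), velocity_scale = 1,
                                soft_hu_max = 0) {
  stopifnot(inherits(array, "transducer_array"),
            inherits(drive, "drive_settings"))
  if (is.null(array$plate_id)) array <- partition_plates(array)
  lam <- wavelength_mm(array$frequency)
  sp <- march$spacing %||% c(lam / 3, lam / 3)
  du <- sp[1]; dz <- sp[length(sp)]
  nx <- march$shape[1]; ny <- march$shape[2]; nz <- march$shape[3]
  props <- NULL; bone_pos <- NULL
  if (!is.null(skull)) {
    props <- build_property_volumes(skull, pset, frequency = array$frequency,
                                    soft_hu_max = soft_hu_max,
                                    velocity_scale = velocity_scale)
    bidx <- which(skull$values > 300)
    if (length(bidx)) {
      ijk <- arrayInd(bidx, dim(skull$values))
      bone_pos <- sweep(ijk - 1, 2, skull$spacing, "*") %*%
        t(skull$orientation)
      bone_pos <- sweep(bone_pos, 2, skull$origin, "+")
    }
  }
  n_plates <- ncol(array$plate_axes)
  planes <- vector("list", n_plates)
  meta <- list(plate = vector("list", n_plates))
  for (p in seq_len(n_plates)) {
    ax <- array$plate_axes[, p]
    el <- which(array$plate_id == p)
    min_dot <- min(array$element_centers[el, , drop = FALSE] %*% ax)
    skull_top <- if (is.null(bone_pos)) -Inf else max(bone_pos %*% ax) + 2
    c0 <- max(skull_top, min(min_dot - 1, (nz - 1) * dz - march$focus_margin))
    n_ahead <- sum(array$element_centers[el, , drop = FALSE] %*% ax < c0)
    planes[[p]] <- project_source_plane(
      array, p, drive, plane_spec(c0, c(nx, ny), du),
      patch_pitch = march$patch_pitch)
    meta$plate[[p]] <- list(offset_mm = c0, n_elements = length(el),
                            n_ahead = n_ahead)
  }
  planes <- normalize_power(planes, drive$acoustic_power)
  acc <- array(0 + 0i, target$shape)
  for (p in seq_len(n_plates)) {
    pl <- planes[[p]]
    vel <- att <- NULL
    if (!is.null(props)) {
      pg <- list(origin = pl$origin, orientation = pl$axes,
                 spacing = c(pl$spacing, dz), shape = c(nx, ny, nz))
      A <- affine_index_map(geom_of(props), pg)
      vel <- resample_affine_cpp(props$velocity, A, nx, ny, nz,
                                 .const$water_velocity)
      att <- resample_affine_cpp(props$attenuation, A, nx, ny, nz, 0)
    }
    pv <- simulate_plate(pl, vel, att, nz = nz, dz = dz,
                         pad_frac = march$pad_frac,
                         mean_speed = march$mean_speed)
    meta$plate[[p]]$peak <- max(Mod(pv$pressure))
    A <- affine_index_map(geom_of(pv), target)
    acc <- acc + resample_complex_cpp(pv$pressure, A, target$shape[1],
                                      target$shape[2], target$shape[3])
  }
  pressure_volume(acc, spacing = target$spacing, origin = target$origin,
                  orientation = target$orientation,
                  frequency = array$frequency, meta = meta)
}

#' Peak-pressure location of a pressure volume
#' @param pvol a `pressure_volume`
#' @return list with `index` (1-based voxel triplet) and `world` (mm)
#' @export
peak_position <- function(pvol) {
  m <- Mod(pvol$pressure)
  idx <- arrayInd(which.max(m), dim(m))[1, ]
  list(index = idx, world = index_to_world(geom_of(pvol), idx))
}

#' Interpolated -6 dB focal extents along the grid axes
#'
#' Extracts the axis-aligned amplitude profiles through the peak voxel and
#' measures the width at half the peak amplitude (-6 dB in pressure) by
#' linear interpolation of the crossing points.
#'
#' @param pvol a `pressure_volume`
#' @param level fraction of the peak amplitude (0.5 = -6 dB)
#' @return named numeric `c(x, y, z)` widths in mm
#' @export
focal_extents <- function(pvol, level = 0.5) {
  m <- Mod(pvol$pressure)
  pk <- arrayInd(which.max(m), dim(m))[1, ]
  thr <- m[pk[1], pk[2], pk[3]] * level
  out <- numeric(3)
  for (a in 1:3) {
    prof <- switch(a, m[, pk[2], pk[3]], m[pk[1], , pk[3]], m[pk[1], pk[2], ])
    out[a] <- profile_width(prof, pk[a], thr) * pvol$spacing[a]
  }
  names(out) <- c("x", "y", "z")
  out
}

profile_width <- function(prof, i0, thr) {
  n <- length(prof)
  lo <- i0
  while (lo > 1 && prof[lo - 1] >= thr) lo <- lo - 1
  left <- if (lo == 1) lo else lo - (prof[lo] - thr) / (prof[lo] - prof[lo - 1])
  hi <- i0
  while (hi < n && prof[hi + 1] >= thr) hi <- hi + 1
  right <- if (hi == n) hi else hi + (prof[hi] - thr) / (prof[hi] - prof[hi + 1])
  right - left
}
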