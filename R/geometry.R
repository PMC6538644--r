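#' Regular 3D simulation grid
#'
#' A grid is a box of voxels placed in the transducer frame: the origin of the
#' frame is the geometric focus and +z points toward the transducer pole.
#' Voxel `(1,1,1)` has its centre at `origin`; voxel axes are the columns of
#' `orientation` (a proper rotation), scaled by `spacing`.
#'
#' @param shape integer length-3, voxel counts
#' @param spacing numeric length-3, voxel size in mm (recycled from length 1)
#' @param origin world position (mm) of the first voxel centre; default centres
#'   the grid on the world origin (the geometric focus)
#' @param orientation 3x3 rotation from voxel axes to world axes
#' @return object of class `sim_grid`
#' @export
sim_grid <- function(shape, spacing, origin = NULL, orientation = diag(3)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(all(is.finite(spacing)), all(spacing > 0))
  check_rotation(orientation)
  if (is.null(origin)) {
    origin <- as.numeric(-orientation %*% ((shape - 1) * spacing / 2))
  }
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin),
                 orientation = orientation),
            class = "sim_grid")
}

#' Named grid presets
#'
#' `"desk"` is the package default: a fusion grid resolving the focal region
#' at one third of the water wavelength. `"paper-grid"` is the full-resolution
#' clinical preset (1097 x 1097 x 1201 voxels at 0.365 x 0.365 x 0.200 mm);
#' it is a configuration option, not a test-scale grid.
#'
#' @param name one of `"desk"`, `"coarse"`, `"paper-grid"`
#' @param frequency Hz, used to derive wavelength-relative spacings
#' @return a `sim_grid`
#' @export
grid_preset <- function(name = c("desk", "coarse", "paper-grid"),
                        frequency = 680e3) {
  name <- match.arg(name)
  lam <- wavelength_mm(frequency)
  switch(name,
    "desk"   = sim_grid(c(96, 96, 96), lam / 3),
    "coarse" = sim_grid(c(64, 64, 64), lam / 2),
    "paper-grid" = sim_grid(c(1097, 1097, 1201), c(0.365, 0.365, 0.200))
  )
}

check_rotation <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0.99) {
    stop("orientation must be a proper rotation matrix")
  }
  invisible(R)
}

#' World coordinates of grid voxel centres along each axis
#' @param g a `sim_grid` (or any object with shape/spacing/origin/orientation)
#' @return list of three numeric vectors of per-axis offsets (mm); only
#'   meaningful directly for identity orientations
#' @keywords internal
grid_axis_coords <- function(g) {
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$shape[a]) - 1) * g$spacing[a])
}

#' Map world points (mm) to continuous 0-based voxel indices of a volume
#' @keywords internal
world_to_index0 <- function(geom, pts) {
  # pts: n x 3 world mm -> n x 3 continuous 0-based indices
  rel <- sweep(pts, 2, geom$origin) %*% geom$orientation
  sweep(rel, 2, geom$spacing, "/")
}

#' Index (1-based integer triplet) to world position
#' @keywords internal
index_to_world <- function(geom, idx) {
  as.numeric(geom$origin + geom$orientation %*% ((idx - 1) * geom$spacing))
}

# 3 x 4 affine mapping 0-based target voxel indices to 0-based source voxel
# indices, for the resampling kernels.
affine_index_map <- function(src_geom, tgt_geom) {
  Rs <- src_geom$orientation; Rt <- tgt_geom$orientation
  M <- diag(1 / src_geom$spacing) %*% t(Rs) %*% Rt %*% diag(tgt_geom$spacing)
  M0 <- diag(1 / src_geom$spacing) %*% t(Rs) %*%
    (tgt_geom$origin - src_geom$origin)
  cbind(M, M0)
}

geom_of <- function(x) {
  list(origin = x$origin, orientation = x$orientation, spacing = x$spacing,
       shape = if (!is.null(x$shape)) x$shape else dim(x$values))
}
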