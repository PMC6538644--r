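#' Acoustic property set
#'
#' A property set bundles the HU -> acoustic property curves and the constants
#' that pin them down. The default ("study") curves are: bone fraction
#' `clip(HU / hu_bone, 0, 1)`; velocity `c_water + (scale * c_max - c_water) *
#' bone_fraction` with `c_water` = 1500 m/s and `c_max` = 2800 m/s so that a
#' +-10 percent rescaling of the bone maximum gives 2520 and 3080 m/s at
#' 2000 HU; density `rho_water + (rho_bone - rho_water) * bone_fraction` with
#' `rho_bone` = 1920 kg/m3; and attenuation (Np/cm at the reference frequency)
#' `alpha_cortical + (alpha_plateau - alpha_cortical) * sqrt(porosity)` with
#' the trabecular plateau `alpha_plateau` = 2.136 Np/cm. Attenuation scales
#' linearly with frequency.
#'
#' The attenuation curve is the bone-material relationship over the whole HU
#' line (it reaches its trabecular plateau at the HU of maximal bone porosity,
#' i.e. HU <= 0, and is continuous). Assignment of the soft-tissue/water
#' baseline to non-bone voxels is the job of [build_property_volumes()],
#' which masks by HU, mirroring how masked HU->property curves are applied in
#' transcranial simulation practice.
#'
#' @param name identifier
#' @param velocity list with `c_water`, `c_max` (m/s)
#' @param attenuation list with `model` ("porosity" or "constant"),
#'   `alpha_plateau`, `alpha_cortical`, `alpha_soft`, and for the constant
#'   model `value` (all Np/cm at the reference frequency)
#' @param density list with `rho_water` (kg/m3)
#' @param constants list with `rho_bone` (kg/m3), `hu_bone` (HU),
#'   `alpha_plateau` (Np/cm), `reference_frequency` (Hz)
#' @return object of class `property_set`
#' @export
property_set <- function(name,
                         velocity = list(c_water = 1500, c_max = 2800),
                         attenuation = list(model = "porosity",
                                            alpha_plateau = 2.136,
                                            alpha_cortical = 0.9,
                                            alpha_soft = 0.04,
                                            value = NA_real_),
                         density = list(rho_water = 1000),
                         constants = list(rho_bone = 1920, hu_bone = 2000,
                                          alpha_plateau = attenuation$alpha_plateau,
                                          reference_frequency = 680e3)) {
  stopifnot(is.character(name), constants$hu_bone > 0,
            constants$alpha_plateau > 0 || attenuation$model == "constant",
            constants$reference_frequency > 0)
  structure(list(name = name, velocity = velocity, attenuation = attenuation,
                 density = density, constants = constants),
            class = "property_set")
}

#' Retrieve a named property set
#'
#' Builtins: `"study"` (this framework's curves, attenuation plateau
#' 2.136 Np/cm, rho_bone 1920 kg/m3, hu_bone 2000), `"vyas"` (the
#' hydroxyapatite-referenced alternative: plateau 3.625 Np/cm, rho_bone
#' 3000 kg/m3, hu_bone 3115), and `"constant:<value>"` giving a flat skull
#' attenuation of `<value>` Np/cm at 680 kHz with the study velocity/density
#' curves (used for attenuation sensitivity experiments).
#'
#' @param name builtin name, or a `property_set` (returned unchanged)
#' @return a `property_set`
#' @export
get_property_set <- function(name) {
  if (inherits(name, "property_set")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  if (name == "study") return(property_set("study"))
  if (name == "vyas") {
    return(property_set("vyas",
      attenuation = list(model = "porosity", alpha_plateau = 3.625,
                         alpha_cortical = 0.9, alpha_soft = 0.04,
                         value = NA_real_),
      constants = list(rho_bone = 3000, hu_bone = 3115,
                       alpha_plateau = 3.625, reference_frequency = 680e3)))
  }
  if (grepl("^constant:", name)) {
    val <- as.numeric(sub("^constant:", "", name))
    if (!is.finite(val) || val < 0) stop("bad constant attenuation value: ", name)
    ps <- property_set(name)
    ps$attenuation$model <- "constant"
    ps$attenuation$value <- val
    return(ps)
  }
  stop("unknown property set: ", name)
}

#' Read / write a property set as YAML
#' @param path YAML file
#' @return a `property_set` (read) or `path` invisibly (write)
#' @export
read_property_set <- function(path) {
  y <- yaml::read_yaml(path)
  property_set(y$name, velocity = y$velocity, attenuation = y$attenuation,
               density = y$density, constants = y$constants)
}

#' @rdname read_property_set
#' @param pset a `property_set`
#' @export
write_property_set <- function(pset, path) {
  yaml::write_yaml(unclass(pset), path)
  invisible(path)
}

check_hu <- function(hu) {
  if (!all(is.finite(hu))) stop("HU values must be finite")
  invisible(hu)
}

#' Bone fraction of a voxel from its HU
#'
#' Linear ramp from 0 at water (0 HU and below) to 1 at `hu_bone` (pure
#' cortical bone), clamped. Porosity is the complement, `1 - bone_fraction`.
#'
#' @param hu Hounsfield units (vectorised)
#' @param pset property set (name or object)
#' @return fraction in `[0, 1]`
#' @export
bone_fraction <- function(hu, pset = "study") {
  check_hu(hu)
  pset <- get_property_set(pset)
  pmin(pmax(hu / pset$constants$hu_bone, 0), 1)
}

#' Map HU to mass density
#'
#' Linear mixture between water density and `rho_bone` in bone fraction.
#'
#' @inheritParams bone_fraction
#' @return density in kg/m3
#' @export
map_density <- function(hu, pset = "study") {
  pset <- get_property_set(pset)
  bf <- bone_fraction(hu, pset)
  pset$density$rho_water + (pset$constants$rho_bone - pset$density$rho_water) * bf
}

#' Map HU to longitudinal acoustic velocity
#'
#' 1500 m/s at and below 0 HU, rising linearly in bone fraction to the bone
#' maximum, clamped at and above `hu_bone`. `scale` rescales only the bone
#' maximum (the water intercept is untouched), which is how the +-10 percent
#' velocity sensitivity curves are produced: at 2000 HU, `scale = 0.9` gives
#' 2520 m/s and `scale = 1.1` gives 3080 m/s.
#'
#' @inheritParams bone_fraction
#' @param scale multiplier applied to the maximum (bone) velocity
#' @return velocity in m/s
#' @export
map_velocity <- function(hu, pset = "study", scale = 1) {
  pset <- get_property_set(pset)
  stopifnot(is.finite(scale), scale > 0)
  bf <- bone_fraction(hu, pset)
  cw <- pset$velocity$c_water
  cw + (scale * pset$velocity$c_max - cw) * bf
}

#' Map HU to acoustic attenuation
#'
#' The bone-material attenuation curve: `alpha_cortical + (alpha_plateau -
#' alpha_cortical) * sqrt(porosity)` Np/cm at the set's reference frequency,
#' scaled linearly to `frequency`. The curve is continuous in HU and attains
#' the trabecular plateau at maximal bone porosity (HU <= 0). Constant-model
#' sets return their flat value. Soft-tissue masking happens in
#' [build_property_volumes()].
#'
#' @inheritParams bone_fraction
#' @param frequency Hz (> 0)
#' @return attenuation in Np/cm at `frequency`
#' @export
map_attenuation <- function(hu, frequency = 680e3, pset = "study") {
  check_hu(hu)
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be > 0")
  pset <- get_property_set(pset)
  fscale <- frequency / pset$constants$reference_frequency
  at <- pset$attenuation
  if (identical(at$model, "constant")) {
    return(rep_len(at$value * fscale, length(hu)))
  }
  porosity <- 1 - bone_fraction(hu, pset)
  (at$alpha_cortical + (at$alpha_plateau - at$alpha_cortical) * sqrt(porosity)) *
    fscale
}

#' Build co-registered acoustic property volumes from a CT volume
#'
#' Applies the velocity, attenuation and density maps voxelwise. Voxels at or
#' below `soft_hu_max` (default 0: water, brain filled to 0 HU, air) receive
#' water/soft-tissue values: water velocity and density, and the set's
#' soft-tissue attenuation scaled to `frequency`.
#'
#' @param vol an [hu_volume()]
#' @param pset property set (name or object)
#' @param frequency simulation frequency, Hz
#' @param soft_hu_max HU at or below which a voxel is treated as soft
#'   tissue/water
#' @param velocity_scale passed to [map_velocity()]
#' @return object of class `property_volumes` with fields `velocity` (m/s),
#'   `attenuation` (Np/cm at `frequency`), `density` (kg/m3) and the source
#'   geometry
#' @export
build_property_volumes <- function(vol, pset = "study", frequency = 680e3,
                                   soft_hu_max = 0, velocity_scale = 1) {
  stopifnot(inherits(vol, "hu_volume"))
  pset <- get_property_set(pset)
  hu <- vol$values
  soft <- hu <= soft_hu_max
  fscale <- frequency / pset$constants$reference_frequency
  vel <- map_velocity(hu, pset, scale = velocity_scale)
  att <- map_attenuation(hu, frequency, pset)
  den <- map_density(hu, pset)
  vel[soft] <- .const$water_velocity
  att[soft] <- pset$attenuation$alpha_soft * fscale
  den[soft] <- pset$density$rho_water
  dim(vel) <- dim(att) <- dim(den) <- dim(hu)
  structure(list(velocity = vel, attenuation = att, density = den,
                 spacing = vol$spacing, origin = vol$origin,
                 orientation = vol$orientation, frequency = frequency,
                 pset_name = pset$name),
            class = "property_volumes")
}

#' Uniform soft-tissue property volumes on a grid
#'
#' Water velocity and density with the property set's soft-tissue attenuation
#' everywhere; used for water-bath/tissue-only runs where no CT volume is
#' involved.
#'
#' @param grid a [sim_grid()]
#' @param pset property set (name or object)
#' @param frequency Hz
#' @return a `property_volumes`
#' @export
uniform_soft_properties <- function(grid, pset = "study", frequency = 680e3) {
  pset <- get_property_set(pset)
  fscale <- frequency / pset$constants$reference_frequency
  d <- grid$shape
  structure(list(
    velocity = array(.const$water_velocity, d),
    attenuation = array(pset$attenuation$alpha_soft * fscale, d),
    density = array(.const$water_density, d),
    spacing = grid$spacing, origin = grid$origin,
    orientation = grid$orientation, frequency = frequency,
    pset_name = pset$name),
    class = "property_volumes")
}

#' Skull density ratio (SDR)
#'
#' For every transducer element, HU is sampled at `step_mm` intervals along
#' the segment from the element to the focus; samples above `bone_threshold`
#' are taken as skull, and the line's ratio is min(HU)/max(HU) over those
#' samples. The SDR is the mean ratio over elements. Low SDR indicates a
#' heterogeneous skull. Lines that intersect no skull voxels are skipped with
#' a warning; if every line is skipped an error is raised.
#'
#' Sampling is nearest-neighbour by default: sub-voxel linear interpolation
#' sweeps through all intermediate values at the skull surface, so the
#' partial-volume samples just above the bone threshold would dominate every
#' line's minimum and a perfectly homogeneous skull would no longer score an
#' SDR of 1.
#'
#' @param vol an [hu_volume()]
#' @param element_positions N x 3 matrix of element centres (mm, world frame)
#' @param focus length-3 target point (mm)
#' @param bone_threshold HU above which a sample counts as skull
#' @param step_mm sampling step along each line
#' @param interp `"nearest"` (default) or `"trilinear"` sampling
#' @return SDR in `(0, 1]`
#' @export
skull_density_ratio <- function(vol, element_positions, focus = c(0, 0, 0),
                                bone_threshold = 300, step_mm = 0.25,
                                interp = c("nearest", "trilinear")) {
  stopifnot(inherits(vol, "hu_volume"))
  interp <- match.arg(interp)
  element_positions <- rbind(element_positions)
  n <- nrow(element_positions)
  stopifnot(n >= 1)
  d3 <- dim(vol$values)
  ratios <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p0 <- element_positions[i, ]
    d <- focus - p0
    len <- sqrt(sum(d^2))
    ts <- seq(0, 1, by = step_mm / len)
    pts <- outer(ts, d) + matrix(p0, length(ts), 3, byrow = TRUE)
    idx0 <- world_to_index0(geom_of(vol), pts)
    if (interp == "trilinear") {
      hu <- sample_trilinear_cpp(vol$values, idx0, fill_value = -1000)
    } else {
      ir <- round(idx0) + 1
      ok <- ir[, 1] >= 1 & ir[, 1] <= d3[1] & ir[, 2] >= 1 &
        ir[, 2] <= d3[2] & ir[, 3] >= 1 & ir[, 3] <= d3[3]
      hu <- rep(-1000, nrow(ir))
      hu[ok] <- vol$values[ir[ok, , drop = FALSE]]
    }
    skull <- hu > bone_threshold
    if (any(skull)) ratios[i] <- min(hu[skull]) / max(hu[skull])
  }
  if (all(is.na(ratios))) stop("no element-focus line intersects skull voxels")
  if (anyNA(ratios)) {
    warning(sum(is.na(ratios)), " element line(s) intersect no skull voxels; skipped")
  }
  mean(ratios, na.rm = TRUE)
}
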