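#' Thermal tissue properties for the Pennes bioheat equation
#'
#' Defaults are brain values in common use: conductivity 0.51 W/m/degC,
#' specific heat 3600 J/kg/degC, perfusion 559 ml/kg/min, blood density
#' 1050 kg/m3, blood specific heat 3617 J/kg/degC, arterial temperature
#' 37 degC, tissue density 1000 kg/m3. Perfusion is stored in ml/kg/min and
#' converted to SI (m3/kg/s, factor 1e-6/60) inside the solver. Conductivity
#' and perfusion may be zero, which switches the corresponding term off (used
#' by the analytic solver checks).
#'
#' @param conductivity kappa, W/m/degC (>= 0)
#' @param specific_heat C, J/kg/degC
#' @param perfusion omega, ml/kg/min (>= 0)
#' @param blood_density rho_b, kg/m3
#' @param blood_specific_heat C_b, J/kg/degC
#' @param blood_temperature T_b, degC
#' @param density tissue density rho, kg/m3
#' @return object of class `thermal_properties`
#' @export
thermal_properties <- function(conductivity = 0.51, specific_heat = 3600,
                               perfusion = 559, blood_density = 1050,
                               blood_specific_heat = 3617,
                               blood_temperature = 37, density = 1000) {
  stopifnot(conductivity >= 0, specific_heat > 0, perfusion >= 0,
            blood_density > 0, blood_specific_heat > 0, density > 0)
  structure(list(conductivity = conductivity, specific_heat = specific_heat,
                 perfusion = perfusion, blood_density = blood_density,
                 blood_specific_heat = blood_specific_heat,
                 blood_temperature = blood_temperature, density = density),
            class = "thermal_properties")
}

perfusion_si <- function(thermal) thermal$perfusion * 1e-6 / 60

# rho_b * C_b * rho * omega, W/m3/K
perfusion_coeff <- function(thermal) {
  thermal$blood_density * thermal$blood_specific_heat * thermal$density *
    perfusion_si(thermal)
}

#' Acoustic heating rate from a steady-state pressure field
#'
#' The bioheat source term: `Q = alpha |p|^2 / (rho c)` voxelwise, with the
#' attenuation converted from Np/cm to Np/m. The property volumes are
#' resampled onto the pressure grid if their geometry differs (water fill
#' outside coverage).
#'
#' @param pressure a `pressure_volume` (Pa, peak amplitude convention)
#' @param props a `property_volumes`, or `NULL` for plain water (zero
#'   absorption, hence zero heating)
#' @return list with `Q` (3D array, W/m3) and the pressure grid geometry
#' @export
heating_rate <- function(pressure, props = NULL) {
  stopifnot(inherits(pressure, "pressure_volume"))
  p2 <- Mod(pressure$pressure)^2
  g <- geom_of2(pressure)
  if (is.null(props)) {
    Q <- array(0, dim(p2))
  } else {
    same <- all(dim(props$velocity) == dim(p2)) &&
      isTRUE(all.equal(props$spacing, pressure$spacing)) &&
      isTRUE(all.equal(props$origin, pressure$origin)) &&
      isTRUE(all.equal(props$orientation, pressure$orientation))
    if (same) {
      vel <- props$velocity; att <- props$attenuation; den <- props$density
    } else {
      A <- affine_index_map(geom_of(props), g)
      d <- dim(p2)
      vel <- resample_affine_cpp(props$velocity, A, d[1], d[2], d[3],
                                 .const$water_velocity)
      att <- resample_affine_cpp(props$attenuation, A, d[1], d[2], d[3], 0)
      den <- resample_affine_cpp(props$density, A, d[1], d[2], d[3],
                                 .const$water_density)
    }
    Q <- (att * 100) * p2 / (den * vel)   # Np/cm -> Np/m
  }
  list(Q = Q, spacing = g$spacing, origin = g$origin,
       orientation = g$orientation)
}

geom_of2 <- function(x) {
  list(origin = x$origin, orientation = x$orientation, spacing = x$spacing,
       shape = dim(x$pressure))
}

#' Explicit stability bound for the bioheat FDTD step
#'
#' `dt <= 0.9 * (rho C / kappa) / (2 * sum(1 / dx_i^2))`. Infinite when
#' conductivity is zero.
#'
#' @param thermal a [thermal_properties()]
#' @param spacing_mm voxel size, mm (length 3 or scalar)
#' @return maximum stable `dt` in seconds
#' @export
bioheat_stability_dt <- function(thermal, spacing_mm) {
  dx <- rep_len(spacing_mm, 3) * 1e-3
  if (thermal$conductivity == 0) return(Inf)
  0.9 * (thermal$density * thermal$specific_heat / thermal$conductivity) /
    (2 * sum(1 / dx^2))
}

#' One explicit FDTD step of the Pennes bioheat equation
#'
#' Updates the temperature-rise grid `dT = T - T_b` by
#' `rho C dT/dt = kappa lap(dT) - rho_b C_b rho omega dT + Q`
#' with a 7-point Laplacian and Dirichlet `dT = 0` on the grid faces. `dt`
#' above the explicit stability bound is rejected with the computed bound.
#'
#' @param T 3D temperature-rise array, degC
#' @param Q 3D heating array, W/m3 (same shape)
#' @param thermal a [thermal_properties()]
#' @param dt time step, s
#' @param spacing_mm voxel size, mm
#' @return the updated temperature-rise array
#' @export
step_temperature <- function(T, Q, thermal, dt, spacing_mm) {
  stopifnot(all(dim(T) == dim(Q)), dt > 0)
  bound <- bioheat_stability_dt(thermal, spacing_mm)
  if (dt > bound) {
    stop("dt = ", dt, " s exceeds the explicit stability bound ",
         signif(bound, 4), " s")
  }
  dx <- rep_len(spacing_mm, 3) * 1e-3
  rhoC <- thermal$density * thermal$specific_heat
  lap <- array(0, dim(T))
  d <- dim(T)
  if (all(d >= 3)) {
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    t0 <- T[i, j, k]
    lap[i, j, k] <-
      (T[i + 1, j, k] - 2 * t0 + T[i - 1, j, k]) / dx[1]^2 +
      (T[i, j + 1, k] - 2 * t0 + T[i, j - 1, k]) / dx[2]^2 +
      (T[i, j, k + 1] - 2 * t0 + T[i, j, k - 1]) / dx[3]^2
  }
  Tn <- T + dt / rhoC *
    (thermal$conductivity * lap - perfusion_coeff(thermal) * T + Q)
  # Dirichlet faces
  Tn[c(1, d[1]), , ] <- 0; Tn[, c(1, d[2]), ] <- 0; Tn[, , c(1, d[3])] <- 0
  Tn
}

#' Heating/imaging protocol for the bioheat solve
#'
#' By default three MR thermometry frames at a 3.5 s frame period, with the
#' first acquisition starting together with the ultrasound, are represented
#' by their frame-centre times 1.75, 5.25 and 8.75 s; the ultrasound stays on
#' for 10 s so the third frame is the latest acquired with ultrasound on.
#'
#' @param on_duration ultrasound-on time, s
#' @param timepoint_times MR frame-centre times, s (sorted)
#' @param dt solver step, s, or `NULL` to use half the stability bound
#' @param cool_down extra integration time after the last event, s
#' @return a `heating_protocol` list
#' @export
heating_protocol <- function(on_duration = 10,
                             timepoint_times = c(1.75, 5.25, 8.75),
                             dt = NULL, cool_down = 0) {
  stopifnot(on_duration > 0, !is.unsorted(timepoint_times),
            is.null(dt) || dt > 0, cool_down >= 0)
  structure(list(on_duration = on_duration,
                 timepoint_times = timepoint_times, dt = dt,
                 cool_down = cool_down),
            class = "heating_protocol")
}

#' Integrate the bioheat equation for one sonication
#'
#' Converts the pressure volume to a heating rate, crops a subgrid around the
#' focus (heating is negligible elsewhere), and integrates the Pennes
#' equation with the compiled explicit stepper. Frames are sampled at the
#' protocol's timepoints by nearest solver step.
#'
#' @param pressure a `pressure_volume`
#' @param props a `property_volumes` or `NULL` (water: zero heating)
#' @param thermal a [thermal_properties()]
#' @param protocol a [heating_protocol()]
#' @param margin_mm half-size of the cropped box around `center`
#' @param center crop centre, mm world (default the focus)
#' @return object of class `temperature_series`: `times`, `peak_curve`
#'   (max temperature rise per step), `frames` (3D arrays on the cropped
#'   grid), `frame_times`, and the cropped geometry
#' @export
simulate_temperature <- function(pressure, props = NULL,
                                 thermal = thermal_properties(),
                                 protocol = heating_protocol(),
                                 margin_mm = 40, center = c(0, 0, 0)) {
  hr <- heating_rate(pressure, props)
  d <- dim(hr$Q)
  ctr_idx <- world_to_index0(list(origin = hr$origin,
                                  orientation = hr$orientation,
                                  spacing = hr$spacing),
                             rbind(center))[1, ] + 1
  half <- margin_mm / hr$spacing
  lo <- pmax(1, floor(ctr_idx - half)); hi <- pmin(d, ceiling(ctr_idx + half))
  Q <- hr$Q[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- as.numeric(hr$origin + hr$orientation %*% ((lo - 1) * hr$spacing))
  bound <- bioheat_stability_dt(thermal, hr$spacing)
  dt <- protocol$dt %||% (if (is.finite(bound)) bound / 2 else 0.1)
  if (dt > bound) {
    stop("protocol dt = ", dt, " s exceeds the stability bound ",
         signif(bound, 4), " s")
  }
  t_end <- max(protocol$timepoint_times, protocol$on_duration) +
    protocol$cool_down
  n_total <- ceiling(t_end / dt)
  n_on <- round(protocol$on_duration / dt)
  frame_steps <- pmin(n_total, round(protocol$timepoint_times / dt))
  res <- bioheat_run_cpp(Q, thermal$density * thermal$specific_heat,
                         thermal$conductivity, perfusion_coeff(thermal),
                         hr$spacing * 1e-3, dt, n_on, n_total,
                         as.integer(frame_steps))
  structure(list(times = (0:n_total) * dt, peak_curve = res$peak,
                 frames = res$frames,
                 frame_times = frame_steps * dt,
                 timepoint_times = protocol$timepoint_times,
                 spacing = hr$spacing, origin = origin,
                 orientation = hr$orientation, dt = dt,
                 protocol = protocol),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("<temperature_series> ", length(x$frames), " frames at t = ",
      paste(signif(x$frame_times, 4), collapse = ", "),
      " s; peak rise ", signif(max(x$peak_curve), 4), " degC\n", sep = "")
  invisible(x)
}

#' Sensitivity of peak temperature rise to thermal parameters
#'
#' Reruns the bioheat solve over a grid of values of one or more thermal
#' parameters (e.g. brain conductivity 0.49-0.54 W/m/degC, perfusion
#' 412-976 ml/kg/min) and reports the peak temperature rise at the requested
#' timepoint. Deterministic.
#'
#' @param pressure,props,thermal,protocol as in [simulate_temperature()]
#' @param ranges named list of numeric vectors; names must be
#'   `thermal_properties` fields (`conductivity`, `perfusion`, ...)
#' @param timepoint index into the protocol's timepoints at which the peak is
#'   read (default 3, the latest frame with ultrasound on)
#' @param margin_mm crop half-size, mm
#' @return data.frame with columns `parameter`, `value`, `peak_dT`
#' @export
sensitivity_sweep <- function(pressure, props, ranges,
                              thermal = thermal_properties(),
                              protocol = heating_protocol(),
                              timepoint = 3, margin_mm = 40) {
  stopifnot(length(ranges) >= 1, all(lengths(ranges) >= 1),
            all(names(ranges) %in% names(thermal)))
  rows <- list()
  for (par in names(ranges)) {
    for (val in ranges[[par]]) {
      th <- thermal
      th[[par]] <- val
      ts <- simulate_temperature(pressure, props, th, protocol,
                                 margin_mm = margin_mm)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, value = val,
        peak_dT = max(ts$frames[[timepoint]]))
    }
  }
  do.call(rbind, rows)
}
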