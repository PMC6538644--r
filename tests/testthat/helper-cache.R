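# Shared fixtures. Full-scale simulations are expensive, so they are built
# once per test session and reused across files.
.fus_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fus_cache)) {
    assign(key, expr, envir = .fus_cache)
  }
  get(key, envir = .fus_cache)
}

full_array <- function() {
  cached("full_array", partition_plates(build_array()))
}

focus_drive <- function(arr, power = 650, target = c(0, 0, 0)) {
  drive_settings(steering_phases(arr, target), 1, power = power,
                 duration = 10, n_elements = arr$n_elements)
}

ref_skull <- function() {
  cached("ref_skull", make_skull_phantom(reference_phantom()))
}

window_skull <- function() {
  cached("window_skull",
         make_skull_phantom(reference_phantom(temporal_window = TRUE)))
}

# Reference-phantom sonication with the study property set, 650 W
ref_sim <- function() {
  cached("ref_sim", {
    arr <- full_array()
    simulate_sonication(arr, focus_drive(arr), ref_skull(), "study")
  })
}

ref_props <- function() {
  cached("ref_props",
         build_property_volumes(ref_skull(), "study", frequency = 680e3))
}

# Small transducer + coarse march used by the pipeline tests: full physics,
# reduced aperture so the patch count stays low
small_run_config <- function(log, ...) {
  run_config(log,
             target = "coarse",
             march = march_spec(shape = c(96, 96, 128), spacing = c(1.1, 1.1)),
             array_args = list(n_elements = 256, aperture = 220),
             bioheat_margin_mm = 20, ...)
}

# A compact focused source plane in water for solver-level tests
focused_plane <- function(n = 64, spacing = 1.1, focal_mm = 60,
                          frequency = 680e3) {
  lam <- 1500 / frequency * 1000
  k <- 2 * pi / lam
  u <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(u^2, u^2, `+`)
  apod <- exp(-(sqrt(r2) / (0.4 * n * spacing / 2))^8)
  p0 <- apod * exp(-1i * k * (sqrt(r2 + focal_mm^2) - focal_mm))
  structure(list(pressure = p0, origin = c(u[1], u[1], 0), axes = diag(3),
                 spacing = c(spacing, spacing), frequency = frequency,
                 plate = 1L, offset_mm = 0),
            class = "source_plane")
}

uniform_plane <- function(value, n = 32, spacing = 1, frequency = 680e3) {
  structure(list(pressure = matrix(value, n, n), origin = c(0, 0, 0),
                 axes = diag(3), spacing = c(spacing, spacing),
                 frequency = frequency, plate = 1L, offset_mm = 0),
            class = "source_plane")
}
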