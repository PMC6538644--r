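#' Read / write a sonication log CSV
#'
#' A documented plain-CSV stand-in for proprietary treatment logs: one row
#' per sonication with columns `index`, `power` (W), `duration` (s),
#' `target_x`, `target_y`, `target_z` (mm, steering target in the transducer
#' frame), `is_alignment`, `phase_encode`, and optionally `peak_dT_tp3`
#' (degC, for measured logs).
#'
#' @param path CSV file
#' @return data.frame (read) or `path` invisibly (write)
#' @export
read_sonication_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("index", "power", "duration") %in% names(log)))
  log
}

#' @rdname read_sonication_log
#' @param log data.frame
#' @export
write_sonication_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything a reproducible simulate -> bioheat -> analyze run
#' needs. All references are plain values or names resolvable by the
#' package; the seed is recorded in the output provenance.
#'
#' @param sonications data.frame (see [read_sonication_log()]) or a CSV path;
#'   missing `target_*` columns default to the geometric focus
#' @param phantom `"none"` (water bath), `"reference"`,
#'   `"reference-window"`, or a [phantom_spec()]
#' @param pset property set name or object
#' @param target a [sim_grid()] or preset name
#' @param march a [march_spec()]
#' @param thermal a [thermal_properties()]
#' @param protocol a [heating_protocol()]
#' @param slab a [slab_spec()] or `NULL` to derive one centred on the focus
#' @param array_args list of overrides for [build_array()]
#' @param bioheat_margin_mm crop half-size for the bioheat solve
#' @param seed integer master seed
#' @param out_dir output directory or `NULL` (no files written)
#' @return a `run_config` list
#' @export
run_config <- function(sonications, phantom = "none", pset = "study",
                       target = "desk", march = march_spec(),
                       thermal = thermal_properties(),
                       protocol = heating_protocol(), slab = NULL,
                       array_args = list(), bioheat_margin_mm = 25,
                       seed = 1L, out_dir = NULL) {
  if (is.character(sonications)) sonications <- read_sonication_log(sonications)
  stopifnot(is.data.frame(sonications), nrow(sonications) >= 1)
  for (col in c("target_x", "target_y", "target_z")) {
    if (is.null(sonications[[col]])) sonications[[col]] <- 0
  }
  if (is.null(sonications$is_alignment)) sonications$is_alignment <- FALSE
  if (is.null(sonications$phase_encode)) sonications$phase_encode <- "RL"
  if (is.character(target)) target <- grid_preset(target)
  structure(list(sonications = sonications, phantom = phantom, pset = pset,
                 target = target, march = march, thermal = thermal,
                 protocol = protocol, slab = slab, array_args = array_args,
                 bioheat_margin_mm = bioheat_margin_mm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_phantom <- function(phantom, seed) {
  if (inherits(phantom, "phantom_spec")) return(make_skull_phantom(phantom))
  if (inherits(phantom, "hu_volume")) return(phantom)
  switch(phantom,
    "none" = NULL,
    "reference" = make_skull_phantom(reference_phantom(seed = seed)),
    "reference-window" = make_skull_phantom(
      reference_phantom(temporal_window = TRUE, seed = seed)),
    stop("unknown phantom: ", phantom))
}

default_slab <- function(grid, n_through = 3) {
  # axial-plane slab through the focus: frequency encode along x (factor 2),
  # phase encode along y (factor 4), n_through slices through plane
  f <- c(2L, 4L, as.integer(n_through))
  img <- c(grid$shape[1] %/% f[1], grid$shape[2] %/% f[2])
  focus_k <- round(world_to_index0(grid, rbind(c(0, 0, 0)))[1, 3]) + 1
  start <- c(1L, 1L, as.integer(focus_k - n_through %/% 2))
  sp <- slab_spec(start, img, f)
  attr(sp, "pixel_size") <- c(f[1] * grid$spacing[1], f[2] * grid$spacing[2])
  sp
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each sonication in the log: simulate the steady-state pressure field
#' (per unique steering target; pressure scales with the square root of
#' power, so one 1 W solve per target is rescaled per sonication), integrate
#' the bioheat equation, extract the thermometry-matched image at each
#' timepoint, and compute the focal-spot metrics (position at timepoint 3,
#' peak temperature rises at timepoints 1-3 read at that position, treatment
#' efficiency). Writes `metrics.csv`, `summary.json` and `config.yaml`
#' (including the seed) to `out_dir` when given; a rerun with the same
#' configuration is bit-identical.
#'
#' @param config a [run_config()]
#' @return a `run_result`: `metrics` data.frame, `images` (per sonication,
#'   per timepoint), `slab` spec used, `config`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  son <- config$sonications
  skull <- resolve_phantom(config$phantom, config$seed)
  arr <- do.call(build_array, modifyList(list(seed = config$seed),
                                         config$array_args))
  arr <- partition_plates(arr)
  slab <- config$slab %||% default_slab(config$target)
  pix <- attr(slab, "pixel_size") %||% c(1.094, 2.188)
  props <- if (!is.null(skull)) {
    build_property_volumes(skull, config$pset, frequency = arr$frequency)
  } else {
    # water-bath runs: acoustically water, but the focal medium absorbs like
    # soft tissue so temperature metrics remain defined
    uniform_soft_properties(config$target, config$pset, arr$frequency)
  }
  targets <- unique(son[, c("target_x", "target_y", "target_z")])
  pressures <- vector("list", nrow(targets))
  for (ti in seq_len(nrow(targets))) {
    tgt <- as.numeric(targets[ti, ])
    drv <- drive_settings(steering_phases(arr, tgt), 1, power = 1,
                          duration = 10, n_elements = arr$n_elements)
    pressures[[ti]] <- simulate_sonication(arr, drv, skull, config$pset,
                                           target = config$target,
                                           march = config$march)
  }
  metrics <- list(); images <- list()
  for (si in seq_len(nrow(son))) {
    s <- son[si, ]
    ti <- which(targets$target_x == s$target_x &
                targets$target_y == s$target_y &
                targets$target_z == s$target_z)[1]
    pv <- pressures[[ti]]
    pv$pressure <- pv$pressure * sqrt(s$power)   # acoustic linearity
    proto <- config$protocol
    proto$on_duration <- min(proto$on_duration, s$duration)
    ts <- simulate_temperature(pv, props, config$thermal, proto,
                               margin_mm = config$bioheat_margin_mm)
    imgs <- lapply(ts$frames, function(fr) {
      vol <- embed_frame(fr, ts, config$target)
      extract_thermometry_slab(vol, slab)
    })
    pos <- focal_spot_position(imgs[[length(imgs)]])
    peaks <- vapply(imgs, function(im) im[pos[1], pos[2]], numeric(1))
    metrics[[si]] <- data.frame(
      index = s$index, power = s$power,
      pos_row = pos[1], pos_col = pos[2],
      peak_dT_tp1 = peaks[1],
      peak_dT_tp2 = if (length(peaks) >= 2) peaks[2] else NA_real_,
      peak_dT_tp3 = if (length(peaks) >= 3) peaks[3] else peaks[length(peaks)],
      is_alignment = s$is_alignment, phase_encode = s$phase_encode)
    images[[si]] <- imgs
  }
  metrics <- do.call(rbind, metrics)
  metrics$tr_eff <- treatment_efficiency(metrics$peak_dT_tp3, metrics$power)
  out <- structure(list(metrics = metrics, images = images, slab = slab,
                        pixel_size = pix, config = config),
                   class = "run_result")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

# Place a cropped bioheat frame back onto the full target grid (zeros
# outside) so slab extraction sees the full field of view.
embed_frame <- function(frame, ts, grid) {
  vol <- array(0, grid$shape)
  i0 <- round(world_to_index0(grid, rbind(ts$origin))[1, ]) + 1
  d <- dim(frame)
  vol[i0[1]:(i0[1] + d[1] - 1), i0[2]:(i0[2] + d[2] - 1),
      i0[3]:(i0[3] + d[3] - 1)] <- frame
  vol
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  summary <- list(
    n_sonications = nrow(run$metrics),
    seed = run$config$seed,
    pset = if (is.character(run$config$pset)) run$config$pset else
      run$config$pset$name,
    phantom = if (is.character(run$config$phantom)) run$config$phantom else
      "custom",
    metrics = run$metrics)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  yaml::write_yaml(list(seed = cfg$seed,
                        phantom = if (is.character(cfg$phantom)) cfg$phantom
                                  else "custom",
                        pset = if (is.character(cfg$pset)) cfg$pset
                               else cfg$pset$name,
                        grid_shape = cfg$target$shape,
                        grid_spacing = cfg$target$spacing,
                        march_shape = cfg$march$shape,
                        sonications = cfg$sonications),
                   file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Compare a simulated run with measured (or reference) metrics
#'
#' Matches sonications by index (the index vectors must be identical),
#' reports per-sonication position errors in the frequency and phase encode
#' directions, fits the robust calibration regression of measured on
#' simulated peak temperature rise (timepoints 1-3 pooled), and, when a
#' noise SD is supplied, the sonication selection report.
#'
#' @param run_sim a `run_result`, or its `metrics` data.frame
#' @param run_meas a `run_result` or a metrics data.frame with columns
#'   `index`, `pos_row`, `pos_col`, `peak_dT_tp1..3`, `power`
#' @param pixel_size mm per pixel `c(freq, phase)` for position errors
#' @param noise_sd optional degC; enables the selection report
#' @return list with `position_errors` (data.frame), `regression`
#'   ([robust_regression()] result), and `selection` (or `NULL`)
#' @export
compare_runs <- function(run_sim, run_meas, pixel_size = NULL,
                         noise_sd = NULL) {
  ms <- if (inherits(run_sim, "run_result")) run_sim$metrics else run_sim
  mm <- if (inherits(run_meas, "run_result")) run_meas$metrics else run_meas
  pixel_size <- pixel_size %||%
    (if (inherits(run_sim, "run_result")) run_sim$pixel_size else c(1.094, 2.188))
  if (!identical(as.integer(ms$index), as.integer(mm$index))) {
    stop("sonication index mismatch between runs")
  }
  pe <- t(vapply(seq_len(nrow(ms)), function(i) {
    position_error(c(ms$pos_row[i], ms$pos_col[i]),
                   c(mm$pos_row[i], mm$pos_col[i]), pixel_size)
  }, numeric(2)))
  position_errors <- data.frame(index = ms$index, freq_err = pe[, 1],
                                phase_err = pe[, 2])
  tp_cols <- intersect(c("peak_dT_tp1", "peak_dT_tp2", "peak_dT_tp3"),
                       intersect(names(ms), names(mm)))
  x <- unlist(ms[tp_cols]); y <- unlist(mm[tp_cols])
  keep <- is.finite(x) & is.finite(y)
  regression <- robust_regression(x[keep], y[keep])
  selection <- NULL
  if (!is.null(noise_sd)) {
    tre <- effective_treatment_efficiency(mm)
    selection <- select_sonications(mm, tre, noise_sd)
  }
  list(position_errors = position_errors, regression = regression,
       selection = selection)
}
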