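#' Block-average a 3D array
#'
#' Non-overlapping block means with integer factors per axis; the array
#' extent must be a multiple of each factor. Building block of the
#' thermometry-matched downsampling.
#'
#' @param a 3D array
#' @param factors integer length-3 block size per axis
#' @return the block-averaged array
#' @export
block_average <- function(a, factors) {
  d <- dim(a); f <- as.integer(factors)
  stopifnot(length(d) == 3, length(f) == 3, all(d %% f == 0))
  dim(a) <- c(f[1], d[1] %/% f[1], f[2], d[2] %/% f[2], f[3], d[3] %/% f[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}

#' Thermometry-matched slab extraction settings
#'
#' The clinical recipe extracts a 768 x 768 x 15 voxel slab from the
#' simulated volume, block-averages 3x along frequency encode, 6x along phase
#' encode and 15x through plane to a 256 x 128 image, then upsamples the
#' phase axis by 2 to 256 x 256 (the underlying resolution is unchanged).
#' The factors are configurable so desk-scale grids can use the same
#' operation.
#'
#' @param start 1-based voxel index `c(i, j, k)` of the slab corner
#' @param image_shape output image size before upsampling `c(n_freq, n_phase)`
#' @param factors block factors `c(freq, phase, through)`
#' @param upsample `"nearest"` or `"linear"` phase-axis upsampling by 2
#' @return a `slab_spec` list
#' @export
slab_spec <- function(start, image_shape, factors = c(3, 6, 15),
                      upsample = c("nearest", "linear")) {
  structure(list(start = as.integer(start),
                 image_shape = as.integer(image_shape),
                 factors = as.integer(factors),
                 upsample = match.arg(upsample)),
            class = "slab_spec")
}

#' Extract a thermometry-matched 2D image from a simulated volume
#'
#' Block-averages the specified slab (frequency, phase, through-plane
#' factors) and upsamples the phase axis by 2. Constant volumes map to
#' constant images; the operation commutes with scaling.
#'
#' @param volume 3D array (temperature rise or any scalar field)
#' @param spec a [slab_spec()]
#' @return 2D image of size `image_shape * c(1, 2)`; the pre-upsampling
#'   image is in attribute `"native"`
#' @export
extract_thermometry_slab <- function(volume, spec) {
  stopifnot(is.array(volume), length(dim(volume)) == 3,
            inherits(spec, "slab_spec"))
  f <- spec$factors
  n <- c(spec$image_shape, 1) * f
  s <- spec$start
  if (any(s < 1) || any(s + n - 1 > dim(volume))) {
    stop("slab exceeds volume bounds")
  }
  slab <- volume[s[1]:(s[1] + n[1] - 1), s[2]:(s[2] + n[2] - 1),
                 s[3]:(s[3] + n[3] - 1), drop = FALSE]
  native <- block_average(slab, f)[, , 1]
  img <- upsample_phase(native, spec$upsample)
  attr(img, "native") <- native
  img
}

upsample_phase <- function(img, method) {
  np <- ncol(img)
  out <- matrix(0, nrow(img), 2 * np)
  if (method == "nearest") {
    out[, seq(1, 2 * np, 2)] <- img
    out[, seq(2, 2 * np, 2)] <- img
  } else {
    # linear: place native samples on odd columns, interpolate evens
    out[, seq(1, 2 * np, 2)] <- img
    mids <- (img[, -np, drop = FALSE] + img[, -1, drop = FALSE]) / 2
    out[, seq(2, 2 * (np - 1), 2)] <- mids
    out[, 2 * np] <- img[, np]
  }
  out
}

#' Focal spot position: hottest pixel
#'
#' Argmax of the image; exact ties break to the lowest row-major index
#' (row-by-row scan order).
#'
#' @param frame 2D image (temperature rise at timepoint 3)
#' @return integer `c(row, col)` of the peak pixel
#' @export
focal_spot_position <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) >= 1)
  if (all(is.na(frame))) stop("all-NaN frame")
  m <- max(frame, na.rm = TRUE)
  cand <- which(frame == m, arr.ind = TRUE)
  rm_idx <- (cand[, 1] - 1) * ncol(frame) + cand[, 2]   # row-major
  as.integer(cand[which.min(rm_idx), ])
}

#' Per-axis focal position error
#'
#' Absolute pixel offset times pixel size, reported separately along the
#' frequency and phase encode axes (default clinical pixel sizes 1.094 and
#' 2.188 mm).
#'
#' @param pos_a,pos_b integer pixel positions `c(row, col)`
#' @param pixel_size mm per pixel, `c(freq, phase)`
#' @param encode_axes which image axis is which encode: `c(freq = 1, phase = 2)`
#' @return named numeric `c(freq, phase)` in mm
#' @export
position_error <- function(pos_a, pos_b, pixel_size = c(1.094, 2.188),
                           encode_axes = c(freq = 1, phase = 2)) {
  d <- abs(pos_a - pos_b)
  c(freq = d[encode_axes["freq"]] * pixel_size[1],
    phase = d[encode_axes["phase"]] * pixel_size[2])
}

#' Treatment efficiency (TrEff)
#'
#' Peak focal temperature rise at the third thermometry timepoint divided by
#' the applied acoustic power.
#'
#' @param peak_dT_tp3 degC
#' @param power W (> 0)
#' @return degC/W
#' @export
treatment_efficiency <- function(peak_dT_tp3, power) {
  if (any(!is.finite(power)) || any(power <= 0)) stop("power must be > 0")
  peak_dT_tp3 / power
}

#' Effective treatment efficiency of a treatment
#'
#' Mean of the two largest per-sonication treatment efficiencies, computed
#' without alignment sonications (the early focal-spot-finding shots).
#'
#' @param records sonication table (data.frame) with columns `peak_dT_tp3`,
#'   `power`, `is_alignment`
#' @return degC/W
#' @export
effective_treatment_efficiency <- function(records) {
  el <- records[!records$is_alignment, , drop = FALSE]
  if (nrow(el) < 2) stop("need >= 2 non-alignment sonications")
  tr <- treatment_efficiency(el$peak_dT_tp3, el$power)
  mean(sort(tr, decreasing = TRUE)[1:2])
}

#' Octagonal annulus mask around a pixel
#'
#' A regular octagon inscribed in the `(2 * outer_half + 1)` square box
#' centred on `center`, minus the octagon inscribed in the inner box: a pixel
#' belongs iff its centre satisfies `max(|dx|, |dy|) <= h` and
#' `|dx| + |dy| <= sqrt(2) h`. Defaults reproduce the 40 x 40 pixel frame of
#' thickness 10 used for the thermometry noise estimate.
#'
#' @param dim image dimensions `c(nrow, ncol)`
#' @param center pixel `c(row, col)`
#' @param outer_half,inner_half octagon half-widths in pixels
#' @return logical matrix
#' @export
octagon_annulus_mask <- function(dim, center, outer_half = 20,
                                 inner_half = 10) {
  dx <- abs(row(matrix(0, dim[1], dim[2])) - center[1])
  dy <- abs(col(matrix(0, dim[1], dim[2])) - center[2])
  octo <- function(h) dx <= h & dy <= h & (dx + dy) <= sqrt(2) * h
  octo(outer_half) & !octo(inner_half)
}

#' Thermometry noise standard deviation around the focal spot
#'
#' Standard deviation of the image inside the octagonal annulus centred on
#' the focal spot. If the annulus is clipped by the image edge the statistic
#' is computed on the unclipped part with a warning.
#'
#' @param frame 2D image (degC)
#' @param center focal pixel `c(row, col)`
#' @inheritParams octagon_annulus_mask
#' @return degC
#' @export
noise_sd <- function(frame, center, outer_half = 20, inner_half = 10) {
  stopifnot(is.matrix(frame))
  if (center[1] - outer_half < 1 || center[1] + outer_half > nrow(frame) ||
      center[2] - outer_half < 1 || center[2] + outer_half > ncol(frame)) {
    warning("octagonal annulus clipped by the image edge")
  }
  mask <- octagon_annulus_mask(dim(frame), center, outer_half, inner_half)
  stats::sd(frame[mask])
}

#' Select sonications for the simulation comparison
#'
#' A sonication is included iff its focal temperature rise lies within three
#' noise standard deviations of the effective treatment efficiency line
#' (`|peak_dT_tp3 - tr_eff_effective * power| <= 3 sd`), it is not the first
#' sonication of the treatment, its phase encode direction is not
#' superior-inferior, and it is not an alignment sonication. Sonications
#' below the line beyond 3 SD are the temperature-rise roll-off region.
#'
#' @param records data.frame with columns `index`, `power`, `peak_dT_tp3`,
#'   `is_alignment`, and optionally `phase_encode` (direction label; `"SI"`
#'   marks superior-inferior)
#' @param tr_eff_effective degC/W, from [effective_treatment_efficiency()]
#' @param noise_sd degC; the per-treatment average noise SD
#' @return the table with logical `included` and character `reason`
#'   (`"included"`, `"first"`, `"alignment"`, `"phase_encode_si"`,
#'   `"roll_off"`)
#' @export
select_sonications <- function(records, tr_eff_effective, noise_sd) {
  stopifnot(is.data.frame(records), noise_sd >= 0)
  dev <- abs(records$peak_dT_tp3 - tr_eff_effective * records$power)
  pe <- if (!is.null(records$phase_encode)) records$phase_encode else "RL"
  reason <- rep("included", nrow(records))
  reason[dev > 3 * noise_sd] <- "roll_off"
  reason[pe == "SI"] <- "phase_encode_si"
  reason[records$is_alignment] <- "alignment"
  reason[records$index == 1] <- "first"
  records$included <- reason == "included"
  records$reason <- reason
  records
}

#' Robust linear calibration regression
#'
#' Iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345) of measured on simulated temperature rise. Reports the slope and
#' intercept with 95 percent confidence intervals from the robust fit's
#' asymptotic covariance, a weighted adjusted r-squared, and the slope
#' p-value (t distribution, n - 2 df). Exactly collinear data fall back to
#' ordinary least squares with zero-width intervals.
#'
#' @param x simulated peak temperature rises
#' @param y measured peak temperature rises
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `adj_r2`, `p_value`, `n`
#' @export
robust_regression <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  ols <- stats::lm(y ~ x)
  if (max(abs(stats::residuals(ols))) < 1e-10 * max(stats::sd(y), 1e-12) ||
      all(abs(stats::residuals(ols)) < 1e-12)) {
    cf <- coef(ols)
    # exactly collinear input: coefficients at machine-noise level are zero
    snap <- 1e-8 * max(stats::sd(y), abs(cf[2]), 1e-12)
    cf[abs(cf) < snap] <- 0
    return(regression_result(cf[2], cf[1], c(0, 0) + cf[2], c(0, 0) + cf[1],
                             1, 0, n))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  sm <- summary(fit)$coefficients
  tq <- qt(0.975, n - 2)
  slope <- sm["x", "Value"]; se_s <- sm["x", "Std. Error"]
  icpt <- sm["(Intercept)", "Value"]; se_i <- sm["(Intercept)", "Std. Error"]
  w <- fit$w
  yhat <- stats::fitted(fit)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p <- 2 * pt(-abs(slope / se_s), n - 2)
  regression_result(slope, icpt, slope + c(-1, 1) * tq * se_s,
                    icpt + c(-1, 1) * tq * se_i, adj, p, n)
}

regression_result <- function(slope, intercept, slope_ci, intercept_ci,
                              adj_r2, p_value, n) {
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 slope_ci = unname(slope_ci),
                 intercept_ci = unname(intercept_ci),
                 adj_r2 = unname(adj_r2), p_value = unname(p_value),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> slope ", signif(x$slope, 4), " [",
      signif(x$slope_ci[1], 4), ", ", signif(x$slope_ci[2], 4),
      "], intercept ", signif(x$intercept, 4), " [",
      signif(x$intercept_ci[1], 4), ", ", signif(x$intercept_ci[2], 4),
      "], adj r2 ", signif(x$adj_r2, 3), ", p ", signif(x$p_value, 3),
      ", n ", x$n, "\n", sep = "")
  invisible(x)
}

prf_rad_per_degc <- function(TE, B0) {
  2 * pi * .const$gamma_hz_per_t * B0 * TE * .const$prf_ppm_per_c * 1e-6
}

#' Convert a PRF phase-difference image to temperature rise
#'
#' `dT = dphi / (2 pi gamma B0 TE alpha)` with the proton resonance frequency
#' thermal coefficient `alpha` = -0.00909 ppm/degC; heating therefore
#' corresponds to a negative phase shift at positive TE.
#'
#' @param phase_diff phase image or array, radians
#' @param TE echo time, s (> 0)
#' @param B0 field strength, T (> 0)
#' @return temperature rise, degC
#' @export
phase_to_temperature <- function(phase_diff, TE, B0) {
  stopifnot(TE > 0, B0 > 0)
  phase_diff / prf_rad_per_degc(TE, B0)
}

#' @rdname phase_to_temperature
#' @param dT temperature-rise image, degC
#' @export
temperature_to_phase <- function(dT, TE, B0) {
  stopifnot(TE > 0, B0 > 0)
  dT * prf_rad_per_degc(TE, B0)
}

#' Referenceless constant and linear phase correction
#'
#' Least-squares fit of `a + b x + c y` over the masked (non-heated)
#' background pixels, subtracted from the whole image. The masked-region
#' residual mean is zero by construction.
#'
#' @param phase_image 2D phase image, radians
#' @param background_mask logical matrix; `TRUE` marks background pixels
#'   (must exclude the hotspot; >= 50 pixels)
#' @return the corrected phase image; fitted coefficients in attribute
#'   `"coefficients"`
#' @export
referenceless_correction <- function(phase_image, background_mask) {
  stopifnot(is.matrix(phase_image),
            all(dim(background_mask) == dim(phase_image)))
  if (sum(background_mask) < 50) stop("background mask too small (< 50 pixels)")
  X <- cbind(1, as.vector(row(phase_image)), as.vector(col(phase_image)))
  sel <- as.vector(background_mask)
  cf <- stats::lm.fit(X[sel, , drop = FALSE],
                      as.vector(phase_image)[sel])$coefficients
  fitted <- matrix(X %*% cf, nrow(phase_image), ncol(phase_image))
  out <- phase_image - fitted
  attr(out, "coefficients") <- cf
  out
}
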