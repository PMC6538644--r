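test_that("slab extraction block-averages and upsamples as specified", {
  # constant volumes stay constant
  vol <- array(3.7, c(48, 48, 15))
  sp <- slab_spec(c(1, 1, 1), c(16, 8), factors = c(3, 6, 15))
  img <- extract_thermometry_slab(vol, sp)
  expect_equal(dim(attr(img, "native")), c(16, 8))   # pre-upsample shape
  expect_equal(dim(img), c(16, 16))
  expect_true(all(img == 3.7))
  # random slab equals the brute-force nested-loop block mean
  set.seed(9)
  vol <- array(rnorm(48 * 48 * 15), c(48, 48, 15))
  img <- extract_thermometry_slab(vol, sp)
  native <- attr(img, "native")
  oracle <- matrix(0, 16, 8)
  for (i in 1:16) for (j in 1:8) {
    oracle[i, j] <- mean(vol[(3 * i - 2):(3 * i), (6 * j - 5):(6 * j), 1:15])
  }
  expect_equal(native, oracle)
  expect_equal(img[, seq(1, 16, 2)], native)   # nearest upsampling
  expect_equal(img[, seq(2, 16, 2)], native)
  # commutes with scaling
  img2 <- extract_thermometry_slab(2.5 * vol, sp)
  expect_equal(img2, 2.5 * img, ignore_attr = TRUE)
  # out-of-bounds slabs are rejected
  expect_error(extract_thermometry_slab(vol, slab_spec(c(2, 1, 1), c(16, 8))),
               "bounds")
})

test_that("focal spot position is the hottest pixel with row-major ties", {
  m <- matrix(0, 6, 6); m[4, 2] <- 5
  expect_equal(focal_spot_position(m), c(4L, 2L))
  # two equal maxima: (2,5) precedes (3,1) in row-major order
  m2 <- matrix(0, 6, 6); m2[2, 5] <- 7; m2[3, 1] <- 7
  expect_equal(focal_spot_position(m2), c(2L, 5L))
  expect_error(focal_spot_position(matrix(NA_real_, 3, 3)), "NaN")
  # noiseless Gaussian blob: argmax is the blob centre
  g <- exp(-outer(((1:21) - 13)^2, ((1:21) - 8)^2, `+`) / 20)
  expect_equal(focal_spot_position(g), c(13L, 8L))
})

test_that("position errors scale by the per-axis pixel size", {
  expect_equal(position_error(c(5, 5), c(5, 5)), c(freq = 0, phase = 0))
  expect_equal(position_error(c(6, 5), c(5, 5)), c(freq = 1.094, phase = 0))
  expect_equal(position_error(c(3, 9), c(5, 6)),
               c(freq = 2.188, phase = 6.564))
})

test_that("treatment efficiency is rise over power", {
  expect_equal(treatment_efficiency(19, 500), 0.038)
  expect_equal(treatment_efficiency(0, 300), 0)
  expect_equal(treatment_efficiency(10, 400),
               treatment_efficiency(10, 200) / 2)
  expect_error(treatment_efficiency(5, 0), "power")
})

test_that("effective treatment efficiency averages the top two", {
  rec <- data.frame(power = c(100, 100, 100, 100),
                    peak_dT_tp3 = c(9, 2, 4, 6),
                    is_alignment = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(effective_treatment_efficiency(rec), mean(c(0.06, 0.04)))
  dup <- data.frame(power = 100, peak_dT_tp3 = c(5, 5, 1),
                    is_alignment = FALSE)
  expect_equal(effective_treatment_efficiency(dup), 0.05)
  expect_error(effective_treatment_efficiency(
    data.frame(power = 100, peak_dT_tp3 = 1:3, is_alignment = TRUE)),
    "non-alignment")
})

test_that("the octagonal annulus has the stated geometry", {
  mask <- octagon_annulus_mask(c(101, 101), c(51, 51))
  dx <- abs(row(mask) - 51); dy <- abs(col(mask) - 51)
  # nothing beyond the outer box, nothing inside the inner octagon
  expect_true(all(dx[mask] <= 20 & dy[mask] <= 20))
  expect_true(all(!(mask & dx <= 10 & dy <= 10 & dx + dy <= sqrt(2) * 10)))
  # the inner 20 x 20 box core (hotspot region) is fully excluded
  expect_false(any(mask & dx <= 7 & dy <= 7))
  # 4-fold symmetric
  expect_equal(mask, mask[101:1, ])
  expect_equal(mask, t(mask))
})

test_that("noise SD is recovered from the annulus and clipping warns", {
  expect_equal(noise_sd(matrix(2, 101, 101), c(51, 51)), 0)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    fr <- matrix(rnorm(101 * 101), 101, 101)
    fr[45:57, 45:57] <- fr[45:57, 45:57] + 30    # hotspot inside inner box
    noise_sd(fr, c(51, 51))
  }, numeric(1))
  expect_true(all(abs(errs - 1) < 0.1))
  expect_warning(noise_sd(matrix(rnorm(400), 20, 20), c(10, 10)), "clipped")
})

test_that("sonication selection applies all four exclusion rules", {
  rec <- data.frame(index = 1:6, power = c(100, 150, 200, 250, 300, 350),
                    is_alignment = c(TRUE, rep(FALSE, 5)),
                    phase_encode = c("RL", "RL", "SI", "RL", "RL", "RL"))
  tre <- 0.04; nsd <- 0.5
  rec$peak_dT_tp3 <- tre * rec$power
  rec$peak_dT_tp3[5] <- tre * rec$power[5] - 4 * nsd   # roll-off outlier
  out <- select_sonications(rec, tre, nsd)
  expect_equal(out$reason,
               c("first", "included", "phase_encode_si", "included",
                 "roll_off", "included"))
  expect_equal(which(out$included), c(2, 4, 6))
  # exactly on the line is included
  expect_true(out$included[2])
  # permutation invariance up to record identity
  perm <- sample(6)
  out2 <- select_sonications(rec[perm, ], tre, nsd)
  expect_equal(out2$reason, out$reason[perm])
  # inclusion is monotone in the noise SD
  out3 <- select_sonications(rec, tre, nsd * 10)
  expect_true(all(out3$included | !out$included))
  expect_true(out3$included[5])
})

test_that("robust regression fits exact and contaminated lines", {
  x <- seq(1, 20)
  r <- robust_regression(x, 1.3 * x)
  expect_equal(r$slope, 1.3, tolerance = 1e-10)
  expect_equal(r$intercept, 0, tolerance = 1e-9)
  expect_true(r$intercept_ci[1] <= 0 && r$intercept_ci[2] >= 0)
  expect_true(r$slope_ci[1] <= r$slope && r$slope <= r$slope_ci[2])
  # one gross outlier barely moves the Huber fit
  set.seed(4)
  y <- x + rnorm(20, 0, 0.1); y[7] <- y[7] + 15
  rr <- robust_regression(x, y)
  expect_lt(abs(rr$slope - 1), 0.05)
  ols <- coef(lm(y ~ x))[2]
  expect_lt(abs(rr$slope - 1), abs(ols - 1))
  expect_error(robust_regression(1:2, 1:2), "at least 3")
  expect_error(robust_regression(rep(2, 5), 1:5), "degenerate")
})

test_that("robust regression recovers slopes with near-nominal coverage", {
  # true slopes 0.5 / 1 / 2; 10 percent gross outliers; n = 20; 200 seeds
  for (s_true in c(0.5, 1, 2)) {
    fits <- vapply(1:200, function(seed) {
      set.seed(seed)
      x <- runif(20, 1, 20)
      y <- s_true * x + rnorm(20, 0, 0.5)
      out <- sample(20, 2)
      y[out] <- y[out] + sample(c(-1, 1), 2, replace = TRUE) * 8 * 0.5
      r <- robust_regression(x, y)
      c(r$slope, r$slope_ci[1] <= s_true && s_true <= r$slope_ci[2])
    }, numeric(2))
    expect_lt(abs(mean(fits[1, ]) - s_true) / s_true, 0.03)
    expect_gte(mean(fits[2, ]), 0.9)
  }
})

test_that("PRF phase and temperature convert as exact inverses", {
  expect_equal(phase_to_temperature(0, 0.013, 3), 0)
  phi <- temperature_to_phase(10, TE = 0.013, B0 = 3)
  expect_lt(phi, 0)    # heating shifts phase negative at the -0.00909 ppm/C
  expect_equal(phase_to_temperature(phi, 0.013, 3), 10)
  img <- matrix(rnorm(100), 10)
  expect_equal(phase_to_temperature(temperature_to_phase(img, 0.01, 1.5),
                                    0.01, 1.5), img)
})

test_that("referenceless correction removes planar backgrounds only", {
  n <- 64
  ramp <- 0.3 + 0.02 * row(matrix(0, n, n)) - 0.015 * col(matrix(0, n, n))
  mask <- matrix(TRUE, n, n)
  out <- referenceless_correction(ramp, mask)
  expect_lt(max(abs(out)), 1e-10)
  # hotspot outside the mask survives untouched
  hot <- matrix(0, n, n)
  hot[30:36, 30:36] <- -1.2 * exp(-outer((-3:3)^2, (-3:3)^2, `+`) / 6)
  mask2 <- mask; mask2[25:41, 25:41] <- FALSE
  out2 <- referenceless_correction(ramp + hot, mask2)
  expect_equal(out2, hot, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mean(out2[mask2]), 0, tolerance = 1e-12)
  # constant offsets are removed; tiny masks are rejected
  out3 <- referenceless_correction(matrix(0.7, n, n), mask)
  expect_lt(max(abs(out3)), 1e-12)
  small <- matrix(FALSE, n, n); small[1:5, 1:5] <- TRUE
  expect_error(referenceless_correction(ramp, small), "mask too small")
})
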