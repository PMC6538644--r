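make_pressure <- function(p, spacing = 1) {
  fusbeam:::pressure_volume(p, spacing = rep(spacing, 3),
                            origin = -(dim(p) - 1) * spacing / 2,
                            orientation = diag(3), frequency = 680e3)
}

uniform_props <- function(d, att_npcm, vel = 1500, den = 1000, spacing = 1) {
  structure(list(velocity = array(vel, d), attenuation = array(att_npcm, d),
                 density = array(den, d), spacing = rep(spacing, 3),
                 origin = -(d - 1) * spacing / 2, orientation = diag(3),
                 frequency = 680e3, pset_name = "test"),
            class = "property_volumes")
}

test_that("the heating rate is alpha p^2 / (rho c) in SI units", {
  p <- array(0 + 0i, c(5, 5, 5)); p[3, 3, 3] <- 2e6
  pv <- make_pressure(p)
  props <- uniform_props(c(5, 5, 5), att_npcm = 0.05)  # 5 Np/m
  Q <- heating_rate(pv, props)$Q
  expect_equal(Q[3, 3, 3], 5 * (2e6)^2 / (1000 * 1500))
  expect_equal(Q[3, 3, 3], 1.333333e7, tolerance = 1e-6)
  expect_true(all(Q[-63] == 0))
  # zero pressure or zero attenuation give zero heating
  expect_true(all(heating_rate(make_pressure(array(0i, c(4, 4, 4))),
                               uniform_props(c(4, 4, 4), 1))$Q == 0))
  expect_true(all(heating_rate(pv, NULL)$Q == 0))
})

test_that("without diffusion and perfusion the rise is exactly linear", {
  d <- c(7, 7, 7)
  Q <- array(2e6, d)
  th <- thermal_properties(conductivity = 0, perfusion = 0)
  T0 <- array(0, d)
  dt <- 0.25
  T1 <- step_temperature(T0, Q, th, dt, spacing_mm = 1)
  T2 <- step_temperature(T1, Q, th, dt, spacing_mm = 1)
  rise <- 2e6 * dt / (1000 * 3600)
  expect_equal(T1[4, 4, 4], rise)
  expect_equal(T2[4, 4, 4], 2 * rise)
  expect_equal(T2[2:6, 2:6, 2:6], array(2 * rise, c(5, 5, 5)))
})

test_that("perfusion-only cooling follows the Pennes relaxation rate", {
  d <- c(5, 5, 5)
  th <- thermal_properties(conductivity = 0, perfusion = 700)
  lam <- th$blood_density * th$blood_specific_heat *
    (700 * 1e-6 / 60) / th$specific_heat          # exp rate, 1/s
  dt <- 0.02; nstep <- 400                         # t = 8 s
  T <- array(1, d)
  Q <- array(0, d)
  for (i in seq_len(nstep)) T <- step_temperature(T, Q, th, dt, 1)
  expect_equal(T[3, 3, 3], exp(-lam * dt * nstep), tolerance = 0.01)
  # measured decay rate within 1 percent of the closed form
  rate <- -log(T[3, 3, 3]) / (dt * nstep)
  expect_equal(rate, lam, tolerance = 0.01)
})

test_that("diffusion grows a Gaussian's variance at 2 D t per axis", {
  n <- 41; dx <- 1
  u <- ((1:n) - 21) * dx
  sig0 <- 4
  g1 <- exp(-u^2 / (2 * sig0^2))
  T <- outer(outer(g1, g1), g1)
  th <- thermal_properties(perfusion = 0)   # conduction only
  D <- th$conductivity / (th$density * th$specific_heat) * 1e6  # mm^2/s
  dt <- 0.2; nstep <- 100                   # t = 20 s
  Q <- array(0, dim(T))
  for (i in seq_len(nstep)) T <- step_temperature(T, Q, th, dt, dx)
  t_end <- dt * nstep
  # second-moment estimate along x through the centre plane
  w <- apply(T, 1, sum)
  v <- sum(u^2 * w) / sum(w)
  expect_equal(v, sig0^2 + 2 * D * t_end, tolerance = 0.02)
})

test_that("the explicit stability bound is enforced", {
  th <- thermal_properties()
  bound <- bioheat_stability_dt(th, 1)
  expect_error(step_temperature(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                                th, dt = bound * 1.1, spacing_mm = 1),
               "stability bound")
  expect_error(
    simulate_temperature(make_pressure(array(1e6 + 0i, c(5, 5, 5))),
                         uniform_props(c(5, 5, 5), 1), th,
                         heating_protocol(dt = bound * 2), margin_mm = 10),
    "stability bound")
  expect_equal(bioheat_stability_dt(thermal_properties(conductivity = 0), 1),
               Inf)
})

test_that("simulate_temperature matches a step-by-step replay", {
  set.seed(3)
  d <- c(9, 9, 9)
  p <- array(complex(real = rnorm(prod(d), sd = 1e5),
                     imaginary = rnorm(prod(d), sd = 1e5)), d)
  pv <- make_pressure(p)
  props <- uniform_props(d, att_npcm = 0.5)
  th <- thermal_properties()
  dt <- 0.1
  proto <- heating_protocol(on_duration = 1, timepoint_times = c(0, 0.5, 1),
                            dt = dt)
  ts <- simulate_temperature(pv, props, th, proto, margin_mm = 100)
  Q <- heating_rate(pv, props)$Q
  T <- array(0, d)
  replay <- list(T)
  for (s in 1:10) {
    T <- step_temperature(T, Q, th, dt, 1)
    if (s %in% c(5, 10)) replay[[length(replay) + 1]] <- T
  }
  expect_equal(ts$frames[[1]], replay[[1]])
  expect_equal(ts$frames[[2]], replay[[2]], tolerance = 1e-10)
  expect_equal(ts$frames[[3]], replay[[3]], tolerance = 1e-10)
  # a timepoint at t = 0 is a zero frame
  expect_true(all(ts$frames[[1]] == 0))
  # the peak curve never decreases while heating without perfusion
  th0 <- thermal_properties(perfusion = 0)
  ts0 <- simulate_temperature(pv, props, th0, proto, margin_mm = 100)
  on_steps <- ts0$times <= 1
  expect_true(all(diff(ts0$peak_curve[on_steps]) >= 0))
})

test_that("temperature rise is exactly linear in the heating rate", {
  d <- c(9, 9, 9)
  p <- array(0i, d); p[5, 5, 5] <- 1e6; p[4, 5, 5] <- 5e5
  pv <- make_pressure(p)
  pv2 <- pv; pv2$pressure <- pv$pressure * sqrt(2)   # doubles Q
  props <- uniform_props(d, 0.6)
  proto <- heating_protocol(on_duration = 1, timepoint_times = c(0.5, 1),
                            dt = 0.1)
  t1 <- simulate_temperature(pv, props, protocol = proto, margin_mm = 100)
  t2 <- simulate_temperature(pv2, props, protocol = proto, margin_mm = 100)
  expect_equal(t2$frames[[2]], 2 * t1$frames[[2]], tolerance = 1e-12)
})

test_that("the per-step energy budget closes for interior heating", {
  d <- c(21, 21, 21); dx <- 1
  u <- ((1:21) - 11)
  g <- exp(-u^2 / 8)
  Q <- outer(outer(g, g), g) * 5e5
  th <- thermal_properties()
  dt <- 0.1
  T <- array(0, d)
  for (s in 1:20) T <- step_temperature(T, Q, th, dt, dx)
  rhoC <- th$density * th$specific_heat
  dV <- (dx * 1e-3)^3
  energy <- sum(T) * rhoC * dV
  # input minus perfusion sink, integrated over the same discrete steps
  input <- sum(Q) * dV * dt * 20
  Tsum <- 0; Tk <- array(0, d)
  for (s in 1:20) { Tsum <- Tsum + sum(Tk) * dt; Tk <- step_temperature(Tk, Q, th, dt, dx) }
  sink <- fusbeam:::perfusion_coeff(th) * Tsum * dV
  expect_equal(energy, input - sink, tolerance = 0.01)
})

test_that("sensitivity sweeps rank conductivity and perfusion monotonically", {
  d <- c(15, 15, 15)
  p <- array(0i, d)
  g <- exp(-(((1:15) - 8)^2) / 6)
  p[] <- complex(real = outer(outer(g, g), g) * 2e6)
  pv <- make_pressure(p)
  props <- uniform_props(d, 0.4)
  proto <- heating_protocol(on_duration = 2, timepoint_times = c(1, 1.5, 2),
                            dt = 0.1)
  sw <- sensitivity_sweep(pv, props,
                          ranges = list(perfusion = c(412, 700, 976),
                                        conductivity = c(0.49, 0.54)),
                          protocol = proto, margin_mm = 100)
  perf <- sw[sw$parameter == "perfusion", ]
  cond <- sw[sw$parameter == "conductivity", ]
  expect_true(all(diff(perf$peak_dT[order(perf$value)]) < 0))
  expect_true(all(diff(cond$peak_dT[order(cond$value)]) < 0))
  # a degenerate single-value range reproduces the baseline
  base <- simulate_temperature(pv, props, thermal_properties(), proto,
                               margin_mm = 100)
  one <- sensitivity_sweep(pv, props, ranges = list(perfusion = 559),
                           protocol = proto, margin_mm = 100)
  expect_equal(one$peak_dT, max(base$frames[[3]]))
})
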