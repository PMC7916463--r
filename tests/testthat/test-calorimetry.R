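test_that("initial heating rate is the least-squares slope over the window", {
  tt <- 0:300
  # noiseless line
  cv <- heating_curve(tt, 25 + 0.06 * tt)
  expect_equal(initial_rate(cv, 30), 0.06)
  # constant curve
  expect_equal(initial_rate(heating_curve(tt, rep(25, 301)), 30), 0)
  # saturating curve: slope over [0, 30 s] sits below the t = 0 tangent
  sat <- heating_curve(tt, 25 + 27.5 * (1 - exp(-tt / 180)))
  r30 <- initial_rate(sat, 30)
  expect_equal(r30, 0.139, tolerance = 2e-2)
  expect_lt(r30, 27.5 / 180)
  expect_equal(27.5 / 180, 0.153, tolerance = 2e-3)
  # window validation
  expect_error(initial_rate(cv, 1000), "window")
  expect_error(initial_rate(heating_curve(c(0, 100), c(25, 30)), 30),
               "fewer than 2")
})

test_that("temperature change reads the configured endpoint", {
  tt <- 0:400
  expect_equal(delta_T(heating_curve(tt, 25 + 0.05 * tt), 300), 15)
  expect_equal(delta_T(heating_curve(tt, rep(25, 401)), 300), 0)
  expect_error(delta_T(heating_curve(0:100, rep(25, 101)), 300), "endpoint")
  # the generator's plateau is recovered in the long-time limit
  long <- make_heating_curve(curve_spec(rise = 27.46, tau = 180,
                                        noise_sd = 0, duration = 300))
  expect_equal(delta_T(long, 300), 27.46 * (1 - exp(-300 / 180)),
               tolerance = 1e-10)
  expect_equal(delta_T(long, 300), 22.3, tolerance = 2e-3)
  very_long <- make_heating_curve(curve_spec(rise = 27.46, tau = 180,
                                             noise_sd = 0, duration = 5000))
  expect_equal(delta_T(very_long, 5000), 27.46, tolerance = 1e-5)
})

test_that("conversion efficiency implements the lumped energy balance", {
  tt <- 0:300
  cv <- heating_curve(tt, 25 + 0.06 * tt, P0 = 0.5, A810 = 1.54,
                      m_w = 0.5, c_p = 4.185)
  # oracle: plain arithmetic
  eta_oracle <- 0.5 * 4.185 * 0.06 / (0.5 * (1 - 10^-1.54))
  expect_equal(conversion_efficiency(cv), eta_oracle)
  expect_equal(conversion_efficiency(cv), 0.259, tolerance = 2e-3)
  # zero rate
  cv0 <- heating_curve(tt, rep(25, 301), P0 = 0.5, A810 = 1.54)
  expect_equal(conversion_efficiency(cv0), 0, tolerance = 1e-12)
  # opaque limit: eta -> m c rate / P0
  cvinf <- heating_curve(tt, 25 + 0.06 * tt, P0 = 0.5, A810 = 50)
  expect_equal(conversion_efficiency(cvinf), 0.5 * 4.185 * 0.06 / 0.5,
               tolerance = 1e-9)
  # transparent sample cannot heat
  cvz <- heating_curve(tt, 25 + 0.06 * tt, P0 = 0.5, A810 = 0)
  expect_error(conversion_efficiency(cvz), "A810")
  # offset invariance
  cv_off <- heating_curve(tt, 40 + 0.06 * tt, P0 = 0.5, A810 = 1.54)
  expect_equal(conversion_efficiency(cv_off), conversion_efficiency(cv))
})

test_that("known efficiencies are recovered from synthetic curves", {
  grid <- expand.grid(A810 = c(1.28, 1.54), P0 = c(0.5, 1.0))
  eta_true <- 0.3
  for (g in seq_len(nrow(grid))) {
    rate <- eta_true * grid$P0[g] * (1 - 10^-grid$A810[g]) / (0.5 * 4.185)
    tt <- 0:300
    cv <- heating_curve(tt, 25 + rate * tt, P0 = grid$P0[g],
                        A810 = grid$A810[g], m_w = 0.5, c_p = 4.185)
    expect_equal(conversion_efficiency(cv), eta_true, tolerance = 1e-10)
  }
})

test_that("viability arithmetic reports both orientations", {
  v <- cell_viability(113, 59)
  expect_equal(v$cv_literal, (1 - 59 / 113) * 100)
  expect_equal(v$cv_literal, 47.8, tolerance = 1e-3)
  expect_equal(v$cv_literal + v$pct_viable, 100)
  expect_equal(cell_viability(50, 50)$cv_literal, 0)
  expect_equal(cell_viability(50, 0)$cv_literal, 100)
  expect_error(cell_viability(0, 0))
  expect_error(cell_viability(10, 11))
  vr <- cell_viability(113, 59, control = 3)
  expect_equal(vr$relative, vr$cv_literal / 3)
})

test_that("heating-curve CSV round-trips and validates its header", {
  cv <- make_heating_curve(curve_spec(noise_sd = 0.05, seed = 3),
                           label = "AuNP-10", P0 = 1, A810 = 1.54)
  p <- tempfile(fileext = ".csv")
  write_heating_curve(cv, p)
  back <- read_heating_curve(p, label = "AuNP-10", P0 = 1, A810 = 1.54)
  expect_equal(back$temp_C, cv$temp_C)
  expect_equal(back$time_s, cv$time_s)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(t = 1:3, temp = 4:6), bad, row.names = FALSE)
  expect_error(read_heating_curve(bad), "format error")
})

test_that("batch report lays out one row per sample", {
  curves <- list(
    make_heating_curve(curve_spec(rise = 15.2, noise_sd = 0),
                       label = "AuNP-10", P0 = 0.5, A810 = 1.54),
    make_heating_curve(curve_spec(rise = 27.46, noise_sd = 0),
                       label = "AuNP-10", P0 = 1.0, A810 = 1.54),
    make_heating_curve(curve_spec(rise = 8.32, noise_sd = 0),
                       label = "AuNP-5", P0 = 0.5, A810 = 1.28),
    make_heating_curve(curve_spec(rise = 17.84, noise_sd = 0),
                       label = "AuNP-5", P0 = 1.0, A810 = 1.28))
  rep <- calorimetry_report(curves)
  expect_equal(nrow(rep), 4)
  expect_named(rep, c("sample", "P0_W", "A810", "dTdt_C_per_s", "dT_C",
                      "eta"))
  expect_true(all(rep$eta > 0))
  expect_true(all(diff(order(rep$dT_C)) != 0))
})
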