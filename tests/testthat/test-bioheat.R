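test_that("temperature-dependent conductivity follows the linear law", {
  expect_equal(thermal_conductivity(293.15, 0.48), 0.48)   # bracket = 1
  expect_equal(thermal_conductivity(310.15, 0.48), 0.48 * 1.0476)
  expect_equal(thermal_conductivity(323.15, 0.21), 0.21 * 1.084)
  expect_warning(out <- thermal_conductivity(-100, 0.2), "clamped")
  expect_equal(out, 1e-3)
})

test_that("damage-dependent perfusion is piecewise as specified and continuous", {
  wb0 <- 5e-4
  expect_equal(perfusion_coefficient(0, wb0), wb0)
  expect_equal(perfusion_coefficient(0.05, wb0), 1.6 * wb0)
  expect_equal(perfusion_coefficient(0.1, wb0), 0.9 * wb0)
  expect_equal(perfusion_coefficient(0.5, wb0), 0.5 * wb0)
  expect_equal(perfusion_coefficient(2, wb0), 0)
  expect_equal(perfusion_coefficient(1 + 1e-12, wb0), 0)
  expect_error(perfusion_coefficient(-0.1, wb0), "omega")
  # continuity at both interior break points and at 0+
  eps <- 1e-9
  expect_equal(perfusion_coefficient(eps, wb0), wb0, tolerance = 1e-6)
  expect_equal(perfusion_coefficient(0.1 - eps, wb0),
               perfusion_coefficient(0.1 + eps, wb0), tolerance = 1e-6)
  expect_equal(perfusion_coefficient(1 - eps, wb0), 0, tolerance = 1e-6)
})

test_that("uniform field with no sources stays in equilibrium", {
  ph <- make_toy_phantom("slab")$phantom
  st <- solver_settings(dt = 1, duration = 20, T_init = 310.15, Tb = 310.15,
                        bc = bc_spec("insulated"), lambda_coeff = 0)
  h <- solve_bioheat(ph, 0, st, probes = "P1")
  expect_equal(max(abs(h$probes$T$P1 - 310.15)), 0)
  expect_equal(max(h$Omega[[1]]), damage_rate(310.15) * 20, tolerance = 1e-10)
})

test_that("steady heated slab reproduces the parabolic closed form", {
  toy <- make_toy_phantom("slab", material = "fat", L = 0.02,
                          spacing = 0.02 / 21)
  Q <- 1e4
  st <- solver_settings(dt = 25, duration = 3000, T_init = 310.15,
                        Tb = 310.15, bc = slab_bcs(310.15), lambda_coeff = 0)
  h <- solve_bioheat(toy$phantom, Q, st, probes = "P1")
  rise <- h$probes$T$P1[length(h$probes$T$P1)] - 310.15
  expect_equal(toy$reference$max_rise(Q), 2.380952, tolerance = 1e-6)
  expect_equal(rise, toy$reference$max_rise(Q), tolerance = 5e-3)
})

test_that("uniform perfused tissue relaxes on the Pennes ODE", {
  # no gradients: insulated uniform gland block; closed form
  # T(t) = Tb + (Qmet / w) (1 - exp(-w t / (rho c))),  w = rho_b c_b wb0
  cfg <- breast_phantom_config(block = c(0.006, 0.006, 0.006),
                               fat_thickness = 1e-3, spacing = 1e-3,
                               seed_rows = 0, seed_cols = 0)
  ph <- build_breast_phantom(cfg)
  ph$labels[] <- "gland"
  st <- solver_settings(dt = 1, duration = 4000, T_init = 310.15,
                        Tb = 310.15, bc = bc_spec("insulated"),
                        lambda_coeff = 0, coupling = "one-way")
  h <- solve_bioheat(ph, 0, st, probes = "P1")
  w <- 1050 * 3617 * 5e-4
  rho_c <- 1041 * 2960
  tt <- h$probes$time
  analytic_rise <- 700 / w * (1 - exp(-w * tt / rho_c))
  expect_equal(h$probes$T$P1 - 310.15, analytic_rise, tolerance = 5e-3)
})

test_that("insulated no-perfusion runs conserve energy to the solver tolerance", {
  ph <- make_toy_phantom("slab", material = "fat")$phantom
  st <- solver_settings(dt = 2, duration = 100, T_init = 310.15,
                        Tb = 310.15, bc = bc_spec("insulated"))
  h <- solve_bioheat(ph, 5e4, st, probes = "P1")
  expect_lt(max(h$diagnostics$energy_resid), 1e-6)
  # and the temperature actually integrates the source: dT/dt = Q/(rho c)
  rho_c <- 911 * 2348
  expect_equal(h$probes$T$P1[length(h$probes$T$P1)] - 310.15,
               5e4 * 100 / rho_c, tolerance = 1e-3)
})

test_that("maximum principle holds without sources or perfusion", {
  toy <- make_toy_phantom("slab", material = "fat", L = 0.02, spacing = 1e-3)
  ph <- toy$phantom
  set.seed(11)
  T0 <- 310.15 + 20 * runif(prod(ph$dims))
  st <- solver_settings(dt = 5, duration = 200, T_init = T0, Tb = 310.15,
                        bc = bc_spec("insulated"))
  h <- solve_bioheat(ph, 0, st, probes = "P1")
  Tend <- h$T[[length(h$T)]]
  expect_lte(max(Tend), max(T0) + 1e-9)
  expect_gte(min(Tend), min(T0) - 1e-9)
})

test_that("coupling modes agree while damage is negligible", {
  cfg <- small_seed_config()
  ph <- build_breast_phantom(cfg)
  src <- array(0, dim = ph$dims)
  src[ph$labels == "seed"] <- 1e5   # mild heating, Omega stays ~ 0
  mk <- function(mode) solver_settings(dt = 1, duration = 30,
                                       coupling = mode)
  h2 <- solve_bioheat(ph, src, mk("two-way"), probes = "P1")
  h1 <- solve_bioheat(ph, src, mk("one-way"), probes = "P1")
  expect_lt(max(h2$Omega[[1]]), 1e-5)
  expect_equal(h2$probes$T$P1, h1$probes$T$P1, tolerance = 1e-9)
})

test_that("temperature rises monotonically with laser power", {
  ph <- build_breast_phantom(small_seed_config())
  beam_at <- function(P0) laser_beam(P0, c(0.0155, 0.0155, 0))
  st <- solver_settings(dt = 1, duration = 60)
  traces <- lapply(c(0.5, 1, 2), function(p) {
    src <- heat_source(fluence(ph, beam_at(p)), ph)
    solve_bioheat(ph, src, st, probes = "P1")$probes$T$P1
  })
  expect_true(all(traces[[2]] - traces[[1]] >= -1e-9))
  expect_true(all(traces[[3]] - traces[[2]] >= -1e-9))
})

test_that("grid refinement converges on the analytic slab", {
  Q <- 1e4
  make_problem <- function(h) {
    toy <- make_toy_phantom("slab", material = "fat", L = 0.02, spacing = h)
    list(phantom = toy$phantom, source = Q,
         settings = solver_settings(dt = 25, duration = 3000,
                                    T_init = 310.15, Tb = 310.15,
                                    bc = slab_bcs(310.15),
                                    lambda_coeff = 0))
  }
  spacings <- 0.02 / c(11, 21, 41)
  out <- refine_to_asymptote(make_problem, spacings, tol = 5e-3,
                             probe = "P1")
  expect_true(out$converged)
  expect_gte(nrow(out$report), 2)
  deltas <- out$report$delta[-1]
  expect_true(all(diff(deltas) <= 0))
  Tend <- out$report$T_end[nrow(out$report)]
  expect_equal(Tend - 310.15, 1e4 * 0.02^2 / (8 * 0.21), tolerance = 1e-2)

  # infinite tolerance returns after the first solve
  out1 <- refine_to_asymptote(make_problem, spacings, tol = Inf,
                              probe = "P1")
  expect_equal(nrow(out1$report), 1)
})

test_that("solver validates inputs and settings", {
  ph <- make_toy_phantom("slab")$phantom
  expect_error(solve_bioheat(ph, array(0, dim = c(2, 2, 2))), "shape error")
  expect_error(solver_settings(dt = 0), "dt")
  expect_error(solver_settings(dt = 1, duration = 0.5), "duration")
  expect_error(solver_settings(snapshot_cadence = 0.1), "snapshot_cadence")
})
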