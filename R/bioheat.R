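#' Temperature-dependent thermal conductivity
#'
#' Linear model `lambda(T) = lambda_37 * (1 + coeff * (T - T_ref))` about the
#' reference temperature. The printed form of the model pairs the 37 degC
#' reference conductivity with `T_ref = 293.15` K; both the slope and the
#' reference are exposed for users who prefer a 310.15 K reference. Results
#' that would fall to or below zero at extreme low temperatures are clamped
#' at `floor` (with a warning).
#'
#' @param T temperature(s), K.
#' @param lambda_37 reference conductivity, W m^-1 K^-1 (> 0).
#' @param coeff linear coefficient, K^-1.
#' @param T_ref reference temperature, K.
#' @param floor lower clamp, W m^-1 K^-1.
#' @return conductivity, W m^-1 K^-1.
#' @export
thermal_conductivity <- function(T, lambda_37, coeff = 0.0028,
                                 T_ref = 293.15, floor = 1e-3) {
  stopifnot(all(lambda_37 > 0), floor > 0)
  out <- lambda_37 * (1 + coeff * (T - T_ref))
  if (any(out < floor)) {
    warning("thermal conductivity clamped at floor = ", floor)
    out[out < floor] <- floor
  }
  out
}

#' Damage-dependent blood perfusion coefficient
#'
#' Piecewise response of perfusion to cumulative thermal damage Omega:
#' baseline at Omega = 0, transient hyperaemia
#' `(1 + 25 Omega - 260 Omega^2)` for 0 < Omega <= 0.1, linear shutdown
#' `(1 - Omega)` for 0.1 < Omega <= 1, and complete stasis beyond. The
#' multiplier is continuous at both interior break points.
#'
#' @param omega cumulative damage(s), dimensionless (>= 0).
#' @param omega_b0 baseline perfusion coefficient, s^-1 (>= 0).
#' @return perfusion coefficient(s), s^-1.
#' @export
perfusion_coefficient <- function(omega, omega_b0) {
  stopifnot(all(omega_b0 >= 0))
  if (any(omega < 0)) stop("omega must be >= 0")
  mult <- ifelse(omega <= 0, 1,
          ifelse(omega <= 0.1, 1 + 25 * omega - 260 * omega^2,
          ifelse(omega <= 1, 1 - omega, 0)))
  mult * omega_b0
}

#' Boundary-condition specification for one (or all) outer faces
#'
#' @param kind `"fixed"` (Dirichlet at the face), `"insulated"` (zero flux)
#'   or `"convective"` (Robin with film coefficient `h` towards `T_amb`).
#' @param T_fix fixed face temperature, K (Dirichlet).
#' @param h film coefficient, W m^-2 K^-1 (convective).
#' @param T_amb ambient temperature, K (convective).
#' @return a `bc_spec`.
#' @export
bc_spec <- function(kind = c("fixed", "insulated", "convective"),
                    T_fix = 310.15, h = 10, T_amb = 298.15) {
  kind <- match.arg(kind)
  if (kind == "convective") stopifnot(h >= 0)
  structure(list(kind = kind, T_fix = T_fix, h = h, T_amb = T_amb),
            class = "bc_spec")
}

#' Bioheat solver settings
#'
#' @param dt time step, s (> 0). Stepping is implicit (backward Euler) and
#'   unconditionally stable, so dt is an accuracy knob, not a stability one.
#' @param duration total simulated time, s (>= dt).
#' @param T_init initial temperature, K: scalar or per-voxel vector.
#' @param Tb arterial blood temperature, K.
#' @param bc a [bc_spec] applied to all six outer faces, or a list of six
#'   (x-lo, x-hi, y-lo, y-hi, z-lo, z-hi).
#' @param coupling `"two-way"` feeds the concurrently accumulated damage
#'   field into the perfusion every step; `"one-way"` keeps perfusion at
#'   baseline and accumulates damage passively (the strictly sequential
#'   temperature-then-damage pipeline).
#' @param snapshot_cadence seconds between stored full-field snapshots
#'   (>= dt); `Inf` stores only the final fields. Probe traces are recorded
#'   every step regardless.
#' @param lambda_coeff,lambda_Tref,lambda_floor conductivity model, see
#'   [thermal_conductivity()]; set `lambda_coeff = 0` for constant
#'   conductivity.
#' @param arrhenius [arrhenius_params] for the concurrent damage
#'   integration.
#' @param cg_rtol,cg_maxit conjugate-gradient relative tolerance and
#'   iteration cap for the per-step linear solves.
#' @return a `solver_settings`.
#' @export
solver_settings <- function(dt = 0.5, duration = 900, T_init = 310.15,
                            Tb = 310.15, bc = bc_spec("fixed"),
                            coupling = c("two-way", "one-way"),
                            snapshot_cadence = Inf,
                            lambda_coeff = 0.0028, lambda_Tref = 293.15,
                            lambda_floor = 1e-3,
                            arrhenius = arrhenius_params(),
                            cg_rtol = 1e-10, cg_maxit = 1000) {
  coupling <- match.arg(coupling)
  stopifnot(dt > 0, duration >= dt, snapshot_cadence >= dt)
  if (inherits(bc, "bc_spec")) bc <- rep(list(bc), 6)
  stopifnot(length(bc) == 6, all(vapply(bc, inherits, TRUE, "bc_spec")))
  structure(list(dt = dt, duration = duration, T_init = T_init, Tb = Tb,
                 bc = bc, coupling = coupling,
                 snapshot_cadence = snapshot_cadence,
                 lambda_coeff = lambda_coeff, lambda_Tref = lambda_Tref,
                 lambda_floor = lambda_floor, arrhenius = arrhenius,
                 cg_rtol = cg_rtol, cg_maxit = cg_maxit),
            class = "solver_settings")
}

#' Solve the Pennes bioheat equation on a phantom
#'
#' Advances `rho c dT/dt = div(lambda(T) grad T) +
#' rho_b c_b omega_b(Omega) (Tb - T) + Qmet + Q` with implicit
#' (backward-Euler) time stepping, harmonic-mean face conductivities, lagged
#' nonlinearities and concurrent trapezoidal Arrhenius damage accumulation.
#' Probe traces are sampled every step; full temperature and damage fields
#' at the snapshot cadence.
#'
#' @param phantom a `tissue_phantom`.
#' @param source volumetric heat source, W m^-3: a 3-d array on the phantom
#'   grid, or a scalar (0 for no laser).
#' @param settings a [solver_settings].
#' @param probes character vector of probe names to trace (default: all
#'   registered on the phantom).
#' @return An object of class `field_history`: snapshot `times`, lists `T`
#'   and `Omega` of 3-d arrays (K / dimensionless), `probes` (per-step
#'   traces), and `diagnostics` (per-step relative energy-balance residual
#'   and CG iteration counts).
#' @export
solve_bioheat <- function(phantom, source, settings = solver_settings(),
                          probes = names(phantom$probes)) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(settings, "solver_settings"))
  dims <- phantom$dims
  nvox <- prod(dims)
  if (length(source) == 1) source <- array(source, dim = dims)
  if (!identical(dim(source), as.integer(dims)))
    stop("shape error: source grid does not match the phantom grid")

  f <- phantom_fields(phantom)
  T0 <- settings$T_init
  if (length(T0) == 1) T0 <- rep(T0, nvox)
  stopifnot(length(T0) == nvox)

  nsteps <- as.integer(round(settings$duration / settings$dt))
  snap_every <- if (is.finite(settings$snapshot_cadence))
    max(1L, as.integer(round(settings$snapshot_cadence / settings$dt)))
  else -1L

  kind_code <- c(fixed = 0L, insulated = 1L, convective = 2L)
  bc_kind <- vapply(settings$bc, function(b) kind_code[[b$kind]], integer(1))
  bc_Tfix <- vapply(settings$bc, `[[`, numeric(1), "T_fix")
  bc_h <- vapply(settings$bc, `[[`, numeric(1), "h")
  bc_Tamb <- vapply(settings$bc, `[[`, numeric(1), "T_amb")

  pidx <- vapply(probes, function(nm)
    flat_index(phantom, probe_index(phantom, nm)) - 1L, integer(1))

  res <- .bioheat_step_cpp(
    dims, phantom$spacing,
    f$rho_c, f$lambda37, f$perf0, f$qmet, as.numeric(source),
    as.numeric(T0), settings$dt, nsteps, settings$Tb,
    bc_kind, bc_Tfix, bc_h, bc_Tamb,
    settings$lambda_coeff, settings$lambda_Tref, settings$lambda_floor,
    settings$arrhenius$A, settings$arrhenius$Ea, settings$arrhenius$R,
    settings$coupling == "two-way",
    pidx, snap_every, settings$cg_rtol, settings$cg_maxit)

  if (res$lambda_clamped)
    warning("thermal conductivity hit its floor during the run")

  nsnap <- length(res$snap_time)
  to_arrays <- function(m) lapply(seq_len(nsnap), function(s)
    array(m[, s], dim = dims))
  probe_t <- seq(0, by = settings$dt, length.out = nsteps + 1)
  structure(list(
    times = as.numeric(res$snap_time),
    T = to_arrays(res$snap_T),
    Omega = to_arrays(res$snap_Omega),
    probes = list(
      time = probe_t,
      T = setNames(lapply(seq_along(probes), function(q) res$probe_T[, q]),
                   probes),
      Omega = setNames(lapply(seq_along(probes),
                              function(q) res$probe_Omega[, q]), probes)),
    diagnostics = list(energy_resid = as.numeric(res$energy_resid),
                       cg_iters = as.numeric(res$cg_iters)),
    settings = settings, dims = dims, spacing = phantom$spacing
  ), class = "field_history")
}

#' @export
print.field_history <- function(x, ...) {
  cat(sprintf("field_history: %d snapshots over %.1f s, %d probes\n",
              length(x$times), max(x$times), length(x$probes$T)))
  cat(sprintf("max energy residual %.2e, max CG iterations %d\n",
              max(x$diagnostics$energy_resid),
              as.integer(max(x$diagnostics$cg_iters))))
  invisible(x)
}

#' Grid refinement to asymptotic convergence
#'
#' Re-solves the same physical problem at successively finer voxel spacings
#' until the monitored probe temperature at the end time changes by less
#' than `tol` between consecutive levels (the seed--tissue interface probe by
#' default). A sequence of level-over-level changes that grows across three
#' consecutive refinements signals a divergent configuration and raises an
#' error.
#'
#' @param make_problem function(spacing) returning
#'   `list(phantom, source, settings)`.
#' @param spacings decreasing vector of voxel spacings to try, m.
#' @param tol convergence tolerance on the probe temperature, K; `Inf`
#'   returns after the first solve.
#' @param probe probe name to monitor.
#' @return list with `history` (finest solved level), `report` (data.frame:
#'   spacing, T_end, delta) and `converged`.
#' @export
refine_to_asymptote <- function(make_problem, spacings, tol, probe = "interface") {
  stopifnot(length(spacings) >= 1, all(diff(spacings) < 0), tol > 0)
  report <- data.frame(spacing = numeric(0), T_end = numeric(0),
                       delta = numeric(0))
  history <- NULL
  prev <- NA_real_
  for (h in spacings) {
    prob <- make_problem(h)
    history <- solve_bioheat(prob$phantom, prob$source, prob$settings,
                             probes = probe)
    Tend <- tail_value(history$probes$T[[probe]])
    delta <- abs(Tend - prev)
    report <- rbind(report,
                    data.frame(spacing = h, T_end = Tend, delta = delta))
    n <- nrow(report)
    if (n >= 4 && all(diff(report$delta[(n - 2):n]) > 0))
      stop("non-monotone divergence across 3 refinements")
    if (is.infinite(tol) || (n >= 2 && delta < tol))
      return(list(history = history, report = report,
                  converged = !is.infinite(tol)))
    prev <- Tend
  }
  list(history = history, report = report, converged = FALSE)
}

tail_value <- function(x) x[length(x)]
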