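#' Synthetic heating-curve generator specification
#'
#' Parameters of the saturating-exponential curve family used to emulate
#' IR-camera heating records: a fast initial rise approaching a plateau,
#' with additive i.i.d. Gaussian measurement noise.
#'
#' @param baseline starting temperature, degC.
#' @param rise plateau rise above baseline, degC (>= 0).
#' @param tau time constant, s (> 0).
#' @param noise_sd measurement noise standard deviation, degC (>= 0).
#' @param rate_hz sampling rate, Hz.
#' @param duration record length, s.
#' @param seed RNG seed (integer); the generator is deterministic given the
#'   seed.
#' @return a `curve_spec`.
#' @export
curve_spec <- function(baseline = 25, rise = 27.46, tau = 180,
                       noise_sd = 0.1, rate_hz = 1, duration = 300,
                       seed = 1L) {
  stopifnot(rise >= 0, tau > 0, noise_sd >= 0, rate_hz > 0, duration > 0)
  structure(list(baseline = baseline, rise = rise, tau = tau,
                 noise_sd = noise_sd, rate_hz = rate_hz,
                 duration = duration, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic heating curve with known ground truth
#'
#' `T(t) = baseline + rise (1 - exp(-t/tau)) + noise`. The returned curve
#' carries a `ground_truth` attribute recording every generating parameter
#' plus the analytic initial slope `rise / tau`, so downstream expected
#' values need no re-derivation.
#'
#' @param spec a [curve_spec].
#' @param ... metadata forwarded to [heating_curve()] (label, P0, A810,
#'   m_w, c_p).
#' @return a `heating_curve` with attribute `ground_truth`.
#' @export
make_heating_curve <- function(spec = curve_spec(), ...) {
  tt <- seq(0, spec$duration, by = 1 / spec$rate_hz)
  clean <- spec$baseline + spec$rise * (1 - exp(-tt / spec$tau))
  noise <- if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    rnorm(length(tt), 0, spec$noise_sd)
  } else 0
  cv <- heating_curve(tt, clean + noise, ...)
  attr(cv, "ground_truth") <- c(unclass(spec),
                                list(slope0 = spec$rise / spec$tau))
  cv
}

#' Constant-temperature trace for damage-model round trips
#'
#' @param T_K constant temperature, K.
#' @param duration total time, s (>= 0).
#' @param dt step, s (> 0).
#' @return list with `times` (s) and `temps` (K), suitable for
#'   [integrate_damage()].
#' @export
make_constant_T_history <- function(T_K, duration, dt) {
  stopifnot(dt > 0, duration >= 0)
  times <- seq(0, duration, by = dt)
  if (tail_value(times) < duration) times <- c(times, duration)
  list(times = times, temps = rep(T_K, length(times)))
}

#' Toy phantoms with attached analytic references
#'
#' Small grids (at most 40^3 voxels) for solver verification:
#' * `"slab"` -- a single-material bar with fixed-temperature x ends and
#'   insulated lateral faces; under a uniform volumetric source `Q` the
#'   steady maximum rise over the end temperature is `Q L^2 / (8 lambda)`.
#' * `"single-seed"` -- one cylindrical photoseed centred in uniform gland;
#'   reference property: temperature decays monotonically with distance
#'   from the seed axis.
#' * `"water-model"` -- the bench validation model at default configuration.
#'
#' @param kind phantom kind.
#' @param material slab material label (slab only).
#' @param L slab length along x, m (slab only).
#' @param spacing voxel spacing, m.
#' @param Q uniform source for the slab reference, W m^-3.
#' @return list with `phantom` and `reference` (closed form or property
#'   description; for the slab, `reference$max_rise(Q)` gives the steady
#'   centre rise).
#' @export
make_toy_phantom <- function(kind = c("slab", "single-seed", "water-model"),
                             material = "fat", L = 0.02, spacing = 1e-3,
                             Q = 1e4) {
  kind <- match.arg(kind)
  if (kind == "slab") {
    mats <- material_table()
    # the conduction closed form assumes no perfusion or metabolic heat
    th <- mats[[material]]$thermo
    mats[[material]]$thermo <- thermo_properties(
      c = th$c, lambda_37 = th$lambda_37, rho = th$rho,
      q_met = 0, omega_b0 = 0)
    nx <- as.integer(round(L / spacing))
    dims <- c(nx, 3L, 3L)
    labels <- array(material, dim = dims)
    ph <- new_tissue_phantom(
      dims, spacing, labels, mats,
      probes = list(P1 = c(L / 2, 1.5 * spacing, 1.5 * spacing)),
      fluence_kernel = setNames(material, material))
    lam <- mats[[material]]$thermo$lambda_37
    list(phantom = ph,
         reference = list(
           max_rise = function(Qv = Q) Qv * L^2 / (8 * lam),
           lambda = lam, L = L))
  } else if (kind == "single-seed") {
    # odd voxel count keeps the single seed axis on a voxel centre
    cfg <- breast_phantom_config(block = c(0.031, 0.031, 0.031),
                                 spacing = spacing,
                                 fat_thickness = 0.005,
                                 seed_rows = 1, seed_cols = 1,
                                 seed = photoseed_spec(L = 0.015))
    list(phantom = build_breast_phantom(cfg),
         reference = list(property = "monotone radial decay from the seed"))
  } else {
    list(phantom = build_water_model(),
         reference = list(property = "bench validation defaults"))
  }
}
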