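#' Laser power actually absorbed by a sample of given absorbance
#'
#' `P_abs = P0 (1 - 10^-A810)`, the decadic absorbed fraction that both the
#' calorimetry energy balance and the bench validation model use.
#'
#' @param P0 incident power, W.
#' @param A810 absorbance at 810 nm.
#' @return absorbed power, W.
#' @export
absorbed_power <- function(P0, A810) {
  stopifnot(P0 >= 0, A810 >= 0)
  P0 * (1 - 10^(-A810))
}

#' Assemble a run configuration
#'
#' @param phantom phantom configuration, see [breast_phantom_config()].
#' @param P0 laser power, W (a single value; see [run_sweep()] for power
#'   sweeps).
#' @param solver solver settings, see [solver_settings()].
#' @param damage_threshold lesion threshold on Omega.
#' @param outdir output directory (`NULL` disables file output).
#' @param write_vtk also write field snapshots as VTK files.
#' @param seed RNG seed recorded in the manifest (the simulation itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = breast_phantom_config(), P0 = 1,
                       solver = solver_settings(),
                       damage_threshold = 1, outdir = NULL,
                       write_vtk = FALSE, seed = 1L) {
  stopifnot(length(P0) == 1, P0 >= 0)
  structure(list(phantom = phantom, P0 = P0, solver = solver,
                 damage_threshold = damage_threshold, outdir = outdir,
                 write_vtk = write_vtk, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Nested sections `phantom`, `beam`, `solver`, `output` map onto the
#' corresponding constructor arguments; every recognised key is validated by
#' the constructors before any compute.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(breast_phantom_config, as_numeric_list(y$phantom))
  sv <- do.call(solver_settings, as_numeric_list(y$solver))
  run_config(phantom = ph,
             P0 = if (!is.null(y$beam$P0)) y$beam$P0 else 1,
             solver = sv,
             damage_threshold = y$damage$threshold %||% 1,
             outdir = y$output$dir,
             write_vtk = isTRUE(y$output$vtk),
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_numeric_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) if (is.list(v)) as_numeric_list(v) else v)
}

fnv_hash <- function(x) {
  # tiny rolling hash over the deparsed object; fingerprints a config
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_probe_csv <- function(history, path) {
  d <- data.frame(time_s = history$probes$time)
  for (nm in names(history$probes$T)) {
    d[[paste0("T_K_", nm)]] <- history$probes$T[[nm]]
    d[[paste0("Omega_", nm)]] <- history$probes$Omega[[nm]]
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, path, extra = list()) {
  m <- c(list(package = "photoseed",
              version = as.character(utils::packageVersion("photoseed")),
              config_hash = fnv_hash(unclass(config)),
              seed = config$seed,
              config = rapply(unclass(config), unclass, how = "replace")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Run the in-vivo photoseed heating simulation
#'
#' Executes the three-stage pipeline: (i) fluence field under the diffusion
#' approximation, (ii) Pennes bioheat integration with the fluence-derived
#' volumetric source, (iii) Arrhenius damage (accumulated concurrently and
#' summarised into lesion metrics). The beam enters the centre of the z = 0
#' face travelling +z, normally incident over the seed array. When `outdir`
#' is set, writes the probe-trace CSV, a lesion-metric CSV, a JSON run
#' manifest, and (optionally) VTK snapshots.
#'
#' @param config a [run_config()].
#' @return list with `history`, `metrics`, `phantom`, `beam`, `files`.
#' @export
run_invivo <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  phantom <- build_breast_phantom(config$phantom)
  blk <- config$phantom$block
  beam <- laser_beam(config$P0, c(blk[1] / 2, blk[2] / 2, 0), c(0, 0, 1))
  src <- if (config$P0 > 0)
    heat_source(fluence(phantom, beam), phantom) else 0
  history <- solve_bioheat(phantom, src, config$solver)
  metrics <- lesion_metrics(history, phantom, config$damage_threshold)

  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(config$outdir, x)
    write_probe_csv(history, fp("probes.csv"))
    write.csv(data.frame(P0_W = config$P0,
                         time_s = max(history$probes$time),
                         lesion_volume_m3 = metrics$lesion_volume_m3,
                         t_omega1_P1_s = metrics$t_cross_s[["P1"]]),
              fp("lesion.csv"), row.names = FALSE)
    write_manifest(config, fp("manifest.json"),
                   extra = list(stage = "invivo"))
    files <- c(fp("probes.csv"), fp("lesion.csv"), fp("manifest.json"))
    if (config$write_vtk) {
      for (s in seq_along(history$times)) {
        p <- fp(sprintf("T_%04.0fs.vtk", history$times[s]))
        write_field_vtk(history$T[[s]], phantom$spacing, p, "temperature_K")
        q <- fp(sprintf("Omega_%04.0fs.vtk", history$times[s]))
        write_field_vtk(history$Omega[[s]], phantom$spacing, q, "Omega")
        files <- c(files, p, q)
      }
    }
  }
  list(history = history, metrics = metrics, phantom = phantom, beam = beam,
       files = files)
}

#' Run a laser-power sweep of the in-vivo simulation
#'
#' @param config base [run_config()]; its `P0` is ignored.
#' @param P0_values powers to simulate, W.
#' @return list with `runs` (one [run_invivo()] result per power) and
#'   `summary` (data.frame keyed by P0).
#' @export
run_sweep <- function(config = run_config(), P0_values = c(0.5, 1, 1.5, 2)) {
  stopifnot(all(P0_values > 0))
  runs <- lapply(P0_values, function(p) {
    cfg <- config
    cfg$P0 <- p
    if (!is.null(cfg$outdir))
      cfg$outdir <- file.path(cfg$outdir, sprintf("P0_%.1fW", p))
    run_invivo(cfg)
  })
  names(runs) <- sprintf("%.1f", P0_values)
  summary <- data.frame(
    P0_W = P0_values,
    lesion_volume_m3 = vapply(runs, function(r)
      r$metrics$lesion_volume_m3, numeric(1)),
    T_P1_end_K = vapply(runs, function(r)
      tail_value(r$history$probes$T$P1), numeric(1)),
    t_omega1_P1_s = vapply(runs, function(r)
      r$metrics$t_cross_s[["P1"]], numeric(1)))
  list(runs = runs, summary = summary)
}

#' Run the bench validation simulation (cubic seed in water)
#'
#' Builds the water model, deposits the absorbed laser power
#' `P0 (1 - 10^-A810)` uniformly within the seed volume (water is essentially
#' transparent and non-scattering at 810 nm, so the turbid-tissue diffusion
#' kernel does not apply here), and integrates conduction from a 25 degC
#' baseline with a convective outer boundary. The traced `bottom` probe sits
#' at the centre of the seed's bottom face, matching where the bench
#' measurement was taken.
#'
#' @param water water-model configuration, see [water_model_config()].
#' @param P0 laser power, W.
#' @param duration exposure, s (default 5 min).
#' @param dt time step, s.
#' @param h_conv convective film coefficient at the outer boundary,
#'   W m^-2 K^-1.
#' @param T_amb ambient (and initial) temperature, K (default 25 degC).
#' @param measured_csv optional path to a measured heating-curve CSV
#'   (columns `time_s`, `temp_C`) to pair with the prediction.
#' @param outdir optional output directory.
#' @return list with `history`, `trace` (data.frame time_s, temp_C),
#'   `measured` (or NULL), `phantom`, `files`.
#' @export
run_validation <- function(water = water_model_config(), P0 = 1,
                           duration = 300, dt = 0.5, h_conv = 10,
                           T_amb = 298.15, measured_csv = NULL,
                           outdir = NULL) {
  phantom <- build_water_model(water)
  src <- array(0, dim = phantom$dims)
  if (P0 > 0) {
    if (is.null(phantom$seeds))
      stop("validation run needs a seed in the water model")
    seed_mask <- phantom$labels == "seed"
    v_seed <- sum(seed_mask) * phantom$spacing^3
    src[seed_mask] <- absorbed_power(P0, phantom$seeds$spec$A810) / v_seed
  }
  settings <- solver_settings(
    dt = dt, duration = duration, T_init = T_amb, Tb = T_amb,
    bc = bc_spec("convective", h = h_conv, T_amb = T_amb),
    coupling = "one-way", snapshot_cadence = Inf)
  history <- solve_bioheat(phantom, src, settings, probes = "bottom")
  trace <- data.frame(time_s = history$probes$time,
                      temp_C = history$probes$T$bottom - 273.15)
  measured <- if (!is.null(measured_csv))
    read_heating_curve(measured_csv, label = "measured") else NULL

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(outdir, "validation_trace.csv")
    write.csv(trace, p, row.names = FALSE)
    files <- p
  }
  list(history = history, trace = trace, measured = measured,
       phantom = phantom, files = files)
}

#' Summarise completed runs
#'
#' Lays out lesion metrics of one or more completed in-vivo runs (or a sweep
#' summary) as a readable table; an empty input yields an empty table with a
#' warning.
#'
#' @param results list of [run_invivo()] results (possibly named by power),
#'   or a [run_sweep()] result.
#' @return data.frame, one row per run.
#' @export
report_runs <- function(results) {
  if (!is.null(results$summary)) return(results$summary)
  if (length(results) == 0) {
    warning("no completed runs to report")
    return(data.frame(P0_W = numeric(0), lesion_volume_m3 = numeric(0),
                      T_P1_end_K = numeric(0), t_omega1_P1_s = numeric(0)))
  }
  do.call(rbind, lapply(results, function(r) data.frame(
    P0_W = r$beam$P0,
    lesion_volume_m3 = r$metrics$lesion_volume_m3,
    T_P1_end_K = tail_value(r$history$probes$T$P1),
    t_omega1_P1_s = r$metrics$t_cross_s[["P1"]])))
}

#' First time a probe trace reaches a fraction of its final rise
#'
#' The plateau-timing metric: given a per-step probe temperature trace, the
#' first time the rise over baseline reaches `frac` of the end-of-run rise,
#' by linear interpolation between steps.
#'
#' @param time_s per-step times, s.
#' @param T_K per-step temperatures, K.
#' @param frac fraction of the final rise (default 0.9).
#' @return time, s.
#' @export
time_to_fraction_of_rise <- function(time_s, T_K, frac = 0.9) {
  stopifnot(length(time_s) == length(T_K), frac > 0, frac <= 1)
  rise <- T_K - T_K[1]
  target <- frac * tail_value(rise)
  if (tail_value(rise) <= 0) return(NA_real_)
  i <- which(rise >= target)[1]
  if (i == 1) return(time_s[1])
  time_s[i - 1] + (target - rise[i - 1]) / (rise[i] - rise[i - 1]) *
    (time_s[i] - time_s[i - 1])
}
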