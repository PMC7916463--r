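#' Photothermal heating curve
#'
#' A time--temperature series recorded (or synthesised) during laser
#' irradiation of a sample, with the metadata the lumped calorimetry
#' analysis needs.
#'
#' @param time_s times, s; strictly increasing, starting at 0.
#' @param temp_C temperatures, degC.
#' @param label sample label.
#' @param P0 laser power, W.
#' @param A810 sample absorbance at 810 nm.
#' @param m_w water mass, g.
#' @param c_p specific heat of water, J g^-1 degC^-1.
#' @return An object of class `heating_curve`.
#' @export
heating_curve <- function(time_s, temp_C, label = "sample",
                          P0 = NA_real_, A810 = NA_real_,
                          m_w = 0.5, c_p = 4.185) {
  stopifnot(length(time_s) == length(temp_C), length(time_s) >= 2,
            time_s[1] == 0, all(diff(time_s) > 0))
  structure(list(time_s = as.numeric(time_s), temp_C = as.numeric(temp_C),
                 label = label, P0 = P0, A810 = A810, m_w = m_w, c_p = c_p),
            class = "heating_curve")
}

#' Read a heating curve from CSV
#'
#' Expects a header with columns `time_s` and `temp_C`.
#'
#' @param path CSV file path.
#' @param ... metadata passed to [heating_curve()].
#' @return a `heating_curve`.
#' @export
read_heating_curve <- function(path, ...) {
  d <- read.csv(path)
  if (!all(c("time_s", "temp_C") %in% names(d)))
    stop("format error: CSV must have columns time_s, temp_C")
  heating_curve(d$time_s, d$temp_C, ...)
}

#' Write a heating curve to CSV
#' @param curve a `heating_curve`.
#' @param path output path.
#' @export
write_heating_curve <- function(curve, path) {
  write.csv(data.frame(time_s = curve$time_s, temp_C = curve$temp_C),
            path, row.names = FALSE)
  invisible(path)
}

#' Initial heating rate of a curve
#'
#' Least-squares slope of temperature against time over the initial window
#' (default the first 30 s), the robust estimate of the initial dT/dt that
#' the conversion-efficiency analysis consumes.
#'
#' @param curve a `heating_curve`.
#' @param window window length, s.
#' @return heating rate, degC s^-1.
#' @export
initial_rate <- function(curve, window = 30) {
  stopifnot(window > 0, window <= tail_value(curve$time_s))
  sel <- curve$time_s <= window
  if (sum(sel) < 2) stop("fewer than 2 samples in the rate window")
  unname(coef(lm(curve$temp_C[sel] ~ curve$time_s[sel]))[2])
}

#' Temperature change over the exposure
#'
#' Difference between the final (default t = 5 min, or the configured
#' endpoint) and initial temperatures.
#'
#' @param curve a `heating_curve`.
#' @param t_end endpoint, s; must not exceed the recorded span.
#' @return temperature change, degC.
#' @export
delta_T <- function(curve, t_end = 300) {
  if (t_end > tail_value(curve$time_s))
    stop("endpoint beyond the recorded data")
  i <- which(curve$time_s <= t_end)
  curve$temp_C[tail_value(i)] - curve$temp_C[1]
}

#' Photothermal conversion efficiency (lumped calorimetry)
#'
#' Roper-style energy balance over the initial heating transient:
#' `eta = m_w c_p (dT/dt) / (P0 (1 - 10^-A810))`, the fraction of the
#' absorbed laser power converted to heat in the water mass. Invariant to
#' constant offsets of the temperature trace (only the rate enters).
#'
#' @param curve a `heating_curve` carrying `P0`, `A810`, `m_w`, `c_p`.
#' @param rate initial heating rate, degC s^-1 (default: computed by
#'   [initial_rate()]).
#' @param control_rate optional heating rate of a no-photoseed control to
#'   subtract before the energy balance (off by default).
#' @return efficiency eta, dimensionless.
#' @export
conversion_efficiency <- function(curve, rate = initial_rate(curve),
                                  control_rate = 0) {
  stopifnot(is.finite(curve$P0), curve$P0 > 0, is.finite(curve$A810),
            curve$A810 >= 0)
  if (curve$A810 == 0 && rate > 0)
    stop("A810 = 0 absorbs no light; efficiency undefined for a heating sample")
  absorbed_frac <- 1 - 10^(-curve$A810)
  if (absorbed_frac == 0) return(0)
  curve$m_w * curve$c_p * (rate - control_rate) / (curve$P0 * absorbed_frac)
}

#' Trypan-blue cell-viability arithmetic
#'
#' Implements the viability expression literally as
#' `%CV = (1 - viable/total) * 100`, and always also reports the opposite
#' orientation `viable/total * 100` (`pct_viable`): the source convention is
#' internally contradictory (its prose describes "viable" cells as the
#' dye-positive ones, the reverse of standard trypan-blue semantics), so
#' both readings are returned rather than silently reconciled. The two
#' always sum to 100.
#'
#' @param total total cells counted (> 0).
#' @param viable cells classed viable (0 <= viable <= total).
#' @param control optional `%CV` (literal orientation) of a control
#'   condition; when given, `relative` is the literal value normalised by
#'   it.
#' @return list with `cv_literal`, `pct_viable`, and optionally `relative`.
#' @export
cell_viability <- function(total, viable, control = NULL) {
  stopifnot(total > 0, viable >= 0, viable <= total)
  lit <- (1 - viable / total) * 100
  out <- list(cv_literal = lit, pct_viable = viable / total * 100)
  if (!is.null(control)) out$relative <- lit / control
  out
}

#' Batch calorimetry report
#'
#' Runs the initial-rate / temperature-change / efficiency analysis over a
#' list of heating curves and lays the results out as one row per sample.
#'
#' @param curves list of `heating_curve` objects.
#' @param window rate window, s, see [initial_rate()].
#' @param t_end endpoint for the temperature change, s.
#' @return data.frame with columns `sample`, `P0_W`, `A810`, `dTdt_C_per_s`,
#'   `dT_C`, `eta`.
#' @export
calorimetry_report <- function(curves, window = 30, t_end = 300) {
  rows <- lapply(curves, function(cv) {
    rate <- initial_rate(cv, window)
    data.frame(sample = cv$label, P0_W = cv$P0, A810 = cv$A810,
               dTdt_C_per_s = rate, dT_C = delta_T(cv, t_end),
               eta = if (is.finite(cv$P0) && is.finite(cv$A810) &&
                         cv$A810 > 0)
                 conversion_efficiency(cv, rate) else NA_real_)
  })
  do.call(rbind, rows)
}
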