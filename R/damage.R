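#' Arrhenius injury-model parameters
#'
#' First-order thermal damage kinetics: the damage rate at absolute
#' temperature T is `k(T) = A exp(-Ea / (R T))` and the cumulative damage
#' Omega is its time integral. Omega = 1 denotes complete irreversible cell
#' damage. Defaults are the breast-tissue literature values used throughout
#' the simulations; note `R = 8.3` J mol^-1 K^-1 as adopted by the source
#' model (not 8.314) -- override if preferred.
#'
#' @param A frequency factor, s^-1.
#' @param Ea activation energy, J mol^-1.
#' @param R gas constant, J mol^-1 K^-1.
#' @return An object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(A = 1.18e44, Ea = 3.02e5, R = 8.3) {
  stopifnot(A > 0, Ea > 0, R > 0)
  structure(list(A = A, Ea = Ea, R = R), class = "arrhenius_params")
}

#' Arrhenius damage rate
#'
#' `k(T) = A exp(-Ea/(R T))`, evaluated in log space so it is overflow-safe
#' for any physiological or ablative temperature.
#'
#' @param T absolute temperature(s), K (> 0).
#' @param p [arrhenius_params].
#' @return damage rate(s), s^-1.
#' @export
damage_rate <- function(T, p = arrhenius_params()) {
  stopifnot(all(T > 0))
  exp(log(p$A) - p$Ea / (p$R * T))
}

#' Trapezoidal damage increment over one time step
#'
#' @param T_now,T_prev temperatures at the ends of the step, K.
#' @param dt step length, s (> 0; a zero-length step contributes nothing).
#' @param p [arrhenius_params].
#' @return damage increment(s) dOmega.
#' @export
arrhenius_increment <- function(T_now, T_prev, dt, p = arrhenius_params()) {
  stopifnot(dt >= 0, all(T_now > 0), all(T_prev > 0))
  dt * (damage_rate(T_now, p) + damage_rate(T_prev, p)) / 2
}

#' Integrate damage along a stepped temperature trace
#'
#' Trapezoidal quadrature of the Arrhenius rate over a (time, temperature)
#' trace, as accumulated by the bioheat solver.
#'
#' @param times strictly increasing times, s.
#' @param temps temperatures, K, same length.
#' @param p [arrhenius_params].
#' @return cumulative Omega at each trace point (first entry 0).
#' @export
integrate_damage <- function(times, temps, p = arrhenius_params()) {
  stopifnot(length(times) == length(temps), length(times) >= 1,
            all(diff(times) > 0))
  k <- damage_rate(temps, p)
  n <- length(times)
  if (n == 1) return(0)
  cumsum(c(0, diff(times) * (k[-n] + k[-1]) / 2))
}

#' Constant-temperature time to complete damage
#'
#' Closed form `t = exp(Ea/(R T)) / A` for Omega to reach 1 while held at a
#' constant temperature; evaluated in log space.
#'
#' @param T_const absolute temperature, K.
#' @param p [arrhenius_params].
#' @return time to Omega = 1, s.
#' @examples
#' time_to_unity(323.15)  # ~ 6.7e4 s at 50 degC
#' @export
time_to_unity <- function(T_const, p = arrhenius_params()) {
  stopifnot(all(T_const > 0))
  exp(p$Ea / (p$R * T_const) - log(p$A))
}

#' Lesion metrics from a damage field history
#'
#' Summarises a solved run: lesion volume (voxels with Omega >= `threshold`
#' times the voxel volume), the first time each probe's Omega crosses the
#' threshold (linear interpolation between recorded steps), and the radial
#' damage profile about P1 averaged over spherical shells one voxel spacing
#' wide.
#'
#' @param history a `field_history` from [solve_bioheat()].
#' @param phantom the `tissue_phantom` it was solved on.
#' @param threshold damage threshold (default 1, complete damage).
#' @return list with `lesion_volume_m3`, `t_cross_s` (named, NA where never
#'   crossed), and `radial_profile` (data.frame: r_m, omega).
#' @export
lesion_metrics <- function(history, phantom, threshold = 1) {
  stopifnot(inherits(history, "field_history"))
  omega_end <- history$Omega[[length(history$Omega)]]
  vv <- phantom$spacing^3
  lesion <- sum(omega_end >= threshold) * vv

  t_cross <- vapply(names(history$probes$Omega), function(nm) {
    om <- history$probes$Omega[[nm]]
    tt <- history$probes$time
    i <- which(om >= threshold)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(tt[1])
    # linear interpolation within the step
    tt[i - 1] + (threshold - om[i - 1]) / (om[i] - om[i - 1]) *
      (tt[i] - tt[i - 1])
  }, numeric(1))

  p1 <- phantom$probes$P1
  if (is.null(p1)) stop("phantom has no P1 probe")
  dims <- phantom$dims
  h <- phantom$spacing
  gx <- rep(voxel_centers(phantom, 1), times = dims[2] * dims[3]) - p1[1]
  gy <- rep(rep(voxel_centers(phantom, 2), each = dims[1]),
            times = dims[3]) - p1[2]
  gz <- rep(voxel_centers(phantom, 3), each = dims[1] * dims[2]) - p1[3]
  r <- sqrt(gx^2 + gy^2 + gz^2)
  shell <- floor(r / h)
  prof <- tapply(as.vector(omega_end), shell, mean)
  radial <- data.frame(r_m = (as.numeric(names(prof)) + 0.5) * h,
                       omega = as.numeric(prof))

  list(lesion_volume_m3 = lesion, t_cross_s = t_cross,
       radial_profile = radial)
}
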