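#' Optical properties of a material
#'
#' Bundles the absorption coefficient and reduced scattering coefficient of a
#' turbid medium and derives the standard diffusion-approximation quantities:
#' transport coefficient `mu_tr = mu_a + mu_s_prime`, diffusion coefficient
#' `D = 1 / (3 mu_tr)` and effective attenuation
#' `mu_eff = sqrt(3 mu_a mu_tr)`.
#'
#' @param mu_a absorption coefficient, m^-1 (>= 0).
#' @param mu_s_prime reduced scattering coefficient, m^-1 (>= 0).
#' @return An object of class `optical_properties` with fields `mu_a`,
#'   `mu_s_prime`, `mu_tr`, `D` (m) and `mu_eff` (m^-1).
#' @examples
#' optical_properties(mu_a = 3, mu_s_prime = 950)  # breast fat
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.finite(mu_s_prime))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_prime < 0) stop("mu_s_prime must be >= 0")
  mu_tr <- mu_a + mu_s_prime
  structure(list(
    mu_a = mu_a,
    mu_s_prime = mu_s_prime,
    mu_tr = mu_tr,
    D = if (mu_tr > 0) 1 / (3 * mu_tr) else Inf,
    mu_eff = sqrt(3 * mu_a * mu_tr)
  ), class = "optical_properties")
}

#' Thermo-physical properties of a material
#'
#' @param c specific heat capacity, J kg^-1 K^-1.
#' @param lambda_37 reference thermal conductivity (at the model's reference
#'   temperature), W m^-1 K^-1.
#' @param rho density, kg m^-3.
#' @param q_met metabolic heat generation, W m^-3 (0 for non-living media).
#' @param omega_b0 baseline blood-perfusion coefficient, s^-1 (0 for
#'   non-perfused media such as implants or water).
#' @return An object of class `thermo_properties`.
#' @examples
#' thermo_properties(c = 2960, lambda_37 = 0.48, rho = 1041,
#'                   q_met = 700, omega_b0 = 5e-4)  # gland
#' @export
thermo_properties <- function(c, lambda_37, rho, q_met = 0, omega_b0 = 0) {
  vals <- c(c = c, lambda_37 = lambda_37, rho = rho,
            q_met = q_met, omega_b0 = omega_b0)
  stopifnot(all(is.finite(vals)))
  if (any(vals < 0)) stop("thermo-physical properties must be >= 0")
  structure(as.list(vals), class = "thermo_properties")
}

#' Blood reference properties
#'
#' Density and specific heat of blood used in the Pennes perfusion term
#' (blood carries no conductivity / metabolic / perfusion entries of its
#' own).
#'
#' @return list with `rho_b` (kg m^-3) and `c_b` (J kg^-1 K^-1).
#' @export
blood_properties <- function() list(rho_b = 1050, c_b = 3617)

#' Default material property table
#'
#' Literature optical and thermo-physical property sets for the simulated
#' domains. `fat` and `gland` carry the breast-tissue values used throughout
#' the in-vivo model; `seed` carries PDMS-matrix nanocomposite values
#' (rho = 970 kg m^-3, c = 1460 J kg^-1 K^-1, lambda = 0.16 W m^-1 K^-1,
#' no perfusion, no metabolic heat); `water` and `air` serve the bench
#' validation model. The seed absorption coefficient is not set here -- it is
#' derived from the measured absorbance via [absorbance_to_mua()] when a
#' phantom is built.
#'
#' @return Named list; each entry has `$optical` ([optical_properties] or
#'   `NULL`) and `$thermo` ([thermo_properties]).
#' @export
material_table <- function() {
  list(
    fat = list(
      optical = optical_properties(mu_a = 3, mu_s_prime = 950),
      thermo = thermo_properties(c = 2348, lambda_37 = 0.21, rho = 911,
                                 q_met = 400, omega_b0 = 2e-4)
    ),
    gland = list(
      optical = optical_properties(mu_a = 6, mu_s_prime = 1100),
      thermo = thermo_properties(c = 2960, lambda_37 = 0.48, rho = 1041,
                                 q_met = 700, omega_b0 = 5e-4)
    ),
    seed = list(
      optical = NULL,  # mu_a from absorbance; no scattering data exists
      thermo = thermo_properties(c = 1460, lambda_37 = 0.16, rho = 970,
                                 q_met = 0, omega_b0 = 0)
    ),
    water = list(
      optical = NULL,
      thermo = thermo_properties(c = 4185, lambda_37 = 0.60, rho = 998,
                                 q_met = 0, omega_b0 = 0)
    ),
    air = list(
      optical = NULL,
      thermo = thermo_properties(c = 1005, lambda_37 = 0.026, rho = 1.2,
                                 q_met = 0, omega_b0 = 0)
    )
  )
}
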