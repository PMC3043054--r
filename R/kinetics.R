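# Debye screening and Debye-Smoluchowski diffusion-limited association
# rates for an ion + protein pair, with the screened-Coulomb interaction
# folded into an effective encounter radius.
#
# Physical constants: CODATA 2018.

.const <- list(
  e = 1.602176634e-19,        # C
  kB = 1.380649e-23,          # J/K
  Avo = 6.02214076e23,        # 1/mol
  eps0 = 8.8541878128e-12     # F/m
)

#' Debye screening length
#'
#' `kappa^-1 = sqrt(eps eps0 kB T / (2 NA e^2 I 1e3))` for a symmetric
#' electrolyte of ionic strength `I` (mol/L). Zero ionic strength returns
#' `Inf` (unscreened Coulomb).
#'
#' @param ionic_strength mol/L, >= 0.
#' @param temperature K.
#' @param permittivity relative permittivity of the solvent (default 78.5,
#'   water at 300 K).
#' @return Debye length in nm.
#' @export
debye_length <- function(ionic_strength, temperature = 300,
                         permittivity = 78.5) {
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  if (ionic_strength == 0) return(Inf)
  with(.const, {
    lam2 <- permittivity * eps0 * kB * temperature /
      (2 * Avo * e^2 * ionic_strength * 1e3)  # m^2
    sqrt(lam2) * 1e9
  })
}

# Bjerrum length in nm
bjerrum_length <- function(temperature = 300, permittivity = 78.5) {
  with(.const,
       e^2 / (4 * pi * permittivity * eps0 * kB * temperature) * 1e9)
}

#' Debye-Smoluchowski parameter set
#'
#' @param D_ion,D_protein diffusion coefficients, cm^2/s.
#' @param contact_radius encounter (reaction) radius R, nm.
#' @param charge_product product of the effective charges z1*z2
#'   (dimensionless; negative = attraction).
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param permittivity relative solvent permittivity.
#' @return list of class `"ds_parameters"`.
#' @export
ds_parameters <- function(D_ion, D_protein = 0, contact_radius,
                          charge_product = 0, ionic_strength = 0.150,
                          temperature = 300, permittivity = 78.5) {
  if (D_ion < 0 || D_protein < 0) stop("diffusion coefficients must be >= 0")
  if (contact_radius <= 0) stop("contact_radius must be > 0")
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  structure(list(D_ion = D_ion, D_protein = D_protein,
                 contact_radius = contact_radius,
                 charge_product = charge_product,
                 ionic_strength = ionic_strength,
                 temperature = temperature, permittivity = permittivity),
            class = "ds_parameters")
}

#' Debye-Smoluchowski association rate
#'
#' Diffusion-limited bimolecular rate
#' `k = 4 pi (D1 + D2) R_eff NA 1e-3` (M^-1 s^-1), where the effective
#' radius absorbs the interaction potential:
#' `1/R_eff = integral_R^inf exp(U(r)/kBT) / r^2 dr` with the screened
#' Coulomb (Debye-Hueckel) potential
#' `U(r)/kBT = z1 z2 lB exp(-kappa (r - R)) / (r (1 + kappa R))`.
#' For `z1 z2 = 0` this reduces exactly to the Smoluchowski limit
#' `R_eff = R`. The integral is evaluated by adaptive quadrature
#' (`stats::integrate`, relative tolerance `tol`).
#'
#' @param params a [ds_parameters()] object.
#' @param tol relative quadrature tolerance.
#' @return list of class `"ds_rate"`: `k_on` (M^-1 s^-1), `R_eff` (nm),
#'   `debye_length` (nm), `params`.
#' @export
ds_rate <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "ds_parameters"))
  R <- params$contact_radius
  z12 <- params$charge_product
  lB <- bjerrum_length(params$temperature, params$permittivity)
  lD <- debye_length(params$ionic_strength, params$temperature,
                     params$permittivity)
  kap <- if (is.finite(lD)) 1 / lD else 0
  if (z12 == 0) {
    R_eff <- R
  } else {
    u_over_kT <- function(r)
      z12 * lB * exp(-kap * (r - R)) / (r * (1 + kap * R))
    ig <- stats::integrate(function(r) exp(u_over_kT(r)) / r^2,
                           lower = R, upper = Inf, rel.tol = tol,
                           subdivisions = 1000L)
    if (ig$message != "OK")
      stop("quadrature did not converge: ", ig$message)
    R_eff <- 1 / ig$value
  }
  Dsum_cm2 <- params$D_ion + params$D_protein
  # 4 pi D R NA, D in cm^2/s, R in cm, then cm^3/(mol s) -> M^-1 s^-1
  k <- 4 * pi * Dsum_cm2 * (R_eff * 1e-7) * .const$Avo * 1e-3
  structure(list(k_on = k, R_eff = R_eff, debye_length = lD,
                 params = params), class = "ds_rate")
}

#' @export
print.ds_rate <- function(x, ...) {
  cat(sprintf("Debye-Smoluchowski rate: k_on = %.4g M^-1 s^-1\n", x$k_on))
  cat(sprintf("  R = %g nm, R_eff = %.4g nm, Debye length = %s nm, z1z2 = %g\n",
              x$params$contact_radius, x$R_eff,
              format(x$debye_length, digits = 4),
              x$params$charge_product))
  invisible(x)
}

#' Pseudo-first-order encounter rate
#'
#' At ligand concentration `C`, the apparent rate is `k_on * C` and the mean
#' time between encounters its reciprocal.
#'
#' @param k_on bimolecular rate, M^-1 s^-1 (a `ds_rate` object is accepted).
#' @param concentration mol/L, > 0.
#' @return list with `rate` (s^-1) and `mean_interval_ns` (ns).
#' @export
pseudo_first_order <- function(k_on, concentration) {
  if (inherits(k_on, "ds_rate")) k_on <- k_on$k_on
  if (concentration <= 0)
    stop("concentration must be > 0: encounter interval undefined at C = 0")
  rate <- k_on * concentration
  list(rate = rate, mean_interval_ns = 1e9 / rate)
}
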