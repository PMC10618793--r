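# Closed-form 1:1 Langmuir interaction model.
#
# The association phase solves dR/dt = kon * C * (Rmax - R) - koff * R with
# R(0) = 0, giving R(t) = Req * (1 - exp(-(kon*C + koff) * t)) where
# Req = C * Rmax / (C + KD) and KD = koff / kon. The dissociation phase is a
# single exponential decay from the response at injection end.

#' Association-phase response of the 1:1 Langmuir model
#'
#' Analytic solution of `dR/dt = k_on * C * (R_max - R) - k_off * R` with
#' `R(0) = 0`: the response-unit (RU) signal while analyte at concentration
#' `C` flows over the surface.
#'
#' @param t Time since injection start, seconds. Vectorised.
#' @param C Analyte concentration, molar. `C = 0` returns 0 for all `t`.
#' @param k_on Association rate constant, 1/(M*s). Must be positive.
#' @param k_off Dissociation rate constant, 1/s. Must be positive.
#' @param R_max Surface capacity, RU. Must be positive.
#'
#' @return Numeric vector of responses in RU, same length as `t`.
#'
#' @examples
#' # half-saturation: at C = KD the plateau is R_max / 2
#' association_response(1e4, C = 4.5e-6, k_on = 1.099e5, k_off = 0.4947,
#'                      R_max = 200)
#' @seealso [dissociation_response()], [steady_state_response()]
#' @export
association_response <- function(t, C, k_on, k_off, R_max) {
  check_positive(k_on = k_on, k_off = k_off, R_max = R_max)
  check_nonnegative(t = t, C = C)
  if (all(C == 0)) {
    return(rep(0, length(t)))
  }
  K_D <- k_off / k_on
  Req <- C * R_max / (C + K_D)
  Req * (1 - exp(-(k_on * C + k_off) * t))
}

#' Dissociation-phase response of the 1:1 Langmuir model
#'
#' Exponential decay `R0 * exp(-k_off * t)` from the response at the end of
#' the association phase, with `t` measured from injection end.
#'
#' @param t Time since injection end, seconds. Vectorised.
#' @param R0 Response at injection end, RU (>= 0).
#' @param k_off Dissociation rate constant, 1/s (> 0).
#'
#' @return Numeric vector of responses in RU.
#' @export
dissociation_response <- function(t, R0, k_off) {
  check_positive(k_off = k_off)
  check_nonnegative(t = t, R0 = R0)
  R0 * exp(-k_off * t)
}

#' Equilibrium (steady-state) binding response
#'
#' The Langmuir isotherm `Req = C * R_max / (C + K_D)`: the plateau response
#' approached at long contact times, used by the steady-state affinity
#' analysis.
#'
#' @param C Analyte concentration, molar (>= 0). Vectorised.
#' @param K_D Equilibrium dissociation constant, molar (> 0).
#' @param R_max Surface capacity, RU.
#'
#' @return Numeric vector of equilibrium responses in RU.
#' @export
steady_state_response <- function(C, K_D, R_max) {
  check_positive(K_D = K_D)
  check_nonnegative(C = C)
  C * R_max / (C + K_D)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_D = k_off / k_on`. The irreversible-binding limit `k_off = 0` gives 0.
#'
#' @param k_on Association rate constant, 1/(M*s) (> 0). Vectorised.
#' @param k_off Dissociation rate constant, 1/s (>= 0).
#'
#' @return Equilibrium dissociation constant(s) in molar.
#'
#' @examples
#' compute_kd(1.099e5, 0.4947) # BX430 on P2X4: 4.50e-6 M
#' @export
compute_kd <- function(k_on, k_off) {
  check_positive(k_on = k_on)
  check_nonnegative(k_off = k_off)
  k_off / k_on
}

#' Theoretical maximal response for a given immobilization level
#'
#' The stoichiometric capacity of an SPR surface:
#' `R_max = (MW_analyte / MW_ligand) * immobilized * stoichiometry`, where
#' "ligand" is the immobilized binding partner (SPR convention) and
#' "analyte" the flowed compound. For a ~29 kDa receptor ectodomain
#' immobilized at 16,000-18,000 RU, cannabinoid analytes of 286-330 g/mol
#' give theoretical capacities of roughly 160-200 RU.
#'
#' @param mw_analyte Analyte molecular weight, g/mol (> 0). Vectorised.
#' @param mw_ligand Immobilized ligand molecular weight, g/mol (> 0).
#' @param immobilized Immobilization level, RU (> 0).
#' @param stoichiometry Binding sites per ligand molecule (default 1).
#'
#' @return Theoretical `R_max` in RU.
#' @export
theoretical_rmax <- function(mw_analyte, mw_ligand, immobilized,
                             stoichiometry = 1) {
  check_positive(mw_analyte = mw_analyte, mw_ligand = mw_ligand,
                 immobilized = immobilized, stoichiometry = stoichiometry)
  (mw_analyte / mw_ligand) * immobilized * stoichiometry
}

# Piecewise model for a full cycle: association on [0, t_assoc], dissociation
# afterwards. `t` is seconds from association start.
langmuir_cycle_response <- function(t, C, k_on, k_off, R_max, t_assoc) {
  r <- numeric(length(t))
  assoc <- t <= t_assoc
  r[assoc] <- association_response(t[assoc], C, k_on, k_off, R_max)
  if (any(!assoc)) {
    R0 <- association_response(t_assoc, C, k_on, k_off, R_max)
    r[!assoc] <- dissociation_response(t[!assoc] - t_assoc, R0, k_off)
  }
  r
}

# --- thermodynamics ---------------------------------------------------------

# Gas constant in kcal/(mol*K)
R_GAS_KCAL <- 1.98720e-3

#' Convert binding free energy to an inhibition constant
#'
#' `Ki = exp(dG / (R * T))` with `R = 1.98720e-3` kcal/(mol K). A docking
#' score of -7.14 kcal/mol at 298.15 K corresponds to Ki of about 5.9 uM.
#'
#' @param dG Binding free energy, kcal/mol (negative for favourable binding).
#' @param temperature Absolute temperature, K (default 298.15).
#'
#' @return Inhibition constant in molar.
#' @seealso [energy_from_inhibition_constant()] for the inverse.
#' @export
inhibition_constant_from_energy <- function(dG, temperature = 298.15) {
  check_positive(temperature = temperature)
  exp(dG / (R_GAS_KCAL * temperature))
}

#' Convert an inhibition constant to a binding free energy
#'
#' Inverse of [inhibition_constant_from_energy()]:
#' `dG = R * T * log(Ki)`.
#'
#' @param Ki Inhibition constant, molar (> 0).
#' @param temperature Absolute temperature, K (default 298.15).
#'
#' @return Binding free energy in kcal/mol.
#' @export
energy_from_inhibition_constant <- function(Ki, temperature = 298.15) {
  check_positive(temperature = temperature, Ki = Ki)
  R_GAS_KCAL * temperature * log(Ki)
}
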