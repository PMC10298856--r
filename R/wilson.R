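#' Wilson local-composition model for a binary liquid
#'
#' `wilson_gibbs()` returns the dimensionless excess molar Gibbs energy
#' \deqn{G^E_m/RT = -x_1\ln(x_1 + \Lambda_{12}x_2) - x_2\ln(x_2 +
#' \Lambda_{21}x_1),}
#' and `wilson_activity()` the activity coefficients obtained from its
#' composition derivative,
#' \deqn{\ln\gamma_1 = -\ln(x_1+\Lambda_{12}x_2) + x_2\left[
#'  \frac{\Lambda_{12}}{x_1+\Lambda_{12}x_2} -
#'  \frac{\Lambda_{21}}{\Lambda_{21}x_1+x_2}\right]}
#' (and symmetrically for \eqn{\gamma_2} with the bracket sign reversed).
#' Both satisfy \eqn{x_1\ln\gamma_1 + x_2\ln\gamma_2 = G^E/RT} identically
#' and the Gibbs-Duhem relation at fixed temperature.
#'
#' @param x1 Mole fraction(s) of component 1 in the liquid.
#' @param Lambda12,Lambda21 Wilson parameters (positive).
#' @return `wilson_gibbs()`: \eqn{G^E/RT} (multiply by `R_GAS * T` for
#'   J/mol); `wilson_activity()`: tibble with `gamma1`, `gamma2`.
#' @examples
#' # equimolar excess Gibbs energy at 298.15 K with the study's parameters
#' 8.314462618 * 298.15 * wilson_gibbs(0.5, 0.4815, 0.5434)
#' @export
wilson_gibbs <- function(x1, Lambda12, Lambda21) {
  stopifnot(all(x1 >= 0 & x1 <= 1), Lambda12 > 0, Lambda21 > 0)
  x2 <- 1 - x1
  # endpoints give 0 * log(1) = 0 exactly
  -(x1 * log(x1 + Lambda12 * x2) + x2 * log(x2 + Lambda21 * x1))
}

#' @rdname wilson_gibbs
#' @export
wilson_activity <- function(x1, Lambda12, Lambda21) {
  stopifnot(all(x1 >= 0 & x1 <= 1), Lambda12 > 0, Lambda21 > 0)
  x2 <- 1 - x1
  d1 <- x1 + Lambda12 * x2
  d2 <- x2 + Lambda21 * x1
  brk <- Lambda12 / d1 - Lambda21 / d2
  tibble::tibble(gamma1 = exp(-log(d1) + x2 * brk),
                 gamma2 = exp(-log(d2) - x1 * brk))
}

#' Interconvert Wilson parameters and interaction-energy differences
#'
#' The Wilson parameters combine the molar-volume ratio with interaction
#' energies: \eqn{\Lambda_{ij} = (V_j^0/V_i^0)\exp[-(\lambda_{ij} -
#' \lambda_{ii})/RT]}. `wilson_energies()` inverts this to the energy
#' differences (J/mol); `wilson_lambdas()` is the exact forward map. The
#' round trip is the identity.
#'
#' @param Lambda12,Lambda21 Wilson parameters.
#' @param dlam12_11,dlam12_22 \eqn{\lambda_{12}-\lambda_{11}} and
#'   \eqn{\lambda_{12}-\lambda_{22}}, J/mol.
#' @param V1,V2 Molar volumes of the two components at `T_K`, m^3/mol.
#' @param T_K Temperature, K.
#' @return A tibble with the converted pair.
#' @examples
#' wilson_energies(0.4815, 0.5434, 76.93e-6, 167.7e-6, 298.15)
#' @export
wilson_energies <- function(Lambda12, Lambda21, V1, V2, T_K) {
  stopifnot(Lambda12 > 0, Lambda21 > 0, V1 > 0, V2 > 0, T_K > 0)
  tibble::tibble(
    dlam12_11 = -R_GAS * T_K * log(Lambda12 * V1 / V2),
    dlam12_22 = -R_GAS * T_K * log(Lambda21 * V2 / V1))
}

#' @rdname wilson_energies
#' @export
wilson_lambdas <- function(dlam12_11, dlam12_22, V1, V2, T_K) {
  stopifnot(V1 > 0, V2 > 0, T_K > 0)
  tibble::tibble(
    Lambda12 = (V2 / V1) * exp(-dlam12_11 / (R_GAS * T_K)),
    Lambda21 = (V1 / V2) * exp(-dlam12_22 / (R_GAS * T_K)))
}
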