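#' Bundled study dataset: (2-propanol + 1,8-cineole)
#'
#' Plain-text fixtures with the complete experimental record of the
#' isothermal study of the binary liquid mixture
#' 2-propanol (1) + 1,8-cineole (2): pure-liquid molar volumes and vapor
#' pressures (278.15-323.15 K), ten isothermal P-x curves of twelve points
#' each, excess molar enthalpies and densities at four temperatures, and the
#' study's own reported reductions (Wilson parameters, Redlich-Kister
#' coefficients, EoS interaction-parameter fits) for cross-checking.
#'
#' @details
#' * `pure_liquid_data()`: one row per temperature with molar volume
#'   (cm^3/mol) and vapor pressure (Pa) of both pure liquids; the
#'   experimental 2-propanol pressures are accompanied by the literature
#'   values they were compared against.
#' * `vle_data()`: long table of the ten isotherms: `T_K`, `x2` (liquid mole
#'   fraction of 1,8-cineole), measured `P_Pa`, and the study's reported
#'   reduction columns `dP_Pa`, `gamma1`, `gamma2`, `GE_Jmol` (useful as
#'   reference values; they are outputs of the original reduction, not
#'   measurements).
#' * `excess_enthalpy_data()`: `T_K`, `x2`, `HE_Jmol` at four temperatures,
#'   including the zero endpoints.
#' * `density_data()`: `T_K`, `x2`, `rho_kgm3` at four temperatures,
#'   including the pure-liquid endpoint rows.
#' * `wilson_reference()`: the study's fitted Wilson parameters per isotherm
#'   with standard deviations and interaction-energy differences (values in
#'   parentheses in the original table are the linear-in-T trend values,
#'   columns `*_trend_Jmol`).
#' * `rk_reference()`: the study's Redlich-Kister coefficients and standard
#'   deviations for excess enthalpy (J/mol) and excess volume (cm^3/mol).
#' * `kij_coefficients()`: quadratic temperature-dependence coefficients
#'   (a, b, c) of the binary interaction parameter
#'   \eqn{k_{ij} = a + bT + cT^2} for each equation of state, with the
#'   regression coefficient as attribute `"R2"`.
#'
#' @return A tibble (or for `kij_coefficients()` a named numeric vector).
#' @name study_data
NULL

.read_fixture <- function(file) {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", file, package = "vlemix", mustWork = TRUE)))
}

#' @rdname study_data
#' @export
pure_liquid_data <- function() .read_fixture("pure_liquids.csv")

#' @rdname study_data
#' @export
vle_data <- function() .read_fixture("vle_px.csv")

#' @rdname study_data
#' @export
excess_enthalpy_data <- function() .read_fixture("excess_enthalpy.csv")

#' @rdname study_data
#' @export
density_data <- function() .read_fixture("densities.csv")

#' @rdname study_data
#' @export
wilson_reference <- function() .read_fixture("wilson_reference.csv")

#' @rdname study_data
#' @export
rk_reference <- function() .read_fixture("rk_reference.csv")

#' @rdname study_data
#' @param model `"PRM-VT"`, `"PRSV-VT"` or `"SAFT"`.
#' @export
kij_coefficients <- function(model = c("PRSV-VT", "PRM-VT", "SAFT")) {
  model <- match.arg(model)
  tab <- .read_fixture("eos_kij.csv")
  row <- tab[tab$model == model, ]
  out <- c(a = row$a, b = row$b, c = row$c)
  attr(out, "R2") <- row$R2
  out
}

#' Evaluate the quadratic temperature dependence of a binary interaction
#' parameter
#'
#' @param coeffs Named vector `c(a, b, c)` as returned by
#'   [kij_coefficients()].
#' @param T_K Temperature(s), K.
#' @return \eqn{k_{ij}(T) = a + bT + cT^2} (T in kelvin).
#' @examples
#' eval_kij(kij_coefficients("PRSV-VT"), 298.15)
#' @export
eval_kij <- function(coeffs, T_K) {
  unname(coeffs[1] + coeffs[2] * T_K + coeffs[3] * T_K^2)
}
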