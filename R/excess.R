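#' Excess molar volume from mixture and pure densities
#'
#' \deqn{V^E_m = x_1 M_1 (1/\rho - 1/\rho_1) + x_2 M_2 (1/\rho - 1/\rho_2)}
#' with molar masses in g/mol and densities in kg/m^3; the result is in
#' m^3/mol (multiply by 1e6 for cm^3/mol).  Exactly zero at both pure limits
#' when the mixture density equals the corresponding pure density.
#'
#' `excess_volume_curve()` applies this to a long density table (columns
#' `T_K`, `x2`, `rho_kgm3`) using each temperature's own `x2 = 0` and
#' `x2 = 1` rows as the pure densities.
#'
#' @param x2 Mole fraction(s) of component 2.
#' @param rho Mixture density, kg/m^3.
#' @param rho1,rho2 Pure-component densities at the same temperature.
#' @param M1,M2 Molar masses, g/mol (defaults: the study pair).
#' @param data Long density table.
#' @return `excess_volume()`: V^E in m^3/mol. `excess_volume_curve()`:
#'   tibble `T_K`, `x2`, `VE_m3mol` for the interior compositions.
#' @examples
#' 1e6 * excess_volume(0.5011, 880.21, 780.99, 920.34) # cm^3/mol
#' @export
excess_volume <- function(x2, rho, rho1, rho2, M1 = 60.096, M2 = 154.25) {
  stopifnot(all(rho > 0), rho1 > 0, rho2 > 0, all(x2 >= 0 & x2 <= 1))
  x1 <- 1 - x2
  x1 * M1 * 1e-3 * (1 / rho - 1 / rho1) + x2 * M2 * 1e-3 * (1 / rho - 1 / rho2)
}

#' @rdname excess_volume
#' @export
excess_volume_curve <- function(data, M1 = 60.096, M2 = 154.25) {
  stopifnot(all(c("T_K", "x2", "rho_kgm3") %in% names(data)))
  data |>
    dplyr::group_by(.data$T_K) |>
    dplyr::group_modify(function(d, key) {
      r1 <- d$rho_kgm3[abs(d$x2) < 1e-12]
      r2 <- d$rho_kgm3[abs(d$x2 - 1) < 1e-12]
      if (length(r1) != 1 || length(r2) != 1) {
        rlang::abort("density table needs x2 = 0 and x2 = 1 rows at each T")
      }
      d <- d[d$x2 > 0 & d$x2 < 1, ]
      tibble::tibble(x2 = d$x2,
                     VE_m3mol = excess_volume(d$x2, d$rho_kgm3, r1, r2, M1, M2))
    }) |>
    dplyr::ungroup()
}

#' Redlich-Kister representation of an excess property
#'
#' Least-squares fit of
#' \deqn{Q^E_m = x_1 x_2 \sum_{j=0}^{k-1} A_j (x_1 - x_2)^j}
#' to an excess-property curve.  The basis is linear in the coefficients, so
#' the fit is ordinary linear least squares on \eqn{x_1x_2(x_1-x_2)^j};
#' endpoint rows (`x2` of 0 or 1) are excluded since the basis is
#' identically zero there.  The standard deviation uses [std_deviation()]
#' with `n = n_coef`.
#'
#' @param data Tibble with `x2` and a single value column (any name; the
#'   first non-`x2`, non-`T_K` column is used).  A `T_K` column, if present,
#'   must be constant.
#' @param n_coef Number of coefficients k (3 is typical for the excess
#'   enthalpies here, 4 for excess volumes).
#' @param property Optional tag (e.g. `"HE"` or `"VE"`) stored with the fit.
#' @return Object of class `rk_fit` with `A` (coefficient vector A0..),
#'   `s`, `property`, `T_K` and the fitted point table.  `predict()` /
#'   [eval_redlich_kister()] evaluate the polynomial.
#' @examples
#' he <- dplyr::filter(excess_enthalpy_data(), T_K == 298.15)
#' fit <- fit_redlich_kister(he, 3, property = "HE")
#' fit$A
#' @export
fit_redlich_kister <- function(data, n_coef, property = NULL) {
  stopifnot("x2" %in% names(data), n_coef >= 1)
  T_K <- if ("T_K" %in% names(data)) unique(data$T_K) else NA_real_
  if (length(T_K) != 1) rlang::abort("fit_redlich_kister fits one temperature at a time")
  vcol <- setdiff(names(data), c("T_K", "x2"))[1]
  d <- data[data$x2 > 0 & data$x2 < 1, ]
  y <- d[[vcol]]
  if (nrow(d) < n_coef + 1) rlang::abort("need more interior points than coefficients")
  x1 <- 1 - d$x2
  X <- vapply(seq_len(n_coef) - 1L,
              function(j) x1 * d$x2 * (x1 - d$x2)^j,
              numeric(nrow(d)))
  qrX <- qr(X)
  if (qrX$rank < n_coef) rlang::abort("rank-deficient Redlich-Kister basis; reduce n_coef")
  A <- qr.coef(qrX, y)
  fitted <- drop(X %*% A)
  out <- list(A = unname(A), s = std_deviation(y - fitted, n_coef),
              property = property %||% vcol, T_K = T_K,
              points = tibble::tibble(x2 = d$x2, value = y, fitted = fitted,
                                      resid = y - fitted))
  class(out) <- "rk_fit"
  out
}

#' Evaluate a Redlich-Kister polynomial
#'
#' @param A Coefficient vector (A0, A1, ...).
#' @param x2 Mole fraction(s) of component 2.
#' @return \eqn{x_1x_2\sum_j A_j(x_1-x_2)^j}; zero at both endpoints.
#' @examples
#' eval_redlich_kister(c(2380, -768, 75), 0.5) # = A0/4
#' @export
eval_redlich_kister <- function(A, x2) {
  x1 <- 1 - x2
  out <- numeric(length(x2))
  for (j in seq_along(A)) out <- out + A[j] * (x1 - x2)^(j - 1)
  x1 * x2 * out
}

#' @export
predict.rk_fit <- function(object, x2, ...) eval_redlich_kister(object$A, x2)

#' @export
print.rk_fit <- function(x, ...) {
  cat(sprintf("Redlich-Kister fit (%s%s, %d coefficients)\n", x$property,
              if (!is.na(x$T_K)) sprintf(" at %.2f K", x$T_K) else "",
              length(x$A)))
  cat("  A =", format(x$A, digits = 5), "\n")
  cat(sprintf("  s = %.4g (property units), n = %d interior points\n",
              x$s, nrow(x$points)))
  invisible(x)
}

#' @method tidy rk_fit
#' @export
tidy.rk_fit <- function(x, ...) {
  tibble::tibble(term = paste0("A", seq_along(x$A) - 1), estimate = x$A)
}

#' @method glance rk_fit
#' @export
glance.rk_fit <- function(x, ...) {
  tibble::tibble(property = x$property, T_K = x$T_K, s = x$s,
                 n_coef = length(x$A), nobs = nrow(x$points))
}

#' @method augment rk_fit
#' @export
augment.rk_fit <- function(x, ...) x$points

#' Isobaric excess heat capacity from the temperature trend of H^E
#'
#' At a fixed composition, \eqn{C_{P,m}^E = (\partial H^E_m/\partial T)_P};
#' when the increase of \eqn{H^E} with temperature is close to linear this is
#' simply the least-squares slope, which is what this helper returns.
#'
#' @param data Tibble with columns `T_K` and `HE_Jmol` (>= 2 rows) at one
#'   composition.
#' @return Slope in J mol^-1 K^-1.
#' @examples
#' cp_excess(data.frame(T_K = c(288.15, 298.15, 308.15, 318.15),
#'                      HE_Jmol = c(517, 599, 663, 749)))
#' @export
cp_excess <- function(data) {
  stopifnot(all(c("T_K", "HE_Jmol") %in% names(data)), nrow(data) >= 2)
  unname(stats::coef(stats::lm(HE_Jmol ~ T_K, data = data))[2])
}

#' Gibbs-Helmholtz consistency test of G^E against calorimetric H^E
#'
#' Rebuilds the excess Gibbs energy at temperatures around `T_K` from the
#' smoothed Wilson interaction energies (a [fit_lambda_trend()] result) and
#' the components' molar-volume tables, and differentiates
#' \eqn{H^E_m = [\partial(G^E_m/T)/\partial(1/T)]_{P,x}} by central
#' difference over `T_K - dT` and `T_K + dT`.  Returns the derived
#' \eqn{H^E(x)} together with \eqn{G^E(x)} at `T_K` and
#' \eqn{TS^E = H^E - G^E}.  An `analytic = TRUE` mode uses the closed-form
#' temperature derivative that holds when the molar-volume ratio is treated
#' as temperature-independent (energies still from the trend at `T_K`);
#' it is mainly a cross-check of the finite difference.
#'
#' @param trend A `lambda_trend` object.
#' @param comp1,comp2 [component()] objects.
#' @param T_K Target temperature, K.
#' @param dT Half-width of the central difference, K.
#' @param x2 Composition grid.
#' @param analytic Use the constant-volume-ratio closed form instead of the
#'   finite difference.
#' @return Tibble `x2`, `GE_Jmol`, `HE_Jmol`, `TSE_Jmol`.
#' @export
gibbs_helmholtz_he <- function(trend, comp1 = component("2-propanol"),
                               comp2 = component("1,8-cineole"),
                               T_K = 298.15, dT = 5,
                               x2 = seq(0.02, 0.98, by = 0.02),
                               analytic = FALSE) {
  x1 <- 1 - x2
  lam_at <- function(TT) stats::predict(trend, T_K = TT)
  Lam_at <- function(TT) {
    en <- lam_at(TT)
    V1 <- as.numeric(molar_volume(comp1, TT))
    V2 <- as.numeric(molar_volume(comp2, TT))
    wilson_lambdas(en$dlam12_11_Jmol, en$dlam12_22_Jmol, V1, V2, TT)
  }
  L0 <- Lam_at(T_K)
  GE <- R_GAS * T_K * wilson_gibbs(x1, L0$Lambda12, L0$Lambda21)
  if (analytic) {
    en <- lam_at(T_K)
    d1 <- x1 + L0$Lambda12 * x2
    d2 <- x2 + L0$Lambda21 * x1
    HE <- x1 * x2 * (en$dlam12_11_Jmol * L0$Lambda12 / d1 +
                     en$dlam12_22_Jmol * L0$Lambda21 / d2)
  } else {
    Lm <- Lam_at(T_K - dT); Lp <- Lam_at(T_K + dT)
    GTm <- R_GAS * wilson_gibbs(x1, Lm$Lambda12, Lm$Lambda21)  # G^E/T at T-dT
    GTp <- R_GAS * wilson_gibbs(x1, Lp$Lambda12, Lp$Lambda21)
    HE <- (GTm - GTp) / (1 / (T_K - dT) - 1 / (T_K + dT))
  }
  tibble::tibble(x2 = x2, GE_Jmol = GE, HE_Jmol = HE, TSE_Jmol = HE - GE)
}

#' @rdname gibbs_helmholtz_he
#' @param he_fit An `rk_fit` of the experimental excess enthalpies at
#'   `T_K`, used as the reference curve.
#' @param ... Passed on to [gibbs_helmholtz_he()].
#' @return `gh_consistency()`: object with the grid tibble (`$grid`, with an
#'   extra experimental-curve column `HE_exp_Jmol`) and `$summary`
#'   (maximum and root-mean-square discrepancy between derived and
#'   experimental H^E).
#' @export
gh_consistency <- function(trend, he_fit, T_K = 298.15, ...) {
  grid <- gibbs_helmholtz_he(trend, T_K = T_K, ...)
  grid$HE_exp_Jmol <- eval_redlich_kister(he_fit$A, grid$x2)
  diff <- grid$HE_Jmol - grid$HE_exp_Jmol
  out <- list(grid = grid, T_K = T_K,
              summary = tibble::tibble(
                max_abs_diff_Jmol = max(abs(diff)),
                rms_diff_Jmol = sqrt(mean(diff^2))))
  class(out) <- "gh_consistency"
  out
}

#' @export
print.gh_consistency <- function(x, ...) {
  cat(sprintf("Gibbs-Helmholtz consistency at %.2f K\n", x$T_K))
  cat(sprintf("  max |H^E_GH - H^E_exp| = %.0f J/mol, rms = %.0f J/mol\n",
              x$summary$max_abs_diff_Jmol, x$summary$rms_diff_Jmol))
  invisible(x)
}
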