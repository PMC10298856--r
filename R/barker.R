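#' Total pressure of the Wilson/virial forward model
#'
#' Computes the total pressure of a binary liquid at fixed temperature and
#' liquid composition from the Wilson activity coefficients with a
#' virial-corrected vapor phase,
#' \deqn{P_{calc} = x_1\gamma_1 P_1^0 R_1 + x_2\gamma_2 P_2^0 R_2,}
#' \deqn{R_1 = \exp\{[(V_1^0 - B_{11})(P - P_1^0) - P\delta_{12}y_2^2]/RT\}}
#' (and symmetrically for \eqn{R_2}).  Because \eqn{R_1, R_2} depend on the
#' pressure and vapor composition being computed, the equations are solved by
#' fixed-point iteration started from the ideal-vapor (\eqn{R=1}) solution
#' until successive pressures agree within `tol`.
#' With all virial coefficients and liquid volumes zero the model reduces
#' exactly to modified Raoult's law.
#'
#' @param x1 Liquid mole fraction(s) of component 1.
#' @param T_K Temperature, K.
#' @param Lambda12,Lambda21 Wilson parameters.
#' @param pure List with `P1`, `P2` (pure vapor pressures, Pa) and `V1`,
#'   `V2` (liquid molar volumes, m^3/mol).
#' @param virials List with `B11`, `B22`, `B12` (m^3/mol); see
#'   [virial_cross()].
#' @param tol Convergence tolerance on the pressure, Pa.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Tibble with `P_calc_Pa`, `y1` and `iterations` for each `x1`.
#' @export
barker_pressure <- function(x1, T_K, Lambda12, Lambda21, pure, virials,
                            tol = 0.01, max_iter = 200) {
  g <- wilson_activity(x1, Lambda12, Lambda21)
  x2 <- 1 - x1
  RT <- R_GAS * T_K
  d12 <- 2 * virials$B12 - virials$B11 - virials$B22
  pg1 <- x1 * g$gamma1 * pure$P1
  pg2 <- x2 * g$gamma2 * pure$P2
  P <- pg1 + pg2
  y1 <- ifelse(P > 0, pg1 / P, x1)
  it <- rep(0L, length(x1))
  active <- rep(TRUE, length(x1))
  for (k in seq_len(max_iter)) {
    y2 <- 1 - y1
    R1 <- exp(((pure$V1 - virials$B11) * (P - pure$P1) - P * d12 * y2^2) / RT)
    R2 <- exp(((pure$V2 - virials$B22) * (P - pure$P2) - P * d12 * y1^2) / RT)
    Pn <- pg1 * R1 + pg2 * R2
    y1 <- ifelse(Pn > 0, pg1 * R1 / Pn, x1)
    it[active] <- k
    active <- abs(Pn - P) >= tol
    P <- Pn
    if (!any(active)) break
  }
  if (any(active)) {
    rlang::abort(sprintf(
      "barker_pressure did not converge within %d iterations (worst |dP| trace at x1 = %.4f)",
      max_iter, x1[which(active)[1]]))
  }
  tibble::tibble(P_calc_Pa = P, y1 = y1, iterations = it)
}

# Resolve pure-component inputs (P1, P2, V1, V2) for one temperature.
# Pressures come from the bundled pure-liquid table when the temperature is
# tabulated, otherwise from each component's Antoine constants; molar volumes
# are always interpolated from the component tables.
.pure_inputs <- function(T_K, comp1, comp2, pure_table = NULL,
                         pressures = c("auto", "table", "antoine")) {
  pressures <- match.arg(pressures)
  if (is.null(pure_table)) pure_table <- pure_liquid_data()
  hit <- which(abs(pure_table$T_K - T_K) < 1e-6)
  use_table <- (pressures == "table") ||
    (pressures == "auto" && length(hit) == 1)
  if (pressures == "table" && length(hit) != 1) {
    rlang::abort(sprintf("no pure-pressure table row at T = %g K", T_K))
  }
  if (use_table) {
    P1 <- pure_table$P0_Pa_1[hit]; P2 <- pure_table$P0_Pa_2[hit]
  } else {
    P1 <- antoine_pressure(comp1$antoine, T_K)
    P2 <- antoine_pressure(comp2$antoine, T_K)
  }
  list(P1 = P1, P2 = P2,
       V1 = as.numeric(molar_volume(comp1, T_K)),
       V2 = as.numeric(molar_volume(comp2, T_K)))
}

#' Reduce isothermal P-x data by Barker's method with the Wilson model
#'
#' For each isotherm in `data`, finds the Wilson parameters
#' \eqn{(\Lambda_{12}, \Lambda_{21})} minimizing the unweighted sum of
#' squared pressure residuals \eqn{\sum(P - P_{calc})^2}, with
#' [barker_pressure()] (virial-corrected vapor phase) inside the objective.
#' Only total pressures are required; vapor compositions are computed, not
#' measured.  The per-isotherm standard deviation uses [std_deviation()]
#' with `n = 2`; interaction-energy differences follow from
#' [wilson_energies()] at each isotherm's temperature.
#'
#' @param data Tibble with columns `T_K`, `x2` (mole fraction of component
#'   2) and `P_Pa`; may contain any number of isotherms (>= 4 points each).
#' @param comp1,comp2 [component()] objects; defaults are the study pair
#'   2-propanol (1) and 1,8-cineole (2).
#' @param pure_table Optional pure-pressure table (see [pure_liquid_data()]
#'   for the layout); used when an isotherm temperature is tabulated.
#' @param pressures How to obtain pure pressures: `"auto"` (table row if
#'   available, else Antoine), `"table"`, `"antoine"`.
#' @param vapor_correction Set `FALSE` to drop the virial/volume vapor-phase
#'   corrections (modified Raoult's law).
#' @param start Starting values for the two Wilson parameters.
#' @return Object of class `barker_fit` with elements `isotherms` (one row
#'   per temperature: parameters, `s_Pa`, energy differences, `n`),
#'   `points` (per-point pressures, deviations, activity coefficients,
#'   excess Gibbs energy, computed vapor composition) and `virials`.
#'   [tidy()] returns the isotherm table, [augment()] the point table.
#' @examples
#' \donttest{
#' fit <- fit_barker(dplyr::filter(vle_data(), T_K == 298.15))
#' tidy(fit)
#' }
#' @export
fit_barker <- function(data, comp1 = component("2-propanol"),
                       comp2 = component("1,8-cineole"),
                       pure_table = NULL,
                       pressures = "auto",
                       vapor_correction = TRUE,
                       start = c(0.5, 0.5)) {
  stopifnot(all(c("T_K", "x2", "P_Pa") %in% names(data)))
  stopifnot(all(data$x2 > 0 & data$x2 < 1))
  virials <- if (vapor_correction) {
    vc <- virial_cross(comp1$B_ref, comp2$B_ref)
    list(B11 = comp1$B_ref, B22 = comp2$B_ref, B12 = vc$B12)
  } else {
    list(B11 = 0, B22 = 0, B12 = 0)
  }

  fit_one <- function(d) {
    T_K <- d$T_K[1]
    if (nrow(d) < 4) rlang::abort("each isotherm needs >= 4 points")
    pu <- .pure_inputs(T_K, comp1, comp2, pure_table, pressures)
    if (!vapor_correction) pu$V1 <- pu$V2 <- 0
    x1 <- 1 - d$x2
    obj <- function(p) {
      if (any(p <= 0)) return(1e12)
      sum((d$P_Pa - barker_pressure(x1, T_K, p[1], p[2], pu, virials)$P_calc_Pa)^2)
    }
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    # code 10 (simplex degeneracy) is routine when restarting at the optimum
    if (!o$convergence %in% c(0, 10)) {
      rlang::warn(sprintf("Barker optimizer did not fully converge at %.2f K (code %d)",
                          T_K, o$convergence))
    }
    L12 <- o$par[1]; L21 <- o$par[2]
    if (L12 < 0.05 || L12 > 20 || L21 < 0.05 || L21 > 20) {
      rlang::warn(sprintf("Wilson parameter outside (0.05, 20) at %.2f K", T_K))
    }
    bp <- barker_pressure(x1, T_K, L12, L21, pu, virials)
    ga <- wilson_activity(x1, L12, L21)
    en <- wilson_energies(L12, L21, pu$V1, pu$V2, T_K)
    list(
      row = tibble::tibble(
        T_K = T_K, Lambda12 = L12, Lambda21 = L21,
        s_Pa = std_deviation(d$P_Pa - bp$P_calc_Pa, 2),
        dlam12_11_Jmol = en$dlam12_11, dlam12_22_Jmol = en$dlam12_22,
        n = nrow(d)),
      pts = tibble::tibble(
        T_K = T_K, x2 = d$x2, P_Pa = d$P_Pa, P_calc_Pa = bp$P_calc_Pa,
        dP_Pa = d$P_Pa - bp$P_calc_Pa,
        gamma1 = ga$gamma1, gamma2 = ga$gamma2,
        GE_Jmol = R_GAS * T_K * wilson_gibbs(x1, L12, L21),
        y1 = bp$y1))
  }

  groups <- split(data[order(data$T_K, data$x2), ],
                  data$T_K[order(data$T_K, data$x2)])
  fits <- lapply(groups, fit_one)
  out <- list(
    isotherms = dplyr::bind_rows(lapply(fits, `[[`, "row")),
    points = dplyr::bind_rows(lapply(fits, `[[`, "pts")),
    virials = virials,
    components = c(comp1$name, comp2$name),
    vapor_correction = vapor_correction)
  class(out) <- "barker_fit"
  out
}

#' @export
print.barker_fit <- function(x, ...) {
  cat("Barker/Wilson reduction of", nrow(x$isotherms), "isotherm(s),",
      paste(x$components, collapse = " (1) + "), "(2)\n")
  print(as.data.frame(x$isotherms), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy barker_fit
#' @export
tidy.barker_fit <- function(x, ...) x$isotherms

#' @method augment barker_fit
#' @export
augment.barker_fit <- function(x, ...) x$points

#' @method glance barker_fit
#' @export
glance.barker_fit <- function(x, ...) {
  tibble::tibble(
    n_isotherms = nrow(x$isotherms),
    n_points = nrow(x$points),
    rms_s_Pa = sqrt(mean(x$isotherms$s_Pa^2)),
    vapor_correction = x$vapor_correction)
}

#' Linear temperature trend of the Wilson interaction energies
#'
#' Ordinary least-squares lines for each interaction-energy difference
#' against temperature, across the isotherms of a [fit_barker()] result (or
#' a tibble with columns `T_K`, `dlam12_11_Jmol`, `dlam12_22_Jmol`).  The
#' smoothed energies are what the Gibbs-Helmholtz consistency test
#' differentiates.
#'
#' @param fits A `barker_fit` object or a compatible tibble (>= 3 rows).
#' @return Object of class `lambda_trend`; `predict()` evaluates both
#'   smoothed energy differences at new temperatures.
#' @export
fit_lambda_trend <- function(fits) {
  tab <- if (inherits(fits, "barker_fit")) fits$isotherms else tibble::as_tibble(fits)
  if (nrow(tab) < 3) rlang::abort("need at least 3 isotherms for a trend")
  out <- list(
    fit11 = stats::lm(dlam12_11_Jmol ~ T_K, data = tab),
    fit22 = stats::lm(dlam12_22_Jmol ~ T_K, data = tab),
    data = tab)
  class(out) <- "lambda_trend"
  out
}

#' @export
predict.lambda_trend <- function(object, T_K, ...) {
  nd <- data.frame(T_K = T_K)
  tibble::tibble(
    T_K = T_K,
    dlam12_11_Jmol = unname(stats::predict(object$fit11, nd)),
    dlam12_22_Jmol = unname(stats::predict(object$fit22, nd)))
}

#' @method tidy lambda_trend
#' @export
tidy.lambda_trend <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    dlam12_11 = stats::coef(x$fit11),
    dlam12_22 = stats::coef(x$fit22))
}

#' @export
print.lambda_trend <- function(x, ...) {
  cf1 <- stats::coef(x$fit11); cf2 <- stats::coef(x$fit22)
  cat(sprintf("lambda12-lambda11 = %.1f %+.3f T  (J/mol)\n", cf1[1], cf1[2]))
  cat(sprintf("lambda12-lambda22 = %.1f %+.3f T  (J/mol)\n", cf2[1], cf2[2]))
  invisible(x)
}
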