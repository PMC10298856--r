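#' Antoine vapor-pressure equation
#'
#' `antoine_constants()` builds a set of constants for the ln-form Antoine
#' equation \eqn{\ln(P^0/\mathrm{kPa}) = A - B/(T/\mathrm{K} - C)};
#' `antoine_pressure()` evaluates it and returns the pressure in Pa.
#'
#' @param A,B,C Antoine constants (kPa / K convention, ln form). `B` must be
#'   positive.
#' @param constants An `antoine` object.
#' @param T_K Temperature(s), K; must satisfy `T_K > C`.
#' @return `antoine_pressure()` returns pressure(s) in Pa, strictly
#'   increasing in temperature.
#' @examples
#' eq <- antoine_constants(17.6939, 4114.55, 39.969)
#' antoine_pressure(eq, 298.15)
#' @export
antoine_constants <- function(A, B, C) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), B >= 0)
  structure(list(A = A, B = B, C = C), class = "antoine")
}

#' @rdname antoine_constants
#' @export
antoine_pressure <- function(constants, T_K) {
  stopifnot(inherits(constants, "antoine"))
  if (any(T_K <= constants$C)) {
    rlang::abort("antoine_pressure: T must exceed the C constant")
  }
  1000 * exp(constants$A - constants$B / (T_K - constants$C))
}

#' @export
print.antoine <- function(x, ...) {
  cat(sprintf("ln(P/kPa) = %.4f - %.2f/(T/K - %.3f)\n", x$A, x$B, x$C))
  invisible(x)
}

#' Standard deviation of a fit
#'
#' Root of the residual sum of squares over the residual degrees of freedom,
#' \eqn{s = \{\sum_i (X - X_{calc})_i^2 / (N - n)\}^{1/2}}, the deviation
#' measure used throughout the data reduction (same units as the residuals).
#'
#' @param residuals Numeric residual vector.
#' @param n_params Number of adjusted parameters `n`; must be `< N`.
#' @export
std_deviation <- function(residuals, n_params) {
  N <- length(residuals)
  if (N <= n_params) rlang::abort("std_deviation needs more residuals than parameters")
  sqrt(sum(residuals^2) / (N - n_params))
}

#' Fit the Antoine equation to pure vapor-pressure data
#'
#' Three-parameter nonlinear least squares of the ln-form Antoine equation.
#' The default objective minimizes squared deviations of \eqn{\ln P}, which
#' weights the low- and high-pressure ends of a wide pressure range evenly
#' and is the objective that reproduces the study's published constants for
#' 2-propanol; `objective = "pressure"` minimizes squared deviations in Pa
#' instead (it favors the high-pressure points and yields a smaller s).
#' The reported standard deviation is always computed in pressure units
#' via [std_deviation()] with `n = 3`.
#'
#' @param data Tibble/data frame with columns `T_K` and `P_Pa` (>= 4 rows,
#'   distinct temperatures, positive pressures).
#' @param objective `"lnp"` (default) or `"pressure"`.
#' @return An object of class `antoine_fit`: list with `constants`
#'   ([antoine_constants()]), `s_Pa`, `objective`, `data` (input plus
#'   `P_calc_Pa` and `resid_Pa`), `max_resid` (one-row tibble with the
#'   largest absolute residual and its temperature).
#' @examples
#' pure <- pure_liquid_data()
#' fit <- fit_antoine(data.frame(T_K = pure$T_K, P_Pa = pure$P0_Pa_1))
#' glance(fit)
#' @export
fit_antoine <- function(data, objective = c("lnp", "pressure")) {
  objective <- match.arg(objective)
  stopifnot(all(c("T_K", "P_Pa") %in% names(data)))
  T_K <- data$T_K; P <- data$P_Pa
  if (length(T_K) < 4) rlang::abort("fit_antoine needs at least 4 points")
  if (anyDuplicated(T_K)) rlang::abort("temperatures must be distinct")
  if (any(P <= 0)) rlang::abort("pressures must be positive")

  # starting values: best linearization ln P ~ 1/(T - C0) over a C0 grid
  best <- NULL
  for (C0 in c(-60, -30, 0, 20, 40, 60)) {
    if (any(T_K - C0 <= 0)) next
    f <- stats::lm(log(P / 1000) ~ I(1 / (T_K - C0)))
    if (is.null(best) || deviance(f) < best$dev) {
      best <- list(dev = stats::deviance(f), C = C0,
                   A = stats::coef(f)[1], B = -stats::coef(f)[2])
    }
  }
  start <- list(A = unname(best$A), B = unname(best$B), C = best$C)

  df <- data.frame(T_K = T_K, P_Pa = P)
  fit <- if (objective == "lnp") {
    minpack.lm::nlsLM(log(P_Pa / 1000) ~ A - B / (T_K - C),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15,
                                                           ptol = 1e-15))
  } else {
    minpack.lm::nlsLM(P_Pa ~ 1000 * exp(A - B / (T_K - C)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15,
                                                           ptol = 1e-15))
  }
  cf <- stats::coef(fit)
  constants <- antoine_constants(cf[["A"]], cf[["B"]], cf[["C"]])
  P_calc <- antoine_pressure(constants, T_K)
  res <- P - P_calc
  out <- list(
    constants = constants,
    s_Pa = std_deviation(res, 3),
    objective = objective,
    data = tibble::tibble(T_K = T_K, P_Pa = P, P_calc_Pa = P_calc,
                          resid_Pa = res),
    max_resid = tibble::tibble(T_K = T_K[which.max(abs(res))],
                               resid_Pa = res[which.max(abs(res))]))
  class(out) <- "antoine_fit"
  out
}

#' @export
print.antoine_fit <- function(x, ...) {
  cat("Antoine fit (", x$objective, " objective, n = ",
      nrow(x$data), " points)\n", sep = "")
  print(x$constants)
  cat(sprintf("s = %.1f Pa; largest residual %.1f Pa at %.2f K\n",
              x$s_Pa, x$max_resid$resid_Pa, x$max_resid$T_K))
  invisible(x)
}

#' @method tidy antoine_fit
#' @export
tidy.antoine_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = c(x$constants$A, x$constants$B, x$constants$C))
}

#' @method glance antoine_fit
#' @export
glance.antoine_fit <- function(x, ...) {
  tibble::tibble(s_Pa = x$s_Pa,
                 max_resid_Pa = x$max_resid$resid_Pa,
                 T_max_resid_K = x$max_resid$T_K,
                 nobs = nrow(x$data), objective = x$objective)
}

#' @method augment antoine_fit
#' @export
augment.antoine_fit <- function(x, ...) x$data

#' @export
predict.antoine_fit <- function(object, newdata, ...) {
  antoine_pressure(object$constants, newdata$T_K)
}
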