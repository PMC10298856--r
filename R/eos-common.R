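#' Equation-of-state generics
#'
#' `pure_saturation()` solves the pure-component vapor pressure at `T_K`
#' from equality of liquid and vapor fugacities; `bubble_point()` solves the
#' isothermal bubble pressure and vapor composition at liquid composition
#' `x1`; both dispatch on the model class ([cubic_model()] or
#' [saft_model()]).
#'
#' @param model An `eos_model` object.
#' @param i Component index (1 or 2).
#' @param T_K Temperature, K.
#' @param x1 Liquid mole fraction of component 1.
#' @param ... Method-specific arguments.
#' @return `pure_saturation()`: tibble `P_Pa`, `v_liq_m3mol`, `v_vap_m3mol`.
#'   `bubble_point()`: tibble `P_Pa`, `y1`, `v_liq_m3mol`, `v_vap_m3mol`,
#'   `iterations`, `converged`.
#' @export
pure_saturation <- function(model, i, T_K, ...) UseMethod("pure_saturation")

#' @rdname pure_saturation
#' @export
bubble_point <- function(model, T_K, x1, ...) UseMethod("bubble_point")

#' Absolute average percentage deviation
#'
#' \eqn{\mathrm{AAD} = (100/N)\sum_i |P_{exp,i} - P_{calc,i}|/P_{exp,i}}.
#'
#' @param P_exp,P_calc Equal-length vectors; `P_exp` positive.
#' @return AAD in percent.
#' @export
aad_percent <- function(P_exp, P_calc) {
  stopifnot(length(P_exp) == length(P_calc), all(P_exp > 0))
  100 * mean(abs(P_exp - P_calc) / P_exp)
}

# shared successive-substitution bubble-pressure loop.
# lnphi_fn(x, phase, P) must return the two ln(fugacity coefficients) at the
# loop's T; Ps are the pure saturation pressures used to start (P, y).
.bubble_loop <- function(lnphi_fn, x1, Ps, tol = 1e-9, max_iter = 500) {
  x <- c(x1, 1 - x1)
  P <- sum(x * Ps)
  y <- x * Ps / P
  conv <- FALSE
  for (i in seq_len(max_iter)) {
    K <- exp(lnphi_fn(x, "L", P) - lnphi_fn(y, "V", P))
    S <- sum(K * x)
    y <- K * x / S
    Pn <- P * S
    if (abs(Pn / P - 1) < tol) { P <- Pn; conv <- TRUE; break }
    P <- Pn
  }
  list(P = P, y1 = y[1], iterations = i, converged = conv)
}

#' Correlate a set of isothermal VLE data with an equation of state
#'
#' Solves the bubble pressure at every `(T_K, x2)` state point of `data`
#' and scores the model by the absolute average percentage deviation,
#' overall and per isotherm.
#'
#' @param model An `eos_model`.
#' @param data Tibble with `T_K`, `x2`, `P_Pa` (e.g. [vle_data()]).
#' @return Object of class `vle_correlation`: `$points` (per-point
#'   computed pressures, vapor compositions and relative deviations),
#'   `$by_isotherm` (per-temperature AAD), and overall AAD via `glance()`.
#' @examples
#' \donttest{
#' m <- cubic_model("PRSV")
#' correlate_vle(m, dplyr::filter(vle_data(), T_K == 298.15))
#' }
#' @export
correlate_vle <- function(model, data) {
  stopifnot(inherits(model, "eos_model"),
            all(c("T_K", "x2", "P_Pa") %in% names(data)))
  pts <- data[order(data$T_K, data$x2), c("T_K", "x2", "P_Pa")]
  res <- dplyr::bind_rows(lapply(split(pts, pts$T_K), function(d) {
    T_K <- d$T_K[1]
    Ps <- c(pure_saturation(model, 1, T_K)$P_Pa,
            pure_saturation(model, 2, T_K)$P_Pa)
    bb <- lapply(1 - d$x2, function(x1) bubble_point(model, T_K, x1, Ps = Ps))
    d$P_calc_Pa <- vapply(bb, function(b) b$P_Pa, 0)
    d$y1 <- vapply(bb, function(b) b$y1, 0)
    d
  }))
  res$rel_dev_pct <- 100 * (res$P_Pa - res$P_calc_Pa) / res$P_Pa
  out <- list(
    points = tibble::as_tibble(res),
    by_isotherm = res |>
      dplyr::group_by(.data$T_K) |>
      dplyr::summarise(aad_pct = aad_percent(.data$P_Pa, .data$P_calc_Pa),
                       n = dplyr::n(), .groups = "drop"),
    model = model$label)
  out$aad_pct <- aad_percent(res$P_Pa, res$P_calc_Pa)
  class(out) <- "vle_correlation"
  out
}

#' @export
print.vle_correlation <- function(x, ...) {
  cat(sprintf("%s correlation of %d points / %d isotherm(s): AAD = %.2f%%\n",
              x$model, nrow(x$points), nrow(x$by_isotherm), x$aad_pct))
  print(as.data.frame(x$by_isotherm), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy vle_correlation
#' @export
tidy.vle_correlation <- function(x, ...) x$by_isotherm

#' @method augment vle_correlation
#' @export
augment.vle_correlation <- function(x, ...) x$points

#' @method glance vle_correlation
#' @export
glance.vle_correlation <- function(x, ...) {
  tibble::tibble(model = x$model, aad_pct = x$aad_pct,
                 n_points = nrow(x$points), n_isotherms = nrow(x$by_isotherm))
}

#' Excess molar volume predicted by an equation of state
#'
#' \eqn{V^E(x) = v_{liq}(x) - x_1 v_{liq,1} - x_2 v_{liq,2}} at fixed
#' temperature and pressure, from the model's liquid-phase molar volumes
#' (translated volumes for the cubics when translation is enabled).
#'
#' @param model An `eos_model`.
#' @param T_K Temperature, K.
#' @param P_Pa Pressure, Pa (ambient by default, matching liquid-density
#'   measurements).
#' @param x2 Composition grid (endpoints allowed; they give exactly zero).
#' @return Tibble `x2`, `VE_m3mol`.
#' @export
predict_excess_volume <- function(model, T_K, P_Pa = 101325,
                                  x2 = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(model, "eos_model"))
  v1 <- liquid_volume(model, T_K, 1, P_Pa)
  v2 <- liquid_volume(model, T_K, 0, P_Pa)
  v <- vapply(1 - x2, function(x1) liquid_volume(model, T_K, x1, P_Pa), 0)
  tibble::tibble(x2 = x2, VE_m3mol = v - (1 - x2) * v1 - x2 * v2)
}

#' @rdname predict_excess_volume
#' @export
liquid_volume <- function(model, T_K, x1, P_Pa) UseMethod("liquid_volume")
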