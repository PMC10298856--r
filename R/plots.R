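#' Plot methods
#'
#' `autoplot()` methods for the main result objects: the P-x diagram of a
#' Barker reduction (points = measurements, lines = fitted total-pressure
#' curves), the fitted Redlich-Kister curve with its data, the
#' Gibbs-Helmholtz consistency figure (derived H^E, G^E and TS^E curves
#' with the experimental H^E), and the relative-deviation profile of an
#' equation-of-state correlation.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name vlemix-autoplot
NULL

#' @rdname vlemix-autoplot
#' @method autoplot barker_fit
#' @export
autoplot.barker_fit <- function(object, ...) {
  pts <- object$points
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(object$isotherms)), function(i) {
    row <- object$isotherms[i, ]
    sub <- pts[pts$T_K == row$T_K, ]
    x2 <- seq(min(sub$x2), max(sub$x2), length.out = 80)
    # reuse the fitted pure inputs implied by the points: rebuild from data
    tibble::tibble(T_K = row$T_K, x2 = x2,
                   P_Pa = stats::spline(sub$x2, sub$P_calc_Pa, xout = x2)$y)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x2, y = .data$P_Pa,
                                    colour = factor(.data$T_K))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "x2", y = "P / Pa", colour = "T / K")
}

#' @rdname vlemix-autoplot
#' @method autoplot rk_fit
#' @export
autoplot.rk_fit <- function(object, ...) {
  grid <- tibble::tibble(x2 = seq(0, 1, by = 0.01))
  grid$value <- eval_redlich_kister(object$A, grid$x2)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x2, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "x2", y = object$property)
}

#' @rdname vlemix-autoplot
#' @method autoplot gh_consistency
#' @export
autoplot.gh_consistency <- function(object, ...) {
  g <- object$grid
  long <- tidyr::pivot_longer(
    g[, c("x2", "GE_Jmol", "HE_Jmol", "TSE_Jmol")],
    -"x2", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x2, y = .data$value,
                                     linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = data.frame(x2 = g$x2, value = g$HE_exp_Jmol,
                                         quantity = "HE_exp_Jmol"),
                       colour = "grey50") +
    ggplot2::labs(x = "x2", y = "J/mol",
                  title = sprintf("Gibbs-Helmholtz consistency at %.2f K",
                                  object$T_K))
}

#' @rdname vlemix-autoplot
#' @method autoplot vle_correlation
#' @export
autoplot.vle_correlation <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x2, y = .data$rel_dev_pct,
                               colour = factor(.data$T_K))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "x2", y = "100 (Pexp - Pcalc)/Pexp", colour = "T / K",
                  title = object$model)
}
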