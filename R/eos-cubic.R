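#' Peng-Robinson-family cubic equations of state
#'
#' Builds a Peng-Robinson model for the binary pair with either the Mathias
#' (PRM) or the Stryjek-Vera (PRSV) alpha function, van der Waals one-fluid
#' mixing with a temperature-dependent binary interaction parameter
#' \eqn{k_{ij}(T) = a + bT + cT^2}, and optional Peneloux volume
#' translation.  Translation shifts reported molar volumes by the constant
#' \eqn{c_i = (c/b)_i b_i} per component but leaves every phase-equilibrium
#' pressure and vapor composition unchanged.
#'
#' @param variant `"PRM"` or `"PRSV"`.
#' @param comp1,comp2 [component()] objects carrying `cubic` parameter
#'   blocks (`p1` or `kappa1`, and `c_over_b`).
#' @param kij Quadratic coefficients `c(a, b, c)` for \eqn{k_{ij}(T)};
#'   default: the bundled study regression for the chosen variant.  Use
#'   `c(0, 0, 0)` for no interaction correction.
#' @param translation Apply Peneloux volume translation to reported volumes.
#' @param prm_convention Sign convention of the Mathias polar term in
#'   \eqn{\sqrt\alpha = 1 + \kappa(1-\sqrt{T_r}) \mp p_1(1-T_r)(0.7-T_r)}:
#'   `"minus"` (default; reproduces the bundled pure-pressure table with the
#'   study's tabulated `p1` values) or `"plus"`.
#' @return An object of classes `cubic_eos`, `eos_model`.
#' @examples
#' m <- cubic_model("PRSV")
#' pure_saturation(m, 1, 298.15)
#' @export
cubic_model <- function(variant = c("PRSV", "PRM"),
                        comp1 = component("2-propanol"),
                        comp2 = component("1,8-cineole"),
                        kij = NULL,
                        translation = TRUE,
                        prm_convention = c("minus", "plus")) {
  variant <- match.arg(variant)
  prm_convention <- match.arg(prm_convention)
  if (is.null(kij)) {
    kij <- kij_coefficients(if (variant == "PRSV") "PRSV-VT" else "PRM-VT")
  }
  comps <- list(comp1, comp2)
  pars <- lapply(comps, function(cp) {
    blk <- cp$cubic[[variant]]
    if (is.null(blk)) rlang::abort(paste0("component ", cp$name,
                                          " lacks ", variant, " parameters"))
    list(Tc = cp$Tc, Pc = cp$Pc, omega = cp$omega,
         alpha_param = if (variant == "PRM") blk$p1 else blk$kappa1,
         c_over_b = blk$c_over_b)
  })
  out <- list(variant = variant, pars = pars, kij = unname(kij),
              translation = translation, prm_convention = prm_convention,
              components = c(comp1$name, comp2$name),
              label = paste0(variant, if (translation) "-VT"))
  class(out) <- c("cubic_eos", "eos_model")
  out
}

#' @export
print.cubic_eos <- function(x, ...) {
  cat("<", x$label, "> ", paste(x$components, collapse = " + "), "\n", sep = "")
  cat(sprintf("  kij(T) = %.4f %+.4e T %+.4e T^2\n",
              x$kij[1], x$kij[2], x$kij[3]))
  invisible(x)
}

#' Temperature-dependent alpha function of the cubic models
#'
#' PRM: \eqn{\sqrt\alpha = 1 + \kappa_{PR}(\omega)(1-\sqrt{T_r}) -
#' p_1(1-T_r)(0.7-T_r)} with
#' \eqn{\kappa_{PR} = 0.37464 + 1.54226\omega - 0.26992\omega^2}.
#' PRSV: \eqn{\sqrt\alpha = 1 + \kappa(1-\sqrt{T_r})},
#' \eqn{\kappa = \kappa_0 + \kappa_1(1+\sqrt{T_r})(0.7-T_r)},
#' \eqn{\kappa_0 = 0.378893 + 1.4897153\omega - 0.17131848\omega^2 +
#' 0.0196554\omega^3}.  Both give \eqn{\alpha(T_c) = 1}.
#'
#' @param variant `"PRM"` or `"PRSV"`.
#' @param T_K Temperature, K.
#' @param Tc,omega Critical temperature (K) and acentric factor.
#' @param param `p1` (PRM) or `kappa1` (PRSV).
#' @param convention PRM polar-term sign convention, see [cubic_model()].
#' @return alpha (dimensionless).
#' @export
alpha_function <- function(variant, T_K, Tc, omega, param,
                           convention = "minus") {
  Tr <- T_K / Tc
  if (variant == "PRM") {
    k <- 0.37464 + 1.54226 * omega - 0.26992 * omega^2
    sgn <- if (convention == "minus") -1 else 1
    sq <- 1 + k * (1 - sqrt(Tr)) + sgn * param * (1 - Tr) * (0.7 - Tr)
  } else {
    k0 <- 0.378893 + 1.4897153 * omega - 0.17131848 * omega^2 +
      0.0196554 * omega^3
    k <- k0 + param * (1 + sqrt(Tr)) * (0.7 - Tr)
    sq <- 1 + k * (1 - sqrt(Tr))
  }
  if (any(sq < 0)) rlang::warn("negative sqrt(alpha); outside validity range")
  sq^2
}

# per-component a_i (J m^3 / mol^2), b_i, c_i (m^3/mol) at T
.cubic_ab <- function(model, T_K) {
  ai <- vapply(model$pars, function(p)
    PR_OMEGA_A * R_GAS^2 * p$Tc^2 / p$Pc *
      alpha_function(model$variant, T_K, p$Tc, p$omega, p$alpha_param,
                     model$prm_convention), 0)
  bi <- vapply(model$pars, function(p) PR_OMEGA_B * R_GAS * p$Tc / p$Pc, 0)
  ci <- vapply(seq_along(model$pars), function(i)
    model$pars[[i]]$c_over_b * bi[i], 0)
  list(ai = ai, bi = bi, ci = ci)
}

# compressibility roots Z > B of the PR cubic
.cubic_z <- function(A, B) {
  z <- polyroot(c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1))
  z <- Re(z[abs(Im(z)) < 1e-9])
  sort(z[z > B])
}

# ln(phi_i) for the mixture at given phase; x length-2
.cubic_lnphi <- function(model, ab, x, T_K, P, phase) {
  k <- eval_kij(model$kij, T_K)
  aij <- (1 - k * (1 - diag(2))) * sqrt(outer(ab$ai, ab$ai))
  am <- as.numeric(t(x) %*% aij %*% x)
  bm <- sum(x * ab$bi)
  A <- am * P / (R_GAS * T_K)^2
  B <- bm * P / (R_GAS * T_K)
  Z <- .cubic_z(A, B)
  if (!length(Z)) rlang::abort("no compressibility root above B")
  Z <- if (phase == "L") min(Z) else max(Z)
  sab <- as.numeric(aij %*% x)
  s2 <- sqrt(2)
  lnphi <- (ab$bi / bm) * (Z - 1) - log(Z - B) -
    A / (2 * s2 * B) * (2 * sab / am - ab$bi / bm) *
    log((Z + (1 + s2) * B) / (Z + (1 - s2) * B))
  list(lnphi = lnphi, Z = Z, v = Z * R_GAS * T_K / P)
}

#' @rdname pure_saturation
#' @param P_init Optional starting pressure, Pa.
#' @export
pure_saturation.cubic_eos <- function(model, i, T_K, P_init = NULL, ...) {
  p <- model$pars[[i]]
  if (T_K >= p$Tc) rlang::abort("T above the critical temperature")
  ab <- .cubic_ab(model, T_K)
  a <- ab$ai[i]; b <- ab$bi[i]
  P <- P_init %||% (p$Pc * exp(5.373 * (1 + p$omega) * (1 - p$Tc / T_K)))
  lnphi_pure <- function(P, Z) {
    A <- a * P / (R_GAS * T_K)^2; B <- b * P / (R_GAS * T_K)
    s2 <- sqrt(2)
    (Z - 1) - log(Z - B) - A / (2 * s2 * B) *
      log((Z + (1 + s2) * B) / (Z + (1 - s2) * B))
  }
  for (it in 1:200) {
    A <- a * P / (R_GAS * T_K)^2; B <- b * P / (R_GAS * T_K)
    Z <- .cubic_z(A, B)
    if (length(Z) < 2) {
      rlang::abort("single-root region: no reliable saturation solve at this T")
    }
    Pn <- P * exp(lnphi_pure(P, min(Z)) - lnphi_pure(P, max(Z)))
    if (abs(Pn / P - 1) < 1e-12) { P <- Pn; break }
    P <- Pn
  }
  A <- a * P / (R_GAS * T_K)^2; B <- b * P / (R_GAS * T_K)
  Z <- .cubic_z(A, B)
  shift <- if (model$translation) ab$ci[i] else 0
  tibble::tibble(P_Pa = P,
                 v_liq_m3mol = min(Z) * R_GAS * T_K / P - shift,
                 v_vap_m3mol = max(Z) * R_GAS * T_K / P - shift)
}

#' @rdname pure_saturation
#' @export
bubble_point.cubic_eos <- function(model, T_K, x1, Ps = NULL, ...) {
  stopifnot(x1 >= 0, x1 <= 1)
  ab <- .cubic_ab(model, T_K)
  if (x1 %in% c(0, 1)) {
    i <- if (x1 == 1) 1L else 2L
    ps <- pure_saturation(model, i, T_K)
    return(tibble::tibble(P_Pa = ps$P_Pa, y1 = x1,
                          v_liq_m3mol = ps$v_liq_m3mol,
                          v_vap_m3mol = ps$v_vap_m3mol,
                          iterations = 0L, converged = TRUE))
  }
  if (is.null(Ps)) {
    Ps <- c(pure_saturation(model, 1, T_K)$P_Pa,
            pure_saturation(model, 2, T_K)$P_Pa)
  }
  lnphi_fn <- function(x, phase, P) .cubic_lnphi(model, ab, x, T_K, P, phase)$lnphi
  sol <- .bubble_loop(lnphi_fn, x1, Ps)
  if (!sol$converged) rlang::warn(sprintf("bubble point not converged at T=%.2f, x1=%.4f", T_K, x1))
  x <- c(x1, 1 - x1); y <- c(sol$y1, 1 - sol$y1)
  L <- .cubic_lnphi(model, ab, x, T_K, sol$P, "L")
  V <- .cubic_lnphi(model, ab, y, T_K, sol$P, "V")
  if (abs(L$Z - V$Z) < 1e-10) rlang::warn("trivial-root collapse: liquid and vapor roots identical")
  shiftL <- if (model$translation) sum(x * ab$ci) else 0
  shiftV <- if (model$translation) sum(y * ab$ci) else 0
  tibble::tibble(P_Pa = sol$P, y1 = sol$y1,
                 v_liq_m3mol = L$v - shiftL, v_vap_m3mol = V$v - shiftV,
                 iterations = sol$iterations, converged = sol$converged)
}

#' @export
liquid_volume.cubic_eos <- function(model, T_K, x1, P_Pa) {
  ab <- .cubic_ab(model, T_K)
  x <- c(x1, 1 - x1)
  L <- .cubic_lnphi(model, ab, x, T_K, P_Pa, "L")
  L$v - if (model$translation) sum(x * ab$ci) else 0
}

#' Fit the pure-component alpha-function parameter to vapor-pressure data
#'
#' One-parameter least squares of relative saturation-pressure deviations,
#' \eqn{\sum((P_{calc} - P)/P)^2}, over a table of pure vapor pressures.
#'
#' @param variant `"PRM"` or `"PRSV"`.
#' @param comp A [component()].
#' @param data Tibble `T_K`, `P_Pa` with at least 5 points below `Tc`.
#' @param interval Search interval for the parameter.
#' @return The fitted `p1` (PRM) or `kappa1` (PRSV).
#' @export
fit_pure_alpha_param <- function(variant, comp, data, interval = c(-1, 1)) {
  stopifnot(nrow(data) >= 5, all(data$T_K < comp$Tc))
  obj <- function(par) {
    m <- cubic_model(variant, comp, comp, kij = c(0, 0, 0))
    m$pars[[1]]$alpha_param <- par
    Pc <- vapply(data$T_K, function(T) pure_saturation(m, 1, T)$P_Pa, 0)
    sum(((Pc - data$P_Pa) / data$P_Pa)^2)
  }
  o <- stats::optimize(obj, interval, tol = 1e-9)
  o$minimum
}

#' Fit the binary interaction parameter per isotherm and its temperature
#' trend
#'
#' Finds the scalar \eqn{k_{ij}} minimizing the relative squared bubble-
#' pressure deviations for each isotherm of `data`, then regresses the
#' per-isotherm values on a quadratic in temperature,
#' \eqn{k_{ij} = a + bT + cT^2}.
#'
#' @param model An `eos_model`; its stored `kij` coefficients are ignored
#'   during the per-isotherm scans.
#' @param data Tibble `T_K`, `x2`, `P_Pa` (>= 3 isotherms for the quadratic
#'   stage).
#' @param interval Search interval for each scalar `kij`.
#' @return Object of class `kij_fit`: `$by_isotherm` (T, fitted kij, AAD),
#'   `$coefficients` `c(a, b, c)`, `$R2`.
#' @export
fit_kij <- function(model, data, interval = c(-0.1, 0.1)) {
  stopifnot(inherits(model, "eos_model"))
  iso <- split(data[order(data$T_K, data$x2), ], data$T_K[order(data$T_K, data$x2)])
  rows <- lapply(iso, function(d) {
    T_K <- d$T_K[1]
    eval_at <- function(k) {
      m <- model
      m$kij <- c(k, 0, 0)
      vapply(1 - d$x2, function(x1) bubble_point(m, T_K, x1)$P_Pa, 0)
    }
    o <- stats::optimize(function(k) {
      Pc <- eval_at(k); sum(((d$P_Pa - Pc) / d$P_Pa)^2)
    }, interval, tol = 1e-6)
    k <- o$minimum
    if (abs(k) > 0.3) rlang::warn(sprintf("|kij| > 0.3 at %.2f K", T_K))
    Pc <- eval_at(k)
    tibble::tibble(T_K = T_K, kij = k, aad_pct = aad_percent(d$P_Pa, Pc))
  })
  tab <- dplyr::bind_rows(rows)
  out <- list(by_isotherm = tab)
  if (nrow(tab) >= 3) {
    qf <- stats::lm(kij ~ T_K + I(T_K^2), data = tab)
    out$coefficients <- unname(stats::coef(qf))
    out$R2 <- summary(qf)$r.squared
  }
  class(out) <- "kij_fit"
  out
}

#' @export
print.kij_fit <- function(x, ...) {
  print(as.data.frame(x$by_isotherm), digits = 4, row.names = FALSE)
  if (!is.null(x$coefficients)) {
    cat(sprintf("kij(T) = %.4f %+.4e T %+.4e T^2   (R2 = %.3f)\n",
                x$coefficients[1], x$coefficients[2], x$coefficients[3], x$R2))
  }
  invisible(x)
}

#' @method tidy kij_fit
#' @export
tidy.kij_fit <- function(x, ...) x$by_isotherm

#' @method glance kij_fit
#' @export
glance.kij_fit <- function(x, ...) {
  tibble::tibble(a = x$coefficients[1], b = x$coefficients[2],
                 c = x$coefficients[3], R2 = x$R2,
                 n_isotherms = nrow(x$by_isotherm))
}
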