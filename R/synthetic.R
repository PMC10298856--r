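#' Specification for synthetic study-like datasets
#'
#' Bundles the ground truth used to generate synthetic isothermal P-x
#' curves and excess-property curves that are drop-in replacements for the
#' bundled experimental fixtures: Wilson parameters per temperature (by
#' default the study's fitted values), Antoine constants for the pure
#' pressures, the composition grid (by default the twelve abscissae of the
#' 298.15 K isotherm), the Gaussian pressure-noise scale (default 13 Pa,
#' the instrument reproducibility the noise model emulates), Redlich-Kister
#' ground-truth vectors for the excess curves, per-temperature pure-density
#' endpoints, and the random seed that makes every generated stream
#' reproducible.
#'
#' @param wilson Tibble `T_K`, `Lambda12`, `Lambda21` of ground-truth
#'   parameters (default: the study's fitted table).
#' @param comp1,comp2 [component()] objects supplying Antoine constants,
#'   molar volumes and virial coefficients for the forward model.
#' @param x2_grid Composition grid, interior to (0, 1).
#' @param sigma_P Gaussian pressure noise, Pa (>= 0).
#' @param rk_he,rk_ve Named lists mapping temperature (as character) to
#'   Redlich-Kister coefficient vectors for H^E (J/mol) and V^E
#'   (cm^3/mol); defaults: the study's Table of coefficients.
#' @param density_endpoints Tibble `T_K`, `rho1_kgm3`, `rho2_kgm3`
#'   (defaults from the bundled density table).
#' @param sigma_HE,sigma_rho Noise scales for the excess curves.
#' @param seed Integer seed; identical specs generate identical data.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(wilson = NULL,
                       comp1 = component("2-propanol"),
                       comp2 = component("1,8-cineole"),
                       x2_grid = NULL,
                       sigma_P = 13,
                       rk_he = NULL, rk_ve = NULL,
                       density_endpoints = NULL,
                       sigma_HE = 0, sigma_rho = 0,
                       seed = 1L) {
  stopifnot(sigma_P >= 0, sigma_HE >= 0, sigma_rho >= 0)
  if (is.null(wilson)) {
    wr <- wilson_reference()
    wilson <- wr[, c("T_K", "Lambda12", "Lambda21")]
  }
  if (is.null(x2_grid)) {
    vd <- vle_data()
    x2_grid <- vd$x2[vd$T_K == 298.15]
  }
  stopifnot(all(x2_grid > 0 & x2_grid < 1))
  rk <- rk_reference()
  if (is.null(rk_he)) {
    h <- rk[rk$property == "HE", ]
    rk_he <- stats::setNames(
      lapply(seq_len(nrow(h)), function(i) unlist(h[i, c("A0", "A1", "A2")])),
      h$T_K)
  }
  if (is.null(rk_ve)) {
    v <- rk[rk$property == "VE", ]
    rk_ve <- stats::setNames(
      lapply(seq_len(nrow(v)), function(i) unlist(v[i, c("A0", "A1", "A2", "A3")])),
      v$T_K)
  }
  if (is.null(density_endpoints)) {
    dd <- density_data()
    density_endpoints <- dd |>
      dplyr::group_by(.data$T_K) |>
      dplyr::summarise(rho1_kgm3 = .data$rho_kgm3[abs(.data$x2) < 1e-12],
                       rho2_kgm3 = .data$rho_kgm3[abs(.data$x2 - 1) < 1e-12],
                       .groups = "drop")
  }
  out <- list(wilson = tibble::as_tibble(wilson), comp1 = comp1, comp2 = comp2,
              x2_grid = sort(x2_grid), sigma_P = sigma_P,
              rk_he = rk_he, rk_ve = rk_ve,
              density_endpoints = tibble::as_tibble(density_endpoints),
              sigma_HE = sigma_HE, sigma_rho = sigma_rho,
              seed = as.integer(seed))
  class(out) <- "synth_spec"
  out
}

# reproducible sub-seed per (spec, purpose, T); RNG state is restored
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic isothermal P-x dataset
#'
#' Pressures at each grid composition come from the full forward model
#' ([barker_pressure()]: Wilson activity coefficients with virial-corrected
#' vapor phase) evaluated at the ground-truth Wilson parameters for the
#' requested temperature, with pure pressures from the components' Antoine
#' constants; additive Gaussian noise of scale `sigma_P` is then applied.
#' The same spec and temperature always generate the same dataset.
#'
#' @param spec A [synth_spec()].
#' @param T_K Temperature; must appear in `spec$wilson` (or supply
#'   `Lambda12`/`Lambda21`).
#' @param Lambda12,Lambda21 Optional explicit ground truth overriding the
#'   spec table.
#' @param replicate Integer >= 1; changes the noise stream only.
#' @return Tibble `T_K`, `x2`, `P_Pa`, `P_true_Pa`.
#' @export
synth_isotherm <- function(spec, T_K, Lambda12 = NULL, Lambda21 = NULL,
                           replicate = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(Lambda12)) {
    row <- spec$wilson[abs(spec$wilson$T_K - T_K) < 1e-9, ]
    if (nrow(row) != 1) rlang::abort("no ground-truth Wilson row at this T")
    Lambda12 <- row$Lambda12; Lambda21 <- row$Lambda21
  }
  pu <- list(P1 = antoine_pressure(spec$comp1$antoine, T_K),
             P2 = antoine_pressure(spec$comp2$antoine, T_K),
             V1 = as.numeric(molar_volume(spec$comp1, T_K)),
             V2 = as.numeric(molar_volume(spec$comp2, T_K)))
  vc <- virial_cross(spec$comp1$B_ref, spec$comp2$B_ref)
  virials <- list(B11 = spec$comp1$B_ref, B22 = spec$comp2$B_ref, B12 = vc$B12)
  x1 <- 1 - spec$x2_grid
  P_true <- barker_pressure(x1, T_K, Lambda12, Lambda21, pu, virials)$P_calc_Pa
  sub <- (spec$seed * 1000L + as.integer(round(T_K)) + 7L * as.integer(replicate)) %% .Machine$integer.max
  noise <- .with_seed(sub, stats::rnorm(length(x1), 0, spec$sigma_P))
  tibble::tibble(T_K = T_K, x2 = spec$x2_grid,
                 P_Pa = P_true + noise, P_true_Pa = P_true)
}

#' Generate synthetic excess-property curves
#'
#' The excess-enthalpy curve is the spec's ground-truth Redlich-Kister
#' polynomial evaluated on the grid (plus optional noise).  The density
#' table is built by inverting the excess-volume relation: a ground-truth
#' V^E curve plus the spec's pure-density endpoints determine the mixture
#' density at each composition exactly, so the generated endpoints equal
#' the specified ones and a subsequent [excess_volume_curve()] +
#' [fit_redlich_kister()] recovers the ground truth when noise is zero.
#'
#' @inheritParams synth_isotherm
#' @return List with `he` (tibble `T_K`, `x2`, `HE_Jmol`) and `density`
#'   (tibble `T_K`, `x2`, `rho_kgm3`, including endpoint rows).
#' @export
synth_excess_curves <- function(spec, T_K, replicate = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  key <- as.character(T_K)
  if (is.null(spec$rk_he[[key]]) || is.null(spec$rk_ve[[key]])) {
    rlang::abort("no ground-truth RK vectors at this T")
  }
  ep <- spec$density_endpoints[abs(spec$density_endpoints$T_K - T_K) < 1e-9, ]
  if (nrow(ep) != 1) rlang::abort("no density endpoints at this T")
  x2 <- spec$x2_grid
  sub <- (spec$seed * 2000L + as.integer(round(T_K)) + 11L * as.integer(replicate)) %% .Machine$integer.max
  HE <- eval_redlich_kister(spec$rk_he[[key]], x2)
  VE <- eval_redlich_kister(spec$rk_ve[[key]], x2) * 1e-6 # cm^3 -> m^3
  M1 <- spec$comp1$M * 1e-3; M2 <- spec$comp2$M * 1e-3
  x1 <- 1 - x2
  rho <- (x1 * M1 + x2 * M2) /
    (VE + x1 * M1 / ep$rho1_kgm3 + x2 * M2 / ep$rho2_kgm3)
  noise <- .with_seed(sub, list(
    he = stats::rnorm(length(x2), 0, spec$sigma_HE),
    rho = stats::rnorm(length(x2), 0, spec$sigma_rho)))
  list(
    he = tibble::tibble(T_K = T_K, x2 = x2, HE_Jmol = HE + noise$he),
    density = tibble::tibble(
      T_K = T_K,
      x2 = c(0, x2, 1),
      rho_kgm3 = c(ep$rho1_kgm3, rho + noise$rho, ep$rho2_kgm3)))
}

#' Parameter-recovery experiment over synthetic replicates
#'
#' Generates `n_replicates` noisy datasets from the spec's ground truth,
#' refits each with the package's estimators, and reports per-parameter
#' bias, root-mean-square error, the median absolute relative error, and
#' whether the truth lies inside the central 95% band of the replicate
#' estimates.
#'
#' @param spec A [synth_spec()].
#' @param n_replicates Number of replicates (>= 1).
#' @param stages Any of `"wilson"` (Barker/Wilson reduction at `T_K`) and
#'   `"rk"` (Redlich-Kister refit of the synthetic H^E curve).
#' @param T_K Temperature of the experiment.
#' @return Tibble with one row per recovered parameter: `stage`, `term`,
#'   `truth`, `bias`, `rmse`, `median_rel_err`, `covered95`.
#' @export
recovery_report <- function(spec, n_replicates = 20, stages = c("wilson", "rk"),
                            T_K = 298.15) {
  stopifnot(inherits(spec, "synth_spec"), n_replicates >= 1)
  stages <- match.arg(stages, several.ok = TRUE)
  rows <- list()
  summarize <- function(stage, term, truth, est) {
    tibble::tibble(
      stage = stage, term = term, truth = truth,
      bias = mean(est) - truth,
      rmse = sqrt(mean((est - truth)^2)),
      median_rel_err = stats::median(abs(est - truth) / abs(truth)),
      covered95 = n_replicates < 3 ||
        (truth >= stats::quantile(est, 0.025) &
         truth <= stats::quantile(est, 0.975)))
  }
  if ("wilson" %in% stages) {
    row <- spec$wilson[abs(spec$wilson$T_K - T_K) < 1e-9, ]
    est <- vapply(seq_len(n_replicates), function(r) {
      d <- synth_isotherm(spec, T_K, replicate = r)
      f <- fit_barker(d[, c("T_K", "x2", "P_Pa")],
                      comp1 = spec$comp1, comp2 = spec$comp2,
                      pressures = "antoine")
      c(f$isotherms$Lambda12, f$isotherms$Lambda21)
    }, numeric(2))
    rows <- c(rows, list(
      summarize("wilson", "Lambda12", row$Lambda12, est[1, ]),
      summarize("wilson", "Lambda21", row$Lambda21, est[2, ])))
  }
  if ("rk" %in% stages) {
    truth <- spec$rk_he[[as.character(T_K)]]
    est <- vapply(seq_len(n_replicates), function(r) {
      cur <- synth_excess_curves(spec, T_K, replicate = r)$he
      fit_redlich_kister(cur, length(truth), property = "HE")$A
    }, numeric(length(truth)))
    est <- matrix(est, nrow = length(truth))
    for (j in seq_along(truth)) {
      rows <- c(rows, list(summarize("rk", paste0("A", j - 1),
                                     truth[[j]], est[j, ])))
    }
  }
  dplyr::bind_rows(rows)
}
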