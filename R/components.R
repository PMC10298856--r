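#' Pure-component data objects
#'
#' A component bundles everything the reduction and equation-of-state code
#' needs about one pure chemical: molar mass, critical constants, acentric
#' factor, a molar-volume table \eqn{V^0(T)}, Antoine vapor-pressure
#' constants, the second virial coefficient at the reference temperature of
#' the vapor-phase corrections, and the per-model equation-of-state parameter
#' blocks (Peng-Robinson-Mathias polar parameter \eqn{p_1},
#' Stryjek-Vera \eqn{\kappa_1}, Peneloux \eqn{c/b} ratios, and SAFT segment /
#' association parameters).
#'
#' `component()` loads one of the two bundled study components,
#' 2-propanol (mixture component 1) or 1,8-cineole (component 2).
#' `read_component()` reads the same JSON layout from an arbitrary file and
#' `write_component()` writes it back.
#'
#' @param name `"2-propanol"` or `"1,8-cineole"` (aliases `"propan-2-ol"`,
#'   `"cineole"`, `"eucalyptol"` are accepted).
#' @param path Path to a component JSON file.
#' @param x A `vlemix_component` object.
#' @return A `vlemix_component` object: a list with fields `name`, `M`
#'   (g/mol), `Tc` (K), `Pc` (Pa), `omega`, `Tb` (K), `volumes` (tibble of
#'   `T_K`, `V0_m3mol`), `antoine` (see [antoine_constants()]), `B_ref`
#'   (m^3/mol at `T_ref`), `cubic` and `saft` parameter lists.
#' @examples
#' ipa <- component("2-propanol")
#' ipa$Tc
#' molar_volume(ipa, 298.15)
#' @export
component <- function(name) {
  file <- switch(tolower(name),
    "2-propanol" = , "propan-2-ol" = , "isopropanol" = "propan-2-ol.json",
    "1,8-cineole" = , "cineole" = , "eucalyptol" = "cineole.json",
    rlang::abort(paste0("no bundled component '", name, "'")))
  read_component(system.file("extdata", "components", file,
                             package = "vlemix", mustWork = TRUE))
}

#' @rdname component
#' @export
read_component <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  antoine <- NULL
  if (!is.null(j$antoine)) {
    antoine <- antoine_constants(j$antoine$A, j$antoine$B, j$antoine$C)
  }
  saft <- NULL
  if (!is.null(j$saft_params)) {
    sp <- j$saft_params
    saft <- list(m = sp$m, v00 = sp$v00 * 1e-3, # L/mol -> m^3/mol
                 u0k = sp$u0_over_k,
                 ek = if (is.null(sp$e_over_k)) 10 else sp$e_over_k,
                 kap = sp$kappa_AB, epsk = sp$eps_AB_over_k,
                 scheme = sp$scheme)
  }
  new_component(
    name = j$name, M = j$molar_mass, Tc = j$Tc, Pc = j$Pc * 1e6,
    omega = j$omega, Tb = j$Tb,
    volumes = tibble::tibble(T_K = j$molar_volume_table$T_K,
                             V0_m3mol = j$molar_volume_table$V0_m3mol),
    antoine = antoine, B_ref = j$B_ref, T_ref = j$T_ref,
    cubic = j$cubic_params, saft = saft)
}

#' @rdname component
#' @export
write_component <- function(x, path) {
  stopifnot(inherits(x, "vlemix_component"))
  j <- list(
    name = x$name, molar_mass = x$M, Tc = x$Tc, Pc = x$Pc / 1e6,
    omega = x$omega, Tb = x$Tb,
    molar_volume_table = as.data.frame(x$volumes),
    antoine = if (!is.null(x$antoine))
      list(A = x$antoine$A, B = x$antoine$B, C = x$antoine$C,
           pressure_unit = "kPa", form = "ln"),
    B_ref = x$B_ref, T_ref = x$T_ref,
    cubic_params = x$cubic,
    saft_params = if (!is.null(x$saft))
      list(m = x$saft$m, v00 = x$saft$v00 * 1e3, u0_over_k = x$saft$u0k,
           e_over_k = x$saft$ek, kappa_AB = x$saft$kap,
           eps_AB_over_k = x$saft$epsk, scheme = x$saft$scheme))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname component
#' @param ... Fields of the component, see Return.
#' @export
new_component <- function(...) {
  x <- list(...)
  stopifnot(is.character(x$name), x$M > 0, x$Pc > 0, x$Tc > x$Tb, x$Tb > 0)
  v <- x$volumes
  if (!is.null(v)) {
    stopifnot(all(diff(v$T_K) > 0), all(v$V0_m3mol > 0))
  }
  if (!is.null(x$saft)) {
    stopifnot(x$saft$m >= 1, x$saft$v00 > 0, x$saft$u0k > 0,
              x$saft$kap >= 0, x$saft$kap < 1, x$saft$epsk >= 0)
  }
  structure(x, class = "vlemix_component")
}

#' @export
print.vlemix_component <- function(x, ...) {
  cat("<component> ", x$name, "\n", sep = "")
  cat(sprintf("  M = %.3f g/mol, Tc = %.2f K, Pc = %.3f MPa, omega = %.3f\n",
              x$M, x$Tc, x$Pc / 1e6, x$omega))
  if (!is.null(x$volumes))
    cat(sprintf("  molar volumes tabulated %.2f-%.2f K (%d rows)\n",
                min(x$volumes$T_K), max(x$volumes$T_K), nrow(x$volumes)))
  if (!is.null(x$B_ref))
    cat(sprintf("  B(%g K) = %.0f cm^3/mol\n", x$T_ref, x$B_ref * 1e6))
  invisible(x)
}

#' Liquid molar volume by interpolation in the component's table
#'
#' Linear interpolation of the tabulated saturated-liquid molar volumes.
#' Linear extrapolation is allowed up to 5 K beyond either end of the table
#' and flagged in the `"extrapolated"` attribute; beyond that the call errors.
#'
#' @param comp A [component()] object.
#' @param T_K Temperature(s), K.
#' @return Molar volume(s) in m^3/mol with a logical attribute
#'   `"extrapolated"` of the same length.
#' @export
molar_volume <- function(comp, T_K) {
  tab <- comp$volumes
  lo <- min(tab$T_K); hi <- max(tab$T_K)
  if (any(T_K < lo - 5 | T_K > hi + 5)) {
    rlang::abort(sprintf(
      "temperature outside the tabulated range %.2f-%.2f K (+/- 5 K) for %s",
      lo, hi, comp$name))
  }
  out <- stats::approx(tab$T_K, tab$V0_m3mol, xout = T_K, rule = 2)$y
  extra <- T_K < lo | T_K > hi
  if (any(extra)) {
    # linear extrapolation from the terminal slope
    for (i in which(extra)) {
      if (T_K[i] < lo) {
        sl <- (tab$V0_m3mol[2] - tab$V0_m3mol[1]) / (tab$T_K[2] - tab$T_K[1])
        out[i] <- tab$V0_m3mol[1] + sl * (T_K[i] - lo)
      } else {
        n <- nrow(tab)
        sl <- (tab$V0_m3mol[n] - tab$V0_m3mol[n - 1]) /
          (tab$T_K[n] - tab$T_K[n - 1])
        out[i] <- tab$V0_m3mol[n] + sl * (T_K[i] - hi)
      }
    }
  }
  attr(out, "extrapolated") <- extra
  out
}

#' Cross second virial coefficient and the vapor-correction combination
#'
#' The unlike-pair virial coefficient follows the cubic Lorenz combining rule
#' \eqn{B_{12} = \frac{1}{8}(B_{11}^{1/3} + B_{22}^{1/3})^3} (signed cube
#' roots, both inputs negative), and
#' \eqn{\delta_{12} = 2B_{12} - B_{11} - B_{22}} is the combination entering
#' the vapor-phase corrections of the total-pressure reduction.
#'
#' @param B11,B22 Pure second virial coefficients, m^3/mol (negative).
#' @return A list with `B12` and `delta12`, m^3/mol.
#' @examples
#' virial_cross(-1810e-6, -5490e-6)
#' @export
virial_cross <- function(B11, B22) {
  stopifnot(B11 < 0 || B11 == 0, B22 < 0 || B22 == 0)
  cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
  B12 <- ((cbrt(B11) + cbrt(B22)) / 2)^3
  list(B12 = B12, delta12 = 2 * B12 - B11 - B22)
}
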