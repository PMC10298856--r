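test_that("alpha functions are normalized at Tc and reduce when switched off", {
  for (v in c("PRM", "PRSV")) {
    expect_equal(alpha_function(v, 508.3, 508.3, 0.665,
                                if (v == "PRM") -0.256223 else 0.166735), 1)
  }
  # PRM with p1 = 0 equals the plain PR alpha
  Tg <- seq(280, 460, by = 20)
  kpr <- 0.37464 + 1.54226 * 0.665 - 0.26992 * 0.665^2
  plain <- (1 + kpr * (1 - sqrt(Tg / 508.3)))^2
  expect_equal(alpha_function("PRM", Tg, 508.3, 0.665, 0), plain)
  # PRSV with kappa1 = 0 uses only its own kappa0 polynomial
  k0 <- 0.378893 + 1.4897153 * 0.665 - 0.17131848 * 0.665^2 +
    0.0196554 * 0.665^3
  expect_equal(alpha_function("PRSV", Tg, 508.3, 0.665, 0),
               (1 + k0 * (1 - sqrt(Tg / 508.3)))^2)
  # positive over the working range for the study parameters
  expect_true(all(alpha_function("PRM", seq(278, 450, 2), 661.12, 0.338,
                                 -0.003518) > 0))
})

test_that("pure saturation pressures track the measured pure pressures", {
  mp <- cubic_model("PRSV")
  expect_equal(pure_saturation(mp, 1, 298.15)$P_Pa, 5781, tolerance = 0.015)
  expect_equal(pure_saturation(mp, 2, 298.15)$P_Pa, 253, tolerance = 0.03)
  mm <- cubic_model("PRM")
  expect_equal(pure_saturation(mm, 1, 298.15)$P_Pa, 5781, tolerance = 0.015)
  expect_equal(pure_saturation(mm, 2, 298.15)$P_Pa, 253, tolerance = 0.03)
  # monotone Psat(T)
  Ps <- vapply(seq(278.15, 323.15, 5), function(T)
    pure_saturation(mp, 1, T)$P_Pa, 0)
  expect_true(all(diff(Ps) > 0))
})

test_that("the shipped PRM sign convention is the one matching the pure data", {
  base <- cubic_model("PRM")
  flipped <- cubic_model("PRM", prm_convention = "plus")
  err <- function(m) abs(pure_saturation(m, 1, 298.15)$P_Pa - 5781)
  expect_lt(err(base), err(flipped))
})

test_that("Peneloux translation changes volumes but not equilibrium", {
  a <- cubic_model("PRSV", translation = TRUE)
  b <- cubic_model("PRSV", translation = FALSE)
  pa <- pure_saturation(a, 1, 298.15); pb <- pure_saturation(b, 1, 298.15)
  expect_identical(pa$P_Pa, pb$P_Pa)
  expect_false(isTRUE(all.equal(pa$v_liq_m3mol, pb$v_liq_m3mol)))
  ba <- bubble_point(a, 298.15, 0.5); bb <- bubble_point(b, 298.15, 0.5)
  expect_identical(ba$P_Pa, bb$P_Pa)
  expect_identical(ba$y1, bb$y1)
})

test_that("interaction parameter and one-fluid mixing behave correctly", {
  expect_equal(eval_kij(kij_coefficients("PRSV-VT"), 298.15), 0.0220,
               tolerance = 1e-2)
  expect_equal(eval_kij(c(0.1, 0, 0), 400), 0.1)
  # bubble point at the pure endpoints equals the pure saturation solve
  m <- cubic_model("PRSV")
  expect_equal(bubble_point(m, 298.15, 1)$P_Pa,
               pure_saturation(m, 1, 298.15)$P_Pa)
  # endpoint continuity of the interior solution
  ps2 <- pure_saturation(m, 2, 298.15)$P_Pa
  expect_equal(bubble_point(m, 298.15, 1e-7)$P_Pa, ps2, tolerance = 1e-5)
})

test_that("identical dummy components give Raoult behavior", {
  dummy <- component("2-propanol")
  m <- cubic_model("PRSV", dummy, dummy, kij = c(0, 0, 0))
  ps <- pure_saturation(m, 1, 300)$P_Pa
  b <- bubble_point(m, 300, 0.37)
  expect_equal(b$P_Pa, ps, tolerance = 1e-8)
  expect_equal(b$y1, 0.37, tolerance = 1e-8)
})

test_that("ideal-gas limit: Z -> 1 and phi -> 1 as P -> 0", {
  m <- cubic_model("PRSV")
  ab <- vlemix:::.cubic_ab(m, 298.15)
  st <- vlemix:::.cubic_lnphi(m, ab, c(0.4, 0.6), 298.15, 1e-3, "V")
  expect_equal(st$Z, 1, tolerance = 1e-8)
  expect_equal(st$lnphi, c(0, 0), tolerance = 1e-7)
})

test_that("volume roots match a dense pressure-isotherm scan", {
  m <- cubic_model("PRSV")
  ab <- vlemix:::.cubic_ab(m, 298.15)
  set.seed(42)
  for (i in 1:20) {
    x1 <- runif(1, 0.05, 0.95)
    P <- 10^runif(1, 2, 5)
    st <- vlemix:::.cubic_lnphi(m, ab, c(x1, 1 - x1), 298.15, P, "L")
    v <- st$v + 0 # untranslated volume from Z
    # residual of the pressure-explicit EoS at the root
    am <- as.numeric(t(c(x1, 1 - x1)) %*%
      ((1 - eval_kij(m$kij, 298.15) * (1 - diag(2))) *
         sqrt(outer(ab$ai, ab$ai))) %*% c(x1, 1 - x1))
    bm <- sum(c(x1, 1 - x1) * ab$bi)
    Pback <- 8.314462618 * 298.15 / (v - bm) - am / (v^2 + 2 * bm * v - bm^2)
    expect_equal(Pback, P, tolerance = 1e-8)
  }
})

test_that("pure alpha-parameter refits land near the tabulated values", {
  kap1 <- fit_pure_alpha_param("PRSV", ipa, propanol_pressures(),
                               interval = c(0, 0.5))
  expect_equal(kap1, 0.166735, tolerance = 0.02)
  p1 <- fit_pure_alpha_param("PRM", ipa, propanol_pressures(),
                             interval = c(-0.5, 0))
  expect_equal(p1, -0.256223, tolerance = 0.03)
  # synthetic recovery is essentially exact
  m <- cubic_model("PRSV")
  d <- data.frame(T_K = seq(280, 320, 10))
  d$P_Pa <- vapply(d$T_K, function(T) pure_saturation(m, 1, T)$P_Pa, 0)
  expect_equal(fit_pure_alpha_param("PRSV", ipa, d, c(0, 0.5)), 0.166735,
               tolerance = 1e-4)
})

test_that("AAD arithmetic", {
  expect_equal(aad_percent(c(100, 200), c(110, 180)), 10)
  expect_equal(aad_percent(c(5, 7, 9), c(5, 7, 9)), 0)
})

test_that("kij refit on a single isotherm recovers a self-generated kij", {
  m <- cubic_model("PRSV", kij = c(0.035, 0, 0))
  x2 <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  d <- tibble::tibble(T_K = 298.15, x2 = x2,
                      P_Pa = vapply(1 - x2, function(x1)
                        bubble_point(m, 298.15, x1)$P_Pa, 0))
  kf <- fit_kij(cubic_model("PRSV", kij = c(0, 0, 0)), d)
  expect_equal(kf$by_isotherm$kij, 0.035, tolerance = 1e-4)
  expect_lt(kf$by_isotherm$aad_pct, 0.01)
})
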