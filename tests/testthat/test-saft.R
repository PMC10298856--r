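sm <- saft_model()

test_that("residual terms vanish in the ideal-gas limit", {
  st <- saft_state(sm, 0.4, 298.15, 1e-6)
  expect_equal(unname(st$terms), rep(0, 4), tolerance = 1e-6)
  expect_equal(st$Z, 1, tolerance = 1e-6)
  # phi -> 1 at vanishing pressure
  lp <- saft_lnphi(sm, 0.4, 298.15, 1e-3, "V")
  expect_equal(lp, c(0, 0), tolerance = 1e-6)
})

test_that("spherical non-associating molecules have no chain or association term", {
  mono <- component("1,8-cineole")
  mono$saft$m <- 1
  m1 <- saft_model(mono, mono, kij = c(0, 0, 0))
  st <- saft_state(m1, 1, 300, 5000)
  expect_equal(unname(st$terms[c("chain", "assoc")]), c(0, 0))
  expect_equal(st$X, 1)
})

test_that("association solver matches the closed form and its limits", {
  # iterative successive substitution vs closed form across densities
  for (rho in c(50, 500, 5000, 13000)) {
    X_it <- association_fractions(sm, 1, 298.15, rho)
    st <- saft_state(sm, 1, 298.15, rho)
    expect_equal(X_it, st$X, tolerance = 1e-10)
    expect_true(X_it > 0 && X_it <= 1)
  }
  # kappa = 0 forces X = 1
  expect_equal(association_fractions(saft_model(component("1,8-cineole"),
                                                component("2-propanol"),
                                                kij = c(0, 0, 0)),
                                     1, 298.15, 5000), 1)
  # X decreases monotonically toward 0 as association strengthens
  rhos <- c(100, 1000, 5000, 12000, 14000)
  Xs <- vapply(rhos, function(r) saft_state(sm, 1, 298.15, r)$X, 0)
  expect_true(all(diff(Xs) < 0))
  expect_gt(min(Xs), 0)
})

test_that("pressure equals the numeric density derivative of the Helmholtz energy", {
  set.seed(7)
  for (i in 1:10) {
    x1 <- runif(1); T <- runif(1, 280, 330)
    rho <- runif(1, 100, 12000)
    st <- saft_state(sm, x1, T, rho)
    h <- rho * 1e-6
    dad <- (saft_state(sm, x1, T, rho + h)$a -
            saft_state(sm, x1, T, rho - h)$a) / (2 * h)
    Z_num <- 1 + rho * dad
    expect_equal(st$Z, Z_num, tolerance = 1e-8)
  }
})

test_that("analytic and numeric fugacity coefficients agree", {
  set.seed(11)
  for (i in 1:8) {
    x1 <- runif(1, 0.05, 0.95)
    T <- runif(1, 280, 325)
    phase <- sample(c("L", "V"), 1)
    P <- if (phase == "L") 10^runif(1, 3, 5) else 10^runif(1, 2, 3.3)
    la <- saft_lnphi(sm, x1, T, P, phase)
    ln <- saft_lnphi(sm, x1, T, P, phase, method = "numeric")
    expect_lt(max(abs(la - ln)), 1e-6)
  }
})

test_that("Gibbs-Duhem holds for the SAFT fugacity coefficients", {
  T <- 298.15; P <- 3000
  h <- 1e-3   # larger step: the residual is density-solver-noise limited
  for (x1 in c(0.25, 0.6)) {
    lp <- saft_lnphi(sm, x1 + h, T, P, "L")
    lm <- saft_lnphi(sm, x1 - h, T, P, "L")
    d <- (lp - lm) / (2 * h)
    # at fixed T and P: x1 dlnphi1/dx1 + x2 dlnphi2/dx1 = 0
    expect_lt(abs(x1 * d[1] + (1 - x1) * d[2]), 1e-5)
  }
})

test_that("pure-component predictions sit near the measured values", {
  ps <- pure_saturation(sm, 1, 298.15)
  expect_equal(ps$P_Pa, 5781, tolerance = 0.10)     # literature-parameter fit
  vliq <- 1e6 * liquid_volume(sm, 298.15, 1, 101325)
  expect_equal(vliq, 76.93, tolerance = 0.05)
  ps2 <- pure_saturation(sm, 2, 298.15)
  expect_equal(ps2$P_Pa, 253, tolerance = 0.05)
  vliq2 <- 1e6 * liquid_volume(sm, 298.15, 0, 101325)
  expect_equal(vliq2, 167.7, tolerance = 0.05)
})

test_that("density solver respects branch selection and mechanical stability", {
  # low-P vapor density approaches ideal gas
  rho <- saft_density(sm, 0.5, 298.15, 10, "V")
  expect_equal(rho, 10 / (8.314462618 * 298.15), tolerance = 1e-3)
  # liquid density increases with pressure
  rhos <- vapply(c(1e5, 5e6, 2e7), function(P)
    saft_density(sm, 1, 298.15, P, "L"), 0)
  expect_true(all(diff(rhos) > 0))
  # the two branches differ at saturation-like conditions
  expect_gt(saft_density(sm, 1, 298.15, 5000, "L") /
            saft_density(sm, 1, 298.15, 5000, "V"), 100)
})

test_that("mixture reduces to the pure model at unit composition", {
  st_mix <- saft_state(sm, 1, 300, 8000)
  pure <- saft_model(component("2-propanol"), component("2-propanol"),
                     kij = c(0, 0, 0))
  st_pure <- saft_state(pure, 1, 300, 8000)
  expect_equal(st_mix$a, st_pure$a, tolerance = 1e-12)
  expect_equal(st_mix$Z, st_pure$Z, tolerance = 1e-12)
})

test_that("only SAFT reproduces the negative excess volume of the mixture", {
  ve_saft <- predict_excess_volume(sm, 298.15, x2 = c(0, 0.5, 1))
  expect_equal(ve_saft$VE_m3mol[c(1, 3)], c(0, 0))
  expect_lt(ve_saft$VE_m3mol[2], 0)
  ve_prsv <- predict_excess_volume(cubic_model("PRSV"), 298.15, x2 = 0.5)
  ve_prm <- predict_excess_volume(cubic_model("PRM"), 298.15, x2 = 0.5)
  expect_gt(ve_prsv$VE_m3mol, 0)
  expect_gt(ve_prm$VE_m3mol, 0)
})

test_that("SAFT bubble point converges to the pure limit", {
  b <- bubble_point(sm, 298.15, 1)
  expect_equal(b$P_Pa, pure_saturation(sm, 1, 298.15)$P_Pa)
  b2 <- bubble_point(sm, 298.15, 0.999)
  expect_equal(b2$P_Pa, b$P_Pa, tolerance = 0.01)
})
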