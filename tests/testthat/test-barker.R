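test_that("forward pressure model has the right limits", {
  pu <- study_pure_inputs(298.15)
  vir <- study_virials()
  # pure limits
  b1 <- barker_pressure(1, 298.15, 0.4815, 0.5434, pu, vir)
  expect_equal(b1$P_calc_Pa, pu$P1)
  expect_equal(b1$y1, 1)
  b0 <- barker_pressure(0, 298.15, 0.4815, 0.5434, pu, vir)
  expect_equal(b0$P_calc_Pa, pu$P2)
  # Raoult reduction when corrections vanish
  pu0 <- list(P1 = pu$P1, P2 = pu$P2, V1 = 0, V2 = 0)
  vir0 <- list(B11 = 0, B22 = 0, B12 = 0)
  x1 <- c(0.2, 0.5, 0.8)
  g <- wilson_activity(x1, 0.4815, 0.5434)
  expect_equal(barker_pressure(x1, 298.15, 0.4815, 0.5434, pu0, vir0)$P_calc_Pa,
               x1 * g$gamma1 * pu$P1 + (1 - x1) * g$gamma2 * pu$P2,
               tolerance = 1e-10)
  # tabulated mid-composition point: deviation close to the study's 12 Pa
  bm <- barker_pressure(1 - 0.5238, 298.15, 0.4815, 0.5434, pu, vir)
  expect_equal(3894 - bm$P_calc_Pa, 12, tolerance = 0.3)
})

test_that("Barker reduction of study isotherms recovers the published parameters", {
  f <- fit_barker(dplyr::bind_rows(isotherm(298.15), isotherm(278.15)))
  tab <- tidy(f)
  r298 <- tab[tab$T_K == 298.15, ]
  expect_equal(r298$Lambda12, 0.4815, tolerance = 0.002 / 0.4815)
  expect_equal(r298$Lambda21, 0.5434, tolerance = 0.002 / 0.5434)
  expect_equal(r298$s_Pa, 16, tolerance = 3 / 16)
  expect_equal(r298$dlam12_11_Jmol, 3743, tolerance = 2 / 3743)
  r278 <- tab[tab$T_K == 278.15, ]
  expect_equal(r278$Lambda12, 0.4255, tolerance = 0.002 / 0.4255)
  expect_equal(r278$Lambda21, 0.5511, tolerance = 0.008 / 0.5511)
  expect_equal(r278$s_Pa, 12, tolerance = 3 / 12)
  # residual definition consistency: sum(dP^2)/(N-2) == s^2
  pts <- augment(f)
  p298 <- pts[pts$T_K == 298.15, ]
  expect_equal(sum(p298$dP_Pa^2) / (nrow(p298) - 2), r298$s_Pa^2)
  # GE non-negative over fitted points
  expect_true(all(pts$GE_Jmol >= 0))
})

test_that("reported activity coefficients and GE are reproduced at the tabulated parameters", {
  wr <- wilson_reference()
  vd <- vle_data()
  for (i in seq_len(nrow(wr))) {
    d <- vd[vd$T_K == wr$T_K[i], ]
    g <- wilson_activity(1 - d$x2, wr$Lambda12[i], wr$Lambda21[i])
    ge <- 8.314462618 * wr$T_K[i] * wilson_gibbs(1 - d$x2, wr$Lambda12[i], wr$Lambda21[i])
    expect_lt(max(abs(g$gamma1 - d$gamma1)), 1e-3)
    expect_lt(max(abs(g$gamma2 - d$gamma2)), 1e-3)
    expect_lt(max(abs(ge - d$GE_Jmol)), 1)
  }
})

test_that("noiseless synthetic isotherms are recovered essentially exactly", {
  sp <- synth_spec(sigma_P = 0)
  d <- synth_isotherm(sp, 298.15)
  f <- fit_barker(d[, c("T_K", "x2", "P_Pa")], pressures = "antoine")
  expect_equal(f$isotherms$Lambda12, 0.4815, tolerance = 1e-5)
  expect_equal(f$isotherms$Lambda21, 0.5434, tolerance = 1e-5)
  expect_lt(f$isotherms$s_Pa, 0.05)
})

test_that("component relabeling symmetry: mirrored data give identical pressures", {
  pu <- study_pure_inputs(298.15)
  vir <- study_virials()
  # mirrored system: swap components, Lambdas, x -> 1-x
  pu_m <- list(P1 = pu$P2, P2 = pu$P1, V1 = pu$V2, V2 = pu$V1)
  vir_m <- list(B11 = vir$B22, B22 = vir$B11, B12 = vir$B12)
  x1 <- seq(0.05, 0.95, by = 0.1)
  a <- barker_pressure(x1, 298.15, 0.4815, 0.5434, pu, vir)
  b <- barker_pressure(1 - x1, 298.15, 0.5434, 0.4815, pu_m, vir_m)
  expect_equal(a$P_calc_Pa, b$P_calc_Pa, tolerance = 1e-10)
  expect_equal(a$y1, 1 - b$y1, tolerance = 1e-8)
})

test_that("interaction-energy trend reproduces the study's smoothed values", {
  wr <- wilson_reference()
  tr <- fit_lambda_trend(dplyr::rename(wr, dlam12_11_Jmol = dlam11_Jmol,
                                       dlam12_22_Jmol = dlam22_Jmol))
  p <- predict(tr, T_K = c(298.15, 303.15))
  expect_equal(p$dlam12_11_Jmol[1], 3752, tolerance = 1 / 3752)
  expect_equal(p$dlam12_22_Jmol[2], -416, tolerance = 1 / 416)
  # smoothed values at every tabulated T agree with the printed trend column
  all_p <- predict(tr, T_K = wr$T_K)
  expect_lt(max(abs(all_p$dlam12_11_Jmol - wr$dlam11_trend_Jmol)), 1)
  expect_lt(max(abs(all_p$dlam12_22_Jmol - wr$dlam22_trend_Jmol)), 1)
  # degenerate constant series: zero slope, intercept equal to the constant
  const <- tibble::tibble(T_K = c(280, 300, 320),
                          dlam12_11_Jmol = 1000, dlam12_22_Jmol = -5)
  trc <- fit_lambda_trend(const)
  expect_equal(unname(coef(trc$fit11)), c(1000, 0), tolerance = 1e-10)
  expect_equal(predict(trc, 310)$dlam12_22_Jmol, -5, tolerance = 1e-10)
})
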