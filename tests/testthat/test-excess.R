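test_that("excess volume from densities matches hand evaluation and endpoints", {
  expect_equal(1e6 * excess_volume(0.5011, 880.21, 780.99, 920.34),
               -0.4984, tolerance = 1e-3)
  expect_equal(excess_volume(0, 780.99, 780.99, 920.34), 0)
  expect_equal(excess_volume(1, 920.34, 780.99, 920.34), 0)
  # endpoint identity at every bundled temperature
  dd <- density_data()
  for (Tt in unique(dd$T_K)) {
    d <- dd[dd$T_K == Tt, ]
    r1 <- d$rho_kgm3[d$x2 == 0]; r2 <- d$rho_kgm3[d$x2 == 1]
    expect_equal(excess_volume(c(0, 1), c(r1, r2), r1, r2), c(0, 0))
  }
})

test_that("Redlich-Kister fits reproduce the study's coefficient table", {
  he <- dplyr::filter(excess_enthalpy_data(), T_K == 298.15)
  fh <- fit_redlich_kister(he, 3, "HE")
  expect_equal(fh$A[1], 2380, tolerance = 5 / 2380)
  expect_equal(fh$A[2], -768, tolerance = 5 / 768)
  expect_equal(fh$A[3], 75, tolerance = 2 / 75)
  expect_equal(fh$s, 6.6, tolerance = 0.15)

  ve <- excess_volume_curve(dplyr::filter(density_data(), T_K == 298.15))
  ve$VE_cm3mol <- ve$VE_m3mol * 1e6
  fv <- fit_redlich_kister(ve[, c("T_K", "x2", "VE_cm3mol")], 4, "VE")
  expect_equal(fv$A[1], -1.979, tolerance = 0.01 / 1.979)
  expect_equal(fv$A, c(-1.979, -0.247, -0.765, -0.300), tolerance = 0.12)
  expect_lt(fv$s, 0.01)
})

test_that("RK fit round-trips exact data and evaluates correctly", {
  A <- c(1500, -300, 80, 40)
  x2 <- seq(0.05, 0.95, by = 0.05)
  d <- tibble::tibble(x2 = x2, Q = eval_redlich_kister(A, x2))
  f <- fit_redlich_kister(d, 4)
  expect_equal(f$A, A, tolerance = 1e-10)
  expect_equal(f$s, 0, tolerance = 1e-9)
  # evaluation: odd terms vanish at equimolar; endpoints are zero
  expect_equal(eval_redlich_kister(c(2380, -768, 75), 0.5), 595)
  expect_equal(eval_redlich_kister(A, c(0, 1)), c(0, 0))
  # fitted curve agrees with the data within the fit's own s-based band
  he <- dplyr::filter(excess_enthalpy_data(), T_K == 298.15)
  fh <- fit_redlich_kister(he, 3)
  pred <- eval_redlich_kister(fh$A, fh$points$x2)
  N <- nrow(fh$points)
  expect_lt(max(abs(pred - fh$points$value)), fh$s * sqrt(N / (N - 3)) * 3)
  # tabulated point at x2 = 0.510 is reproduced within s
  expect_equal(eval_redlich_kister(fh$A, 0.510), 599, tolerance = fh$s / 599)
  expect_error(fit_redlich_kister(d[1:3, ], 4), "more interior points")
})

test_that("both excess properties increase with temperature (leading coefficient)", {
  A0_he <- vapply(c(288.15, 298.15, 308.15, 318.15), function(Tt) {
    fit_redlich_kister(dplyr::filter(excess_enthalpy_data(), T_K == Tt), 3)$A[1]
  }, 0)
  expect_true(all(diff(A0_he) > 0))
  A0_ve <- vapply(c(288.15, 298.15, 308.15, 318.15), function(Tt) {
    ve <- excess_volume_curve(dplyr::filter(density_data(), T_K == Tt))
    fit_redlich_kister(ve, 4)$A[1]
  }, 0)
  expect_true(all(diff(A0_ve) > 0)) # less negative as T rises
})

test_that("excess heat capacity from the H^E temperature trend", {
  d <- data.frame(T_K = c(288.15, 298.15, 308.15, 318.15),
                  HE_Jmol = c(517, 599, 663, 749))
  expect_equal(cp_excess(d), 7.6, tolerance = 1e-10)
  expect_equal(cp_excess(data.frame(T_K = c(290, 300, 310), HE_Jmol = 500)), 0)
  expect_equal(cp_excess(data.frame(T_K = c(288.15, 318.15),
                                    HE_Jmol = c(517, 749))), 232 / 30)
})

test_that("Gibbs-Helmholtz H^E has the right shape, scale and stability", {
  wr <- wilson_reference()
  tr <- fit_lambda_trend(dplyr::rename(wr, dlam12_11_Jmol = dlam11_Jmol,
                                       dlam12_22_Jmol = dlam22_Jmol))
  gh <- gibbs_helmholtz_he(tr, T_K = 298.15, dT = 5)
  # positive with a single interior maximum, hundreds of J/mol
  expect_true(all(gh$HE_Jmol > 0))
  expect_equal(sum(diff(sign(diff(gh$HE_Jmol))) != 0), 1)
  expect_gt(max(gh$HE_Jmol), 300)
  expect_lt(max(gh$HE_Jmol), 1500)
  # TS^E identity
  expect_equal(gh$TSE_Jmol, gh$HE_Jmol - gh$GE_Jmol)
  # halving the step changes the curve by < 1 %
  gh2 <- gibbs_helmholtz_he(tr, T_K = 298.15, dT = 2.5)
  expect_lt(max(abs(gh2$HE_Jmol - gh$HE_Jmol) / abs(gh$HE_Jmol)), 0.01)
})

test_that("finite-difference GH derivative matches the closed form for constant volumes", {
  # constant-volume components: flat molar-volume tables
  flatc <- function(base, V) {
    base$volumes <- tibble::tibble(T_K = c(250, 350), V0_m3mol = c(V, V))
    base
  }
  c1 <- flatc(component("2-propanol"), 76.93e-6)
  c2 <- flatc(component("1,8-cineole"), 167.7e-6)
  tr <- fit_lambda_trend(tibble::tibble(
    T_K = c(280, 300, 320), dlam12_11_Jmol = 3750, dlam12_22_Jmol = -420))
  fd <- gibbs_helmholtz_he(tr, c1, c2, T_K = 298.15, dT = 1)
  an <- gibbs_helmholtz_he(tr, c1, c2, T_K = 298.15, analytic = TRUE)
  expect_equal(fd$HE_Jmol, an$HE_Jmol, tolerance = 1e-4)
})

test_that("consistency report compares derived and calorimetric H^E", {
  wr <- wilson_reference()
  tr <- fit_lambda_trend(dplyr::rename(wr, dlam12_11_Jmol = dlam11_Jmol,
                                       dlam12_22_Jmol = dlam22_Jmol))
  fh <- fit_redlich_kister(dplyr::filter(excess_enthalpy_data(), T_K == 298.15),
                           3, "HE")
  cc <- gh_consistency(tr, fh, T_K = 298.15)
  # same sign and order of magnitude across the composition range
  expect_true(all(cc$grid$HE_Jmol > 0))
  expect_lt(cc$summary$rms_diff_Jmol, 300)
  expect_equal(cc$grid$TSE_Jmol, cc$grid$HE_Jmol - cc$grid$GE_Jmol)
})
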