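---
title: "Methods: reducing and modeling isothermal VLE of (2-propanol + 1,8-cineole)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reducing and modeling isothermal VLE of (2-propanol + 1,8-cineole)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlemix)
library(dplyr)
```

vlemix implements the complete computational chain of an isothermal
vapor-liquid-equilibrium (VLE) study of the binary liquid mixture
2-propanol (1) + 1,8-cineole (2): reduction of total-pressure P-x
measurements to activity coefficients and excess Gibbs energies, fitting of
calorimetric and volumetric excess properties, a thermodynamic consistency
test connecting the two, and correlation of the same data with three
equations of state.  The full experimental record (ten isotherms of twelve
points between 278.15 and 323.15 K, plus excess enthalpies and densities at
four temperatures) ships with the package as plain-text fixtures, so every
number in this vignette is recomputed from the printed data at build or test
time.

## Pure components

Pure 2-propanol vapor pressures are represented by the ln-form Antoine
equation $\ln(P^0/\mathrm{kPa}) = A - B/(T/\mathrm{K} - C)$.
`fit_antoine()` offers two objectives.  The default minimizes squared
deviations of $\ln P$: over a pressure range spanning 1.5-24 kPa this
weights all ten temperatures evenly, and it is the objective that reproduces
the study's published constants (17.6939, 4114.55, 39.969) and its quoted
standard deviation of 25 Pa (computed, like every deviation measure in the
package, as $s = \{\sum (X - X_{calc})^2/(N - n)\}^{1/2}$ in pressure
units).  A pressure-space objective is available behind
`objective = "pressure"`; it concentrates accuracy at the high-pressure end
and yields $s \approx 18$ Pa with visibly larger low-temperature relative
errors.  We ship `lnp` as the default because it is the choice that matches
the published reduction and because relative pressure accuracy is what the
downstream Barker reduction consumes.

Second virial coefficients are treated as constants at 325.0 K
($B_{11} = -1810$, $B_{22} = -5490$ cm$^3$/mol), the temperature at which
the vapor phase of the static apparatus was thermostatted; no temperature
dependence of $B$ is modeled.  The cross coefficient uses the cubic Lorenz
rule $B_{12} = \frac18 (B_{11}^{1/3} + B_{22}^{1/3})^3$ with signed cube
roots, and $\delta_{12} = 2B_{12} - B_{11} - B_{22}$.  Molar volumes
interpolate each component's table linearly, with extrapolation allowed
(and flagged) up to 5 K beyond the tabulated range.

## Barker reduction with the Wilson model

For each isotherm, `fit_barker()` finds the Wilson parameters
$(\Lambda_{12}, \Lambda_{21})$ minimizing the unweighted sum of squared
pressure residuals.  Inside the objective, `barker_pressure()` solves

$$P_{calc} = x_1\gamma_1 P_1^0 R_1 + x_2\gamma_2 P_2^0 R_2, \qquad
R_1 = \exp\frac{(V_1^0 - B_{11})(P - P_1^0) - P\,\delta_{12} y_2^2}{RT}$$

by fixed-point iteration on $(P, y)$, started from the ideal-vapor
solution, to 0.01 Pa -- an order of magnitude below the 13 Pa pressure
reproducibility of the measurements, so the inner tolerance contributes
nothing to the fitted parameters.  The isotherm temperature is used in the
$RT$ denominators while the virial coefficients stay at their 325 K values,
mirroring the apparatus.  The objective is unweighted because the reported
per-isotherm deviations are unweighted and the pressure range within one
isotherm is modest.  The optimizer is Nelder-Mead started at
$\Lambda_{12} = \Lambda_{21} = 0.5$ (the middle of the range the system
occupies), restarted once at its own optimum; parameters outside
$(0.05, 20)$ trigger a warning.

The signs in the activity-coefficient bracket (the typography of which is
ambiguous in many sources) are pinned down by two tests: the Gibbs-Duhem
residual $x_1 \mathrm{d}\ln\gamma_1/\mathrm{d}x_1 + x_2
\mathrm{d}\ln\gamma_2/\mathrm{d}x_1$ must vanish, and the reduction must
reproduce the study's printed $\gamma$ and $G^E_m$ columns at its tabulated
parameters (it does, to $\pm 0.001$ in $\gamma$ and $\pm 1$ J/mol in
$G^E_m$; the residual 0.001 rather than a half printed digit reflects the
four-digit rounding of the published $\Lambda$'s).

```{r barker}
fit <- fit_barker(filter(vle_data(), T_K %in% c(278.15, 298.15, 323.15)))
tidy(fit)
```

Interaction-energy differences follow from
$\Lambda_{ij} = (V^0_j/V^0_i)\exp[-(\lambda_{ij}-\lambda_{ii})/RT]$, and
`fit_lambda_trend()` smooths them linearly in temperature across the ten
isotherms, which is what the consistency test differentiates.

## Excess properties

Excess molar volumes come from densities via
$V^E_m = x_1M_1(1/\rho - 1/\rho_1) + x_2M_2(1/\rho - 1/\rho_2)$, using each
temperature's own pure-density rows as endpoints.  Both excess properties
are smoothed with Redlich-Kister polynomials
$Q^E_m = x_1x_2\sum_{j=0}^{k-1} A_j(x_1 - x_2)^j$ -- three coefficients for
$H^E_m$, four for $V^E_m$, matching the structure of the published
coefficient table.  The leading coefficient is indexed $A_0$ (so the
equimolar value is $A_0/4$); endpoint rows are excluded from the linear
least squares since the basis vanishes there identically, and their
inclusion would only add zero-variance rows.  The basis is linear in the
coefficients, so the fit is a QR solve, and a noiseless round trip is exact
to machine precision.

At $x_2 \approx 0.51$ the excess enthalpy grows almost linearly with
temperature; the least-squares slope of the four tabulated values is the
excess heat capacity estimate $C^E_{P,m} \approx 7.6$ J/(mol K).

```{r rk}
fh <- fit_redlich_kister(filter(excess_enthalpy_data(), T_K == 298.15), 3, "HE")
fh
```

## Gibbs-Helmholtz consistency

Because vapor compositions are computed rather than measured, the
Gibbs-Duhem test cannot be applied to the raw measurements; instead the
package cross-checks the two independent experimental routes via
$H^E_m = [\partial(G^E_m/T)/\partial(1/T)]_{P,x}$.
`gibbs_helmholtz_he()` rebuilds $G^E(x, T)$ at $T \pm \Delta T$ from the
smoothed $\lambda$-trends and the temperature-dependent molar-volume ratio,
and differentiates by central difference with $\Delta T = 5$ K by default.
A finite difference is used rather than the analytic Wilson derivative
because $\Lambda(T)$ inherits temperature dependence from the molar-volume
ratio as well as from $RT$; the analytic constant-volume form is retained
(`analytic = TRUE`) and agrees with the finite difference to better than
0.1% when volumes are held constant, while halving $\Delta T$ moves the
derived curve by less than 1%.  The derived $H^E$ is positive with a single
interior maximum of the same order (hundreds of J/mol) as the calorimetric
curve, which is the qualitative agreement the test is after --
quantitatively, enthalpies differentiated from vapor pressures carry
substantial uncertainty.  $TS^E = H^E - G^E$ is reported alongside.

## Equations of state

Two Peng-Robinson variants and one SAFT model correlate the same 120 state
points, all with van der Waals one-fluid mixing and a quadratic
$k_{ij}(T) = a + bT + cT^2$ (T in kelvin) fitted by the original study and
bundled here.

**Cubics.** PRM uses the Mathias polar extension
$\sqrt\alpha = 1 + \kappa_{PR}(1 - \sqrt{T_r}) - p_1(1 - T_r)(0.7 - T_r)$;
PRSV the Stryjek-Vera $\kappa_0 + \kappa_1(1 + \sqrt{T_r})(0.7 - T_r)$
form.  The sign convention of the Mathias term is genuinely ambiguous
across implementations, so it is a constructor switch; the shipped default
(`"minus"`, with the tabulated negative $p_1$ values) reproduces the
measured pure vapor pressures of both components within about 1.5% across
278-323 K, while the opposite convention misses 2-propanol by over 40%.
$\Omega_a = 0.457235$ and $\Omega_b = 0.077796$ are fixed.  Peneloux
translation is implemented as a reporting-time shift
$c_i = (c/b)_i b_i$ of the molar volumes: it never enters the fugacity
equality, so bubble pressures and vapor compositions are bit-identical with
translation on or off -- asserted in the tests rather than assumed.
Volume-root selection takes the smallest real root above $b$ for the
liquid, the largest for the vapor.

**SAFT.** The original square-well-segment formulation: temperature-
dependent segment volume $v^0 = v^{00}[1 - 0.12\exp(-3u^0/kT)]^3$, segment
energy $u/k = (u^0/k)(1 + e/kT)$ with $e/k = 10$ K for both compounds,
hard-sphere term $\bar m(4\eta - 3\eta^2)/(1 - \eta)^2$, the universal
24-constant dispersion series, chain term $(1 - m)\ln g_{hs}$, and 2B
association (one donor, one acceptor) on the alkanol with no sites on the
ether -- so the model deliberately omits alkanol-ether cross-association,
a recorded limitation rather than an oversight, given the spectroscopic
evidence for OH-O complexation in this mixture.  The association strength
is $\Delta = \sqrt2\,v^0_1\,g_{hs}\,\kappa^{AB}[\exp(\epsilon^{AB}/kT)-1]$;
the 2B site balance has a closed-form solution which the general damped
successive-substitution solver (`association_fractions()`, residual
$<10^{-12}$) reproduces to $10^{-10}$.

For the mixture we evaluated both canonical one-fluid forms of this SAFT
family: the fully quadratic rule (cross segment volumes
$v_{ij} = ((v_i^{1/3}+v_j^{1/3})/2)^3$ inside both the packing fraction and
the energy average) and the volume-fraction rule
($\eta = \tau\rho\sum x_im_iv_i$,
$u/kT = \sum\sum f_if_ju_{ij}/kT$ with $f_i \propto x_im_iv_i$).  With the
bundled $k_{ij}(T)$ regression the volume-fraction rule reproduces the
study's correlation quality (overall AAD 20.5% vs the reported 19.3%) and
per-isotherm refits of $k_{ij}$ land near the published magnitudes, while
the fully quadratic rule needs $k_{ij}$ values five times larger and scores
24.5%; the volume-fraction form is therefore the package default.  The
binary parameter enters only the cross segment energy
$u_{ij} = (1 - k_{ij})\sqrt{u_iu_j}$.

Fugacity coefficients come from analytic composition derivatives of the
residual Helmholtz energy at constant $T, V$; a central-difference route is
kept (`saft_lnphi(..., method = "numeric")`) and must agree within
$10^{-6}$, which together with the $P$-vs-$\partial A/\partial\rho$
identity ($<10^{-8}$) pins the implementation's internal consistency.
Density solves use Newton iteration on the packing fraction (vapor started
from the ideal gas, liquid from $\eta = 0.45$) with a bracketed-scan
fallback; bubble points use successive substitution on
$K_i = \varphi_i^L/\varphi_i^V$ to a relative pressure change of
$10^{-9}$.

Model quality is scored by $\mathrm{AAD} = (100/N)\sum|P_{exp} -
P_{calc}|/P_{exp}$ over all 120 points (the averaging set is a package
choice; the per-isotherm breakdown is always reported so any other
averaging can be reconstructed).  The characteristic volumetric contrast is
checked as a sign property at ambient pressure, 298.15 K: SAFT predicts the
observed negative equimolar $V^E$, both translated cubics predict positive
values.  Excess-volume predictions are evaluated at 101.325 kPa since the
density measurements are ambient-pressure.

## Synthetic data and what the tests can show

`synth_spec()` freezes a ground truth -- by default the study's own fitted
Wilson parameters, Antoine constants, the twelve abscissae of the 298.15 K
isotherm, and additive Gaussian pressure noise of 13 Pa, the instrument
reproducibility.  The noise is additive rather than relative because the
manometer error is constant in pressure.  `synth_isotherm()` runs the full
forward model (not a shortcut around it), `synth_excess_curves()` inverts
the density relation from a Redlich-Kister $V^E$ so endpoints are exact by
construction, and `recovery_report()` summarizes bias, RMSE, median
relative error and empirical 95%-band coverage over replicates.  Under the
study's noise level the Wilson parameters come back with median relative
errors below 2%.

The generator emulates the study conditions (grid, noise scale,
temperature range).  It does not emulate mole-fraction drift between
isotherms, correlated manometer errors, or impurity effects -- so passing
recovery tests demonstrate estimator correctness under the stated error
model, not robustness to every artifact of real apparatus.

Problem sizes throughout the test suite are the study's own: ten isotherms
of twelve points, eleven-point excess curves, and a few dozen Monte-Carlo
replicates for the recovery checks, which keeps the whole suite in the
one-to-two-minute range on one core.

## Numerical choices and limitations

* SI units internally (Pa, K, m$^3$/mol, J/mol); $R = 8.314462618$
  J/(mol K); conversions only at interfaces (kPa in Antoine constants,
  cm$^3$/mol in reported RK coefficients for $V^E$).
* The Barker inner fixed point and the bubble-point successive
  substitution both warn (with state) rather than silently return on
  non-convergence; neither occurs over the study's conditions.
* The Tsonopoulos correlation behind the virial coefficients is not
  implemented -- the two coefficients are component constants, because the
  polar parameters needed to re-derive them are not part of the record.
* No azeotrope search (the system shows none in range), no isobaric
  reduction, no NRTL/UNIQUAC alternatives, no flash or dew-point-driven
  fitting, and no multicomponent support: the package models exactly the
  binary, isothermal scope of the study.
* The SAFT Gibbs-Duhem finite-difference residual is solver-noise limited
  near $10^{-5}$; the analytic-vs-numeric fugacity agreement is the
  stronger (and passing) consistency statement.
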