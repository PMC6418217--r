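---
title: "Biogeochemical budgets and process models for a glacier-fed Arctic watershed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biogeochemical budgets and process models for a glacier-fed Arctic watershed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacierLOAC)
```

`glacierLOAC` implements the quantitative backbone of a watershed-scale
biogeochemical study of a large glacier-fed High Arctic lake: how much
water and nutrient mass enters the lake from snowmelt and glacial rivers,
how much leaves through the outflow, what the lake retains or releases,
how fast its sediments consume oxygen, and how its plankton community is
structured along the nutrient-limitation gradient. This vignette explains
the models, their assumptions, the tunable parameters, and the design
choices made where the methods literature leaves the design open.

## The water and mass balance

The central bookkeeping identity is the annual storage change

$$\Delta S = \sum \text{Outputs} - \sum \text{Inputs},$$

with three hydrological inputs — snowmelt on the lake surface, snowmelt
runoff from the ice-free landscape, and glacial river inflow — and a
single river outflow. All loads are carried in metric tons per year
(1 km^3 at 1 mg/L = 1000 t). A negative $\Delta S$ means the lake is a
net sink for that constituent; a positive value a net source (internal
production, dissolution or desorption exceeding retention).

Two conventions deserve comment:

* **Standard errors of sums add linearly**, not in quadrature. This is the
  convention under which the shipped reference budget table is internally
  consistent (each printed total SE equals the sum of its component SEs),
  so the package follows it by default; `sum_inputs(..., se_method =
  "quadrature")` is available for users who prefer independence
  assumptions.
* **Source/sink classification** uses interval disjointness: a budget is
  significant when the $k$-SE intervals around total inputs and total
  outputs do not overlap ($k = 1$ by default). The sign of $\Delta S$ then
  assigns sink or source; overlapping intervals are "neutral". With the
  published table this rule reproduces most, but not all, of the published
  significance stars; the handful of cells where a mechanical 1-SE rule
  and the published stars disagree are asserted in the test suite at the
  rule's arithmetic value and noted there as known discrepancies.
* `percent_difference()` is $100(\text{out}-\text{in})/\text{in}$. The
  corresponding column of the published table is not reproducible from its
  printed loads by any simple formula we tried, so the package reports its
  own definition and does not attempt to match that column.

The outflow is ungauged; its discharge is approximated as the sum of the
modelled glacial inflows plus both snowmelt volumes
(`outflow_discharge()`), which assumes negligible evaporation — recorded
as an attribute on the result.

## Snow hydrology

Snow-core surveys give the areal water volume
$\mathrm{AWV} = w / (\pi r^2)$ (L/m^2, numerically mm of water
equivalent) from core weight $w$ (kg, 1 kg = 1 L) and corer radius $r$
(0.0215 m by default). Replicates are averaged within a site first and
the survey SE is taken across sites, so it reflects spatial variability
of the snowpack rather than replicate noise.

Landscape snowmelt is partitioned with a conservative tracer (sulfate).
If the tracer is conserved in the pack while part of the melt sublimates,
the overland-flow volume fraction is the ratio of snowpack to snowmelt
tracer concentration:

$$f_{\text{runoff}} = c_{\text{pack}} / c_{\text{melt}},$$

with $1 - f$ sublimated. The assumptions are: complete tracer
conservation, no additional tracer sources between pack and stream, and
well-mixed sampling of both pools. With the published concentrations
(1.82 and 14.9 mg/L) this yields 12.2% runoff / 87.8% sublimation. The
source study also quotes a 16% runoff ratio in a table footnote; the
tracer-derived value is the default and the fraction can be overridden
where a user prefers the footnote convention. On-lake snow needs no
partition (it melts into the lake; no sublimation correction is applied),
and its loads use snowpack chemistry, while landscape loads use
snowmelt-stream chemistry, which already integrates elution and
sublimation enrichment.

## Rating-curve river loads

Dissolved constituent loads for each river are estimated from sparse
concentration samplings and continuous (modelled) daily discharge with
log-linear rating curves:

$$\ln L = a_0 + a_1 \ln \hat Q \; (+\; a_2 \ln^2 \hat Q), \qquad
  \ln\hat Q = \ln Q - c,$$

where $L = cQ$ is the instantaneous load and the centering constant $c$
solves $\sum \ln^3\hat Q_i = 0$ over the calibration points, decorrelating
the linear and quadratic terms (the rating-curve software convention; a
plain ln-mean centering is available and annual loads are invariant to
the choice). The model is fitted by ordinary least squares. Because
detection-limit substitution happens upstream (DL/2), no censored values
enter the fits and a censored-likelihood estimator would reduce to OLS —
the reason this package uses OLS with Duan's nonparametric smearing
factor $\widehat{s} = \overline{e^{\hat\varepsilon}}$ to correct
retransformation bias, rather than an AMLE.

Between the linear (form 1) and quadratic (form 2) models, the package
keeps the fit minimizing the absolute **load bias percentage**

$$B_p = 100 \cdot \frac{\sum \hat L_i - \sum L_i}{\sum L_i}$$

over the calibration set, breaking near-ties (0.1 percentage points) by
$r^2$ and then by simplicity. Form 2 requires at least five calibration
points.

Annual loads integrate the smearing-corrected daily predictions over the
melt season (days with zero discharge contribute zero load). The SE comes
from a residual bootstrap with three deliberate refinements, because the
quantity of interest is the *realized* annual load, not the curve's
expectation:

1. resampled residuals are inflated by $\sqrt{n/(n-p)}$ so their variance
   is an unbiased estimate of the residual variance;
2. model selection (form 1 vs 2) can be repeated inside each replicate
   (`reselect = TRUE`), so selection uncertainty is part of the SE;
3. each replicate draws day-level log-normal scatter around its curve
   (`prediction = TRUE`), adding the variance of the realized total about
   the curve's expectation.

Defaults: `n_boot = 500`, seeded. All three refinements can be switched
off to obtain a plain coefficient-uncertainty bootstrap.

Particulate constituents are deliberately out of scope for load models:
their concentration-discharge relations in braided proglacial rivers are
too irregular for log-linear models, and the pipeline follows that
exclusion. Ungauged sub-catchments are handled by area-scaling a
neighbouring modelled runoff series (`scale_runoff_by_area()`), assuming
equal specific runoff.

## Sediment oxygen microprofiles

Porosity per 1-cm core section comes from water loss on freeze-drying,
$\phi = (m_{\text{wet}} - m_{\text{dry}}) / (\rho_w V_{\text{section}})$,
with the 8.6-cm tube giving $V = 58.09$ cm^3. The sediment diffusivity
uses the tortuosity relation $D_s = D_0 / (1 + 3(1 - \phi))$, and the
free-solution $D_0$ for O2 can be taken from a small built-in
temperature-interpolation table (`o2_diffusivity_d0()`) when no
site-specific value is supplied — analyses in this package's tests always
pass $D_0$ explicitly.

The steady-state diagenetic model is

$$\frac{d}{dz}\!\left(\phi D_s \frac{dC}{dz}\right) = R(z),$$

with $R$ piecewise constant over consumption zones ($R > 0$ =
consumption; negative fitted rates are allowed but flagged as
production). The solver uses flux-conservative second-order finite
differences with harmonic-mean interface diffusivities and
control-volume-averaged rates, so zone boundaries need not coincide with
grid nodes; with aligned boundaries the scheme reproduces the piecewise
quadratic closed forms to machine precision. Boundary conditions are
either measured top and bottom concentrations, or — for profiles in which
oxygen is exhausted — zero concentration *and* zero flux at depth, in
which case the one-sided second-order bottom-gradient row replaces the
top equation.

The inverse problem exploits linearity: the forward solution is linear in
the zone rates (and, for concentration boundaries, in the two boundary
values), so fitting is a single linear least squares of the measured
profile on unit-rate basis solutions. The Dirichlet boundary
concentrations are *estimated* as two extra coefficients rather than
pinned to single noisy electrode readings; pinning them transfers their
measurement error into the rates in a way the least-squares covariance
cannot see, and measurably miscalibrates the rate SEs. Zone structure is
chosen by backward merging: starting from `max_zones` equal-thickness
zones, the adjacent pair whose merge (a nested rate-equality constraint)
costs the least SSE is merged while an F test finds the richer model not
significantly better at `alpha = 0.05`; the minimal adequate model is
returned. Depth-integrated consumption $\sum R_i \Delta z_i$ equals the
diffusive flux across the sediment-water interface at steady state, and
the package checks this conservation property numerically.

The sediment-water interface is taken at the operator-recorded zero depth
and is not auto-detected from the gradient.

## Water column and stoichiometry

* `depth_integrated_mean()` is a trapezoidal depth-weighted mean —
  geometric weighting, not hypsographic volume weighting, since no
  hypsometry enters the method.
* `extinction_from_secchi()` uses the Poole-Atkins relation
  $k = 1.7 / z_{SD}$; the constant is an argument for users who prefer
  1.44 or other calibrations.
* Nutrient limitation is classed from the DIN:TP mass ratio with
  inclusive thresholds 1.5 and 3.4 (below: N-limited; above: P-limited;
  between: co-limited).
* `co2_saturation()` speciates DIC with freshwater equilibrium constants
  (Harned & Davis / Harned & Scholes infinite-dilution $K_1, K_2$; Weiss
  CO2 solubility at salinity 0) and reports
  $100 \cdot [\mathrm{CO_2}] / (K_H\, p\mathrm{CO_2})$. Valid for pH 4-10
  in dilute fresh water; no ionic-strength correction is applied, which
  is appropriate for an ultraoligotrophic lake.
* `loac_summary()` orders compartments glacier terminus to outflow,
  splits the lake water column into surface (< 50 m) and bottom
  (>= 200 m) strata, assembles DIN = NH4 + NO3NO2 and
  TC = DIC + DOC + PC per sample, and cross-checks bulk TN against
  DIN + PN (within 20%) when both exist.

Censored analytes are quantified as DL/2 everywhere (summaries and
regressions alike), uniformly flagged `substituted`; the source
literature states the convention only "for statistical purposes", and
applying it uniformly keeps every downstream computation reproducible
from one table.

## Community ordination

Cell densities or biomasses are Hellinger-transformed
($y' = \sqrt{y/\text{rowsum}}$, unit row sum-of-squares) so that
Euclidean ordination is appropriate for species data. PCA is an
eigen-decomposition of the column-centered covariance matrix (divisor
$n-1$), with axis signs fixed so each axis's largest-magnitude loading is
positive. RDA is, definitionally, the PCA of the fitted values of the
multivariate regression of the (transformed) community on standardized
environmental predictors; the package implements it exactly that way and
its constrained eigenvalues agree with the field-standard implementation
to numerical precision (checked in the tests). Collinearity is screened
with VIFs ($1/(1-R^2_j)$), and predictors are chosen by greedy forward
selection under an AIC for the multivariate regression:

$$\mathrm{AIC} = nm \log\!\big(\mathrm{RSS}/(nm)\big) + 2m(k+1),$$

counting one coefficient per response column per predictor. Selection
stops when no candidate lowers AIC; ties break by input column order.
This convention differs in detail from the permutation-based selection of
some ordination software, but it is deterministic, fast, and — because
every added predictor must beat a per-response penalty — appropriately
reluctant on pure-noise predictors.

## The synthetic watershed

Because no field data accompany the package, a seeded generator
(`scenario_config()`, `simulate_watershed()`) produces a full synthetic
field season with known truth, mirroring the study design: seven glacial
rivers over a mid-June-to-end-August melt season (two sampled on the
weekly design, 11 calibration samplings across two years; the rest
synoptically), 20 lake and 13 landscape snow sites with three cores each,
one sediment microprofile at 0.1-mm resolution, and a 30-sample plankton
community. Its structural choices:

* **Hydrographs** are Gaussian seasonal pulses (peak 20 July, width 15 d)
  with multiplicative log-normal daily event noise (log-SD 0.3,
  mean-corrected), emulating melt-dominated nival/glacial regimes.
* **Chemistry** follows power laws in discharge relative to the
  melt-season mean: dissolved species dilute
  ($c \propto q^{-b}$, $b$ = 0.1-0.3), particulates amplify
  ($c \propto q^{+d}$, $d \approx 0.8$), with log-normal noise — the
  qualitative pattern observed in glacial rivers. The realized true
  annual load is recorded for every species.
* **Snow** surveys draw site AWVs around 145 L/m^2 (between-site SD 30)
  and build core weights through the corer geometry; the snowmelt tracer
  concentration is snowpack concentration divided by the true runoff
  fraction (0.122), so the tracer partition inverts exactly when noise
  is off.
* **Sediment** profiles are forward-solved from two consumption zones
  with depth-integrated rates of order $10^{-3}$ nmol cm^-2 s^-1 and
  Gaussian electrode noise (SD 2 umol/L); readings may dip slightly
  negative where oxygen is exhausted, as real electrode output does —
  they are not clipped, which would bias the inversion.
* **Communities** give six taxonomic groups monotone logistic responses
  to a DIN:TP gradient (mixotroph-like groups declining, diatom-like
  groups rising) with Poisson sampling noise.

A master seed expands into fixed per-component substreams, so any
component can be regenerated independently and every written file records
the seed in its header.

What the generator does **not** emulate: braided-channel reorganization
and discharge-concentration hysteresis, autocorrelated measurement error,
snow redistribution by wind, bioirrigation or non-steady sediment
transport, and zero-inflated taxon counts. Passing recovery tests
therefore demonstrate that the estimators are correct and well-calibrated
under the stated generating assumptions — not that field data of this
kind will satisfy those assumptions.

## Numerical choices and test design

* The centering cubic is solved with `polyroot()` (unique real root,
  guaranteed by monotonicity), falling back to the ln-mean if the root
  solve fails.
* Zone-merge F tests guard against zero-SSE (noiseless) fits with a
  scale-relative tolerance rather than dividing by zero.
* The recovery experiments in the test suite use deliberately moderate
  problem sizes — 100 rating-curve scenarios with 200-400 bootstrap
  replicates, 200 sediment inversions, 40 end-to-end budget closures —
  chosen so the full suite exercises every stochastic guarantee while
  remaining quick to run routinely. The noisy sediment recovery
  conditions on the true zone partition (boundary selection is exercised
  separately by the noiseless reduction tests), and the conservative
  budget closure uses a constant-concentration tracer so the
  flow-weighted outflow concentration equals the input concentration by
  construction and the true storage change is exactly zero.

## Known limitations

* Load SEs assume independent, homoscedastic log-scale residuals; serial
  correlation in daily concentrations would widen true uncertainty.
* The budget's linear SE addition is a reporting convention, not a
  probability model; classification at $k = 1$ is correspondingly
  conservative about neither Type I nor Type II error in a formal sense.
* The carbonate module ignores ionic strength and non-carbonate
  alkalinity.
* PROFILE-style zone fitting optimizes boundaries only over the merge
  lattice of the initial equal partition, not continuously.
* TDP and particulate species budgets are intentionally not computed
  (detection and model-quality limits, respectively).
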