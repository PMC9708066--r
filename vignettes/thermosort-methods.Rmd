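---
title: "Methods: thermal traits, phylogenetic signal and species sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal traits, phylogenetic signal and species sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosort)
```

This vignette documents the models behind `thermosort`, the choices
made where the methodology was genuinely open, and what the synthetic
calibration does and does not establish.

## Trait derivation from raw assays

A growth–respiration assay observes a bacterial culture over a few
hours of exponential growth at one temperature: cell counts and cell
diameters (flow cytometry) at start and end, cumulative respired carbon
over the interval, and a luminescence (RLU) time series proportional to
ATP.

**Cell shape.** Only diameters are measured, so cells are treated as
spheres, `V = pi d^3 / 6` (µm³). This understates the volume of rods
and filaments; `derive_traits()` accepts volumes directly when better
morphology is available.

**Carbon per cell.** The allometric calibration
`fgC = 133.754 * V^0.438` converts volume to carbon mass. Its exponent
is below 1, so per-cell carbon is concave in volume — a property the
test suite asserts. Biomass is count × per-cell carbon; all biomass is
in fgC, and the cumulative respired carbon `Rtot` must be supplied in
the same unit.

**Growth.** Exponential growth gives `mu = log(Ctot/C0) / t` (natural
log, per hour). Negative `mu` (a shrinking culture) is legal and
propagates unchanged.

**Respiration.** Because biomass changes during the assay, dividing
`Rtot` by a fixed biomass would bias the rate; instead
`R = mu * Rtot / (C0 e^{mu t} - C0)`, the biomass-weighted rate of an
exponentially growing culture. The denominator vanishes with `mu`, so
for `|mu t| < 1e-8` the analytic limit `Rtot/(C0 t)` is substituted;
the threshold keeps `expm1`-type cancellation below the 1e-6 relative
continuity tolerance the tests check.

**ATP.** The luminescence reaction develops over ~6 minutes, so the
peak RLU across timepoints is used, then converted with
`log10(nM ATP) = 1.21 log10(RLU) - 4.69`. The calibration is taken to
be base-10 (the convention for calibration curves), while the growth
equation uses natural log (the exponential-growth convention). The unit
of ATP/biomass is nM per fgC; since downstream analyses work on its
natural log, the unit choice only shifts an additive constant.

## The thermal performance curve

Rates follow the four-parameter Sharpe–Schoolfield model with explicit
peak temperature (temperatures in Kelvin internally; all I/O is in °C):

$$B(T) = \frac{B_0\, e^{-\frac{E}{k}\left(\frac{1}{T}-\frac{1}{T_{ref}}\right)}}
{1 + \frac{E}{E_D - E}\, e^{\frac{E_D}{k}\left(\frac{1}{T_{pk}}-\frac{1}{T}\right)}},
\qquad k = 8.617\times 10^{-5}\ \mathrm{eV\,K^{-1}}.$$

`E` (eV) sets the Boltzmann–Arrhenius rise, `E_D > E` the decline
beyond the peak; in this parameterization the maximum is exactly at
`T_pk` (differentiating log B shows the two terms cancel there), which
is why `peak_rate()` is a closed form and `T_opt = T_pk - 273.15`.

Choices a user can change:

* **`Tref` = 273.15 K.** A reference temperature must be fixed but only
  rescales `B0`; it never moves `T_pk`, `E` or `E_D` (asserted in the
  tests).
* **Residual scale: linear rates.** Least squares on the rate scale is
  the default; `log_scale = TRUE` fits multiplicative residuals
  instead.
* **Bounds and starts.** `log(B0)` is optimized with `E ∈ [0.01, 10]`
  eV, `E_D - E ∈ [0.01, 30]` eV (the gap parameterization makes
  `E_D > E` a box constraint), and `T_pk` within the observed range
  padded by −5/+10 K. Multi-start over `E ∈ {0.2, 0.65, 1.2}` eV with
  `E_D = 4E` and `T_pk` at the argmax rate; lowest RSS wins, ties to
  the smaller `E`. Rates are normalized by their maximum before
  optimization, which conditions the problem and makes the fit exactly
  invariant to uniform rescaling.
* **Fallback.** A 4-parameter curve needs at least 5 distinct
  temperatures; below that the thermal optimum is the temperature of
  the highest directly measured rate, flagged `method = "fallback"`.
  Data still rising at the warmest assay temperature are fitted but
  flagged, since `E_D` is then barely identified.
* **Niche width.** The half-maximum crossing below the peak is found by
  bracketed root finding between a floor (default −10 °C, a numerical
  bound, not a biological claim) and `T_pk`; if the curve is above
  half-maximum at the floor the width is reported as undefined rather
  than extrapolated.
* **Non-positive rates** are dropped before fitting (the model is
  strictly positive), with a message.

## Phylogenetic signal and ancestral states

The thermal optimum is right-skewed across isolates, so signal is
estimated on `log(T_opt)` (optima in °C, all well above 0 °C; the
`transform` flag switches this off).

**Pagel's λ** multiplies the off-diagonal of the Brownian covariance
`C` (shared root-to-MRCA path lengths). For each λ the mean and rate
σ² are profiled analytically by GLS, leaving a 1-D likelihood
maximized on [0, 1] (tolerance 1e-8); values above 1 are not searched.
Because `optimize()` never evaluates endpoints, λ = 0 and λ = 1 are
checked explicitly and the estimate snaps to 0 when the boundary is not
beaten; the likelihood-ratio test against λ = 0 then has statistic 0
and p = 1 exactly. The p-value uses a plain χ²₁ without a boundary
correction — conservative for a parameter tested at its boundary, and
documented as such.

**Blomberg's K** is the observed MSE₀/MSE ratio (tip variance about the
phylogenetic mean over the covariance-weighted MSE) divided by its
Brownian expectation `(tr C − n/1'C⁻¹1)/(n−1)`, so K = 1 under Brownian
motion. Significance comes from tip-label permutations (default 999,
one-sided upper tail, `(1 + #{K* ≥ K})/(n+1)`), with the seed recorded
in the result.

**Ancestral states** under Brownian motion are exact ML: the joint
likelihood factorizes over edges, so the internal states solve a
weighted tree-Laplacian system (weights 1/branch length) with tips
fixed — equivalent to the GLS construction that treats each node as an
extra zero-length tip, which is how the test oracle computes them.
Prediction variances use the GLS formula with the uncertainty of the
estimated root mean propagated. Polytomies are supported throughout
(the covariance formulation needs no binary tree); reconstruction
requires strictly positive branch lengths.

Both λ and K are invariant to affine trait transforms and to uniform
branch-length rescaling (σ² rescales inversely) — all asserted as
property tests against independent implementations (`phytools`).

## Community statistics

* **Sorting regression** (`quadratic_vs_linear`): OLS fits of T_opt on
  sorting temperature with and without a quadratic term, compared by
  the nested F-test `F = (RSS₁−RSS₂)/(RSS₂/(n−3))` on (1, n−3) df.
  Only sorting-mode isolates enter this comparison; standard-mode
  isolates are described by the simple linear model.
* **Trait PCA** (`pca_traits`): variables standardized to mean 0, SD 1;
  eigenvector signs fixed by making each component's largest-magnitude
  loading positive (signs are otherwise arbitrary and determinism is
  needed for testing). Row filters support including or excluding
  particular phyla.
* **Power-law scaling** (`powerlaw_fit`): OLS of log₁₀(ATP) on
  log₁₀(respiration); the slope is the scaling exponent (1 = linear,
  <1 = sublinear). Replicate-level measurements are pooled per phylum
  rather than averaged per isolate.
* **Rank-sum contrasts** (`rank_sum_test`, `phylum_summary`): exact
  enumeration when the pooled sample is ≤ 12 without ties, else the
  normal approximation with tie and continuity corrections. The exact
  and approximate branches agree closely but not always within 0.01 in
  p, so the corresponding property test allows 0.02. Two-sided by
  default; no multiple-testing correction is applied, but the number
  of tests run is recorded. Rates can be Arrhenius-corrected to a
  common temperature (default 20 °C, E = 0.61 eV) before contrasting.

## The synthetic-data layer

The generators define the calibration conditions; they are first-class,
tested code, not fixtures.

* **Assay records** invert the derivation chain algebraically, so with
  noise off the round trip is exact to machine precision (the tests
  require ≤ 1e-9 relative). Optional Poisson count noise is off by
  default precisely so that exactness is testable.
* **Rate observations** multiply the true curve by lognormal noise with
  mean 1 and a chosen CV (rates are positive and skewed; no noise model
  is dictated by the assay itself, so the simplest positive one is
  used). The calibration design is 7 temperatures spanning 4–50 °C ×
  4 replicates at 5% CV — the assay ladder of the motivating
  experiment; the 5% CV is a plausible placeholder, as per-replicate
  measurement error is not known.
* **Trees** are pure-birth (Yule), rescaled to unit depth; recovery
  studies need only some ultrametric topology, not a particular one.
* **λ-BM traits** are multivariate-normal draws with covariance
  σ²·C(λ) via Cholesky.
* **The community scenario** places sorting-isolate optima on the 1:1
  line plus a cold-end bias that decays quadratically (zero slope) to
  zero at ≥ 21 °C — reproducing the curvature of incomplete sorting at
  cold temperatures without asserting a mechanism — with default
  magnitude 8 °C at the coldest temperature. Standard-mode isolates
  draw optima around 25 °C independent of incubation temperature.
  Defaults of 5 isolates per temperature per mode give 60 isolates
  over the 4–50 °C ladder. Isolates with optima ≥ 30 °C are labelled
  Firmicutes (hot-adapted isolates in such experiments are
  Firmicutes), others Proteobacteria, and the phyla receive
  contrasting r/K trait blocks (Firmicutes: faster growth, higher ATP,
  lower yield). Strong phylogenetic signal is built by labelling
  Yule-tree tips in traversal order with isolates sorted by optimum.

What the scenario does **not** emulate: real assay noise structure
(temperature-dependent error, plate effects), non-Brownian trait
evolution, unbalanced phylum membership, missing data, or any
correlation between the tree and the trait blocks beyond the optimum.
Passing calibration therefore shows the estimators are correct and
well-calibrated under their own assumptions — not that real data meet
those assumptions.

## Problem sizes and determinism

The calibration suite uses 100 simulated curves for parameter recovery
(median |T̂_pk − T_pk| and relative error on E), 50 random parameter
sets against a 0.001 °C grid for the niche width, 100 Brownian
simulations on 200-tip trees for λ and K (with 100 tip-shuffled
counterparts), and 50 random 10-tip trees against the full-GLS
ancestral-state oracle. Every stochastic function takes a seed and is a
pure function of it; `run_pipeline()` records seeds, parameters, output
checksums and stage timings in its manifest.

## Known limitations

* λ is restricted to [0, 1]; traits more similar than Brownian
  expectation (λ > 1) are reported as 1.
* The ancestral-state solver is dense (O(n³) worst case) — fine for
  hundreds of tips, not for tens of thousands.
* The χ²₁ LRT for λ is conservative at the boundary.
* The Sharpe–Schoolfield fit assumes homoscedastic errors on the
  chosen scale and does not weight replicates by their variance.
* No alternative TPC forms are offered, and no phylogenetic regression
  — the community statistics are deliberately the ordinary OLS / PCA /
  rank-sum toolkit.
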