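# thermosort

Trait analysis for temperature-driven **species sorting** in soil
bacteria. When a soil community is incubated along a temperature ladder
(4–50 °C), taxa whose thermal niches do not include the new temperature
are lost, and the isolates recovered afterwards tend to have thermal
optima matching the incubation temperature. Testing that idea requires a
chain of quantitative steps, all of which this package implements:

1. **Trait derivation** from raw growth–respiration–ATP assays: cell
   volumes (spheres from flow-cytometry diameters), per-cell carbon via
   the allometric relation *fgC cell⁻¹ = 133.754 · V^0.438*, culture
   biomass, the mass-specific exponential growth rate
   *μ = log(Ctot/C0)/t*, the biomass-corrected respiration rate
   *R = μ·Rtot / (C0·e^{μt} − C0)*, and ATP from peak luminescence via
   *log₁₀(nM ATP) = 1.21·log₁₀(RLU) − 4.69*.
2. **Thermal performance curves**: nonlinear least-squares fits of the
   four-parameter Sharpe–Schoolfield model with explicit peak
   temperature,

   *B(T) = B₀ · e^{−E/k·(1/T − 1/Tref)} / (1 + E/(E_D − E) ·
   e^{E_D/k·(1/T_pk − 1/T)})*,

   giving the thermal optimum T_opt (= T_pk), peak rate (μmax or Rmax)
   and the operational niche width (T_opt minus the temperature below it
   where the rate halves). Isolates measured at too few temperatures
   fall back to the temperature of the highest observed rate.
   Boltzmann–Arrhenius corrections standardize rates across assay
   temperatures.
3. **Phylogenetic signal and ancestral states** of T_opt on a
   time-calibrated phylogeny: maximum-likelihood Pagel's λ with a
   likelihood-ratio test, Blomberg's K with a permutation test, and
   Brownian-motion ancestral state reconstruction (exact GLS, verified
   against an independent implementation).
4. **Community statistics**: quadratic-versus-linear regression of
   T_opt on sorting temperature (nested F-test), PCA of standardized
   life-history traits, ATP–respiration power-law scaling exponents per
   phylum, and Wilcoxon rank-sum phylum contrasts.

A synthetic-data layer generates every input with known ground truth —
assay records that invert the derivation chain exactly, rate
observations from known curves, Yule trees, λ-scaled Brownian traits,
and a full community-sorting scenario — so every estimator is
calibrated against the truth that generated its data.

## Worked example

```r
library(thermosort)

## fit a thermal performance curve to noisy simulated rates
truth <- ss_params(B0 = 0.25, E = 0.65, ED = 3, Tpk = celsius_to_kelvin(32))
obs <- generate_tpc_observations(truth, noise_cv = 0.05, replicates = 4, seed = 11)
fit <- fit_ss(obs$temp, obs$rate)
fit
#> Sharpe-Schoolfield thermal performance curve fit
#>   method: fitted (28 obs at 7 temperatures)
#>   Topt = 32.32 degC, peak rate = 3.564
#>   E = 0.6446 eV, ED = 3.171 eV, B0 = 0.2469
#>   operational niche width = 11.03 degC
#>   RSS = 0.07261, R^2 = 0.997
```

The true optimum (32 °C) is recovered to 0.3 °C from 5%-noise data; the
activation energy E (thermal sensitivity of the rise) and deactivation
energy E_D (steepness of the decline) bracket their true values.
`coef()`, `predict()`, `residuals()`, `plot()` and `summary()` work as
for any fitted model object.

```r
## a full synthetic sorting experiment: 60 isolates, 6 temperatures
scen <- generate_community_scenario(seed = 1)
topt <- setNames(scen$traits$topt, scen$traits$isolate_id)

estimate_lambda(scen$tree, topt, transform = "log")
#> Pagel's lambda = 1 (n = 60 tips)
#>   logL = 52.76 (logL at lambda=0: -27.12)
#>   LRT vs lambda=0: chisq = 159.8, p = 1.276e-36
#>   trait transform: log

srt <- subset(scen$traits, isolation_mode == "sorting")
quadratic_vs_linear(srt$incubation_temp, srt$topt)
#> Quadratic vs straight-line regression (nested F-test)
#>   n = 30; RSS linear = 116.3, RSS quadratic = 48.92
#>   F(1, 27) = 37.2, p = 1.631e-06
#>   R^2: linear 0.980, quadratic 0.991
```

λ = 1 says the log thermal optimum is exactly as similar among
relatives as Brownian evolution on the tree predicts (the scenario
builds it that way); the significant quadratic term reflects the
cold-end mismatch — isolates sorted at 4–10 °C carry optima well above
their sorting temperature, while warm-sorted isolates sit on the 1:1
line. `run_pipeline()` chains all stages (simulate → derive traits →
fit curves → phylogenetic signal → community statistics) from one seed
and writes CSV/newick/JSON artifacts plus a manifest.

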