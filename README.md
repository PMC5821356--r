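# demicabc

Spatially explicit simulation of demic range expansions and Approximate
Bayesian Computation (ABC) inference of the demography behind them, for
population geneticists asking how much spatial genetic structure —
diversity clines *and* apparent population clusters — a plain
isolation-by-distance expansion can generate on its own.

## What it does

The world is a lattice of square demes (default 160 km edge) with a
land/water mask. A forward-in-time simulation grows the population from
`N_i` founders in an origin deme under stochastic logistic regulation
(Poisson sizes around `n + r n (1 − n/N)`) with stepping-stone migration
(each individual emigrates with probability `m`, split over the four land
neighbours; realized counts recorded). A backward-in-time, exact
Wright–Fisher coalescent — conditioned on those recorded counts, so the
genetics is consistent with the demography by construction — simulates
microsatellite loci under the single stepwise mutation model (rate `mu`
per locus per generation).

Genotypes are reduced to six *pattern statistics* from two cline
regressions: number of alleles A against distance from the origin, and
pairwise Weir–Cockerham F<sub>ST</sub> against pairwise distance (mean,
slope and log₁₀ squared-residual sum of each). Six parameters
(`T, N_i, N, r, m, mu`) are inferred by ABC: Euclidean rejection on
standardized statistics, then local-linear regression adjustment with
Epanechnikov weights; marginal posteriors are weighted kernel densities
whose mode is the point estimate and whose 95% highest-posterior-density
set is the interval. The estimator is validated on pseudo-observed
simulations (R², slope, SRMSE, HPD coverage per parameter). A comparison
stage reproduces the classic analyses on simulated data:
population-frequency PCA with per-axis R², an EM fit of the admixture
(STRUCTURE) likelihood with CLUMPP-style replicate alignment, and
Evanno's ΔK.

## Worked example

```r
library(demicabc)

# a 30 x 10 corridor world, 15 sampled demes of 10 diploids
fx <- make_fixture_landscape("corridor")

# simulate one "true" history and its genotypes
p <- parameter_set(T_gen = 2000, N_i = 1000, N = 1000, r = 0.5,
                   m = 0.2, mu = 5e-4)
obs <- make_pseudo_observation(fx$landscape, fx$scheme, p,
                               n_loci = 8, seed = 1)
round(obs$pattern, 5)
#>     mean_A    slope_A   logSSR_A   mean_Fst  slope_Fst logSSR_Fst
#>    5.22500   -0.00011    0.35921    0.00220    0.00000   -1.62872

# a (small, demonstration-sized) reference table and posterior
prior <- prior_config(T_mean_years = 50000, T_sd_years = 12000)
tab <- build_reference_table(fx$landscape, fx$scheme, prior,
                             n_sims = 300, n_loci = 8, seed = 2)
tab
#> ABC reference table: 300 simulations, 242 colonized (80.7%), 8 loci
post <- estimate_posterior(tab, obs$pattern, k = 60)
coef(post)["mu"]     # posterior mode for the mutation rate
#>           mu
#> 0.0002773581
confint(post)["mu", ]  # 95% HPD interval
#>        lower        upper
#> 7.974560e-05 6.997065e-04
plot(post)           # marginal posterior densities
```

The negative `slope_A` (diversity decays away from the origin) and
positive `slope_Fst` (differentiation grows with pairwise distance) are
the two clines the model is built to expose. With a 300-row table the
posterior is demonstration-grade: the mode for `mu` (2.8e-4) lands on
the order of the truth (5e-4) and the 95% HPD comfortably contains it;
the shipped study design uses 1,500 simulations.

Full runs — reference table, posterior, validation, re-simulation sets
drawn from Prior / 95%HPD / Mode, PCA comparison and ΔK clustering — are
orchestrated by `run_full_pipeline(run_config(...))`, or from a shell via
the thin wrapper `inst/cli/demicabc` (`run-all`, `fixtures`,
`simulate-demography`, ... subcommands).

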