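---
title: "Methods: demic range expansion, pattern statistics and ABC inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demic range expansion, pattern statistics and ABC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`demicabc` studies how much of the spatial structure of neutral genetic
diversity — both *clines* (diversity falling with distance from an
expansion origin, differentiation rising with pairwise distance) and
*clusters* (discrete groups found by ordination or admixture analysis) —
can be produced by a single, deliberately simple process: a demic range
expansion with isolation by distance over a bounded landscape.

## World

The world is a lattice of square demes with a land/water mask
(`build_landscape()`). Demes default to 160 km edges. Individuals move
only between the four orthogonal neighbours (a two-dimensional
stepping-stone), so water is an absolute barrier, and geographic distance
is defined as the shortest all-land 4-neighbour path length times the deme
edge. On an abstract lattice the step metric is exact, symmetric and
satisfies the triangle inequality; no map projection or Earth-curvature
correction is attempted (rasters supplied by the user carry whatever
geometry they encode).

## Forward demography

The expansion starts `T_gen` generations before present with `N_i`
diploids in the origin deme. Each generation applies, in this order:

1. **Growth/regulation.** A deme of size $n$ has expected next size
   $n + r\,n(1 - n/N)$; the realized size is Poisson with that mean
   ("stochastic logistic"). A `deterministic` switch uses the rounded mean
   instead. The expectation is clamped to $[0, 10N]$ as an overflow guard.
2. **Migration.** Each individual emigrates with total probability `m`;
   emigrants split equally among the deme's land neighbours, with
   multinomial realization. By default coastal demes renormalize `m` over
   their existing land neighbours (nobody drowns); `sea_absorb = TRUE`
   switches to the alternative where water-bound emigrants are lost.

Growth-then-migration is a modelling choice the backward pass inverts
exactly; the reverse order would be an equally valid but different model.
The realized per-neighbour migrant counts of every generation are recorded
— they are what makes the genetic (backward) stage exactly consistent with
the demography rather than an approximation to it.

## Backward genetics

Conditioned on a recorded history, `simulate_genotypes()` runs an exact
generation-by-generation Wright–Fisher coalescent for each locus
independently: sampled gene copies trace back through (i) migration
inversion — the probability a lineage in deme $j$ came from neighbour $i$
is proportional to the recorded migrant count $i \to j$ that generation —
and (ii) parent choice uniform among the $2n$ gene copies of the deme's
pre-migration size, so lineages picking the same parent merge (multiple
mergers are allowed, which matters in the tiny demes of the wave front).
Before the onset, the origin deme is panmictic at constant size `N_i`.

Microsatellite mutation follows the single stepwise model: each branch
receives a Poisson(`mu` × branch length) number of ±1 repeat changes,
reflected at one repeat. The ancestral length (default 20) is an arbitrary
anchor; every statistic used downstream is invariant to a global
translation of allele lengths. Diploids are assembled by pairing the two
gene copies sampled per individual (random union of gametes).

We chose the exact discrete-generation coalescent over a continuous-time
approximation deliberately: wave-front demes hold a handful of
individuals, where the continuous approximation is at its worst, and the
discrete process costs little at the scales the package targets.

## Summary statistics and the 2,485 → 6 reduction

Per sampled population: mean number of distinct alleles per locus (A),
unbiased gene diversity $\hat H_S = \frac{n}{n-1}(1 - \sum_a p_a^2)$,
allelic richness rarefied to the smallest typed gene-copy count, and
Garza–Williamson $M$ (allele count over allele-length range + 1). Per
population pair: the Weir–Cockerham (1984) variance-components
$\hat\theta$ combined across loci as the ratio of summed components —
negative estimates are *kept*, because clamping would distort Euclidean
distances near zero differentiation — and the Cavalli-Sforza–Edwards
chord distance, here $\frac{2}{\pi}\sqrt{2(1 - \sum_a\sqrt{p_{1a}p_{2a}})}$
per locus averaged over loci.

The ABC stage uses six "pattern" statistics from two OLS regressions: A
against distance from the origin, and pairwise $F_{ST}$ against pairwise
distance. Each contributes its response mean, its slope and
$\log_{10}(\mathrm{SSR} + 10^{-12})$. Raw residuals sum to zero by
construction, so the scatter statistic must be the *squared*-residual sum;
the $10^{-12}$ guard keeps exact fits finite. With 70 sampled demes this
reduces 70 + 2,415 = 2,485 numbers to 6. A per deme is the *mean* over
loci of distinct-allele counts, making it comparable across locus panels;
the regressions are unweighted.

## Priors and ABC estimator

Default priors (`prior_config()`): `N_i`, `N` ~ U(2, 5120); `m` ~
U(0, 0.5); `mu` ~ U(1e-5, 1e-3) per locus per generation (a log-uniform
switch exists); onset time ~ Normal(155,000, 32,000) years truncated
above 25 years, at 25 years per generation; `r` ~ Lognormal with
meanlog = ln 0.5 and sdlog = 0.6. The lognormal is parameterized so the
*median* is 0.5 — "mean 0.5, SD 0.6" is ambiguous between natural- and
log-scale moments, and the log-scale reading keeps the distribution
centred where logistic growth rates for humans are usually placed; both
parameters are user-overridable.

`estimate_posterior()` implements rejection plus local-linear adjustment:
statistics are standardized by the reference table's mean/SD (this makes
rejection invariant to affine rescaling of any raw statistic), the `k`
nearest simulations in Euclidean distance are retained, and each
parameter is corrected by a weighted linear regression on the
standardized statistics with Epanechnikov weights vanishing at the k-th
distance ($\theta^* = \theta - b(s - s_{obs})$). Marginals are weighted
Gaussian kernel densities on a 512-point grid over the prior support with
boundary reflection and a Silverman bandwidth (floored at one grid cell so
near-degenerate retained sets cannot drop all mass between grid points).
The point estimate is the density mode; intervals are 95% highest-density
superlevel sets, reported by their range. We use SD (not MAD)
standardization and weight all six statistics equally. The full
Gaussian-GLM variant of the correction was considered and not implemented;
the local-linear form has the same intent (project retained draws onto the
observation) and is easier to verify.

For unbounded priors (onset time, growth rate) the "prior range" used for
density grids and SRMSE standardization is the central 99.9% quantile
range; uniform priors use their exact bounds.

`validate_estimator()` draws colonized reference rows as
pseudo-observations, leave-one-out (a row is excluded from its own
reference set — otherwise every pseudo-observation would trivially match
itself at distance zero), and reports per parameter the $R^2$ and slope of
mode-on-truth, SRMSE (RMSE of the mode over the prior range) and 95% HPD
coverage.

## Clustering comparison

`population_pca()` ordinates populations on centred per-population allele
frequencies; simulated and observed solutions are compared per axis by
squared Pearson correlation of matched population coordinates, which is
invariant to the sign and scale indeterminacy of principal axes.

`admixture_fit()` maximizes the same admixture likelihood STRUCTURE
samples from — allele copy of individual $i$ at locus $l$ from cluster
$z$ with probability $Q_{iz}$, then allele $a$ with probability $P_{zla}$
— by EM from seeded random starts (default 5 restarts, best likelihood
kept). Divergence from STRUCTURE is deliberate and documented: no
Dirichlet prior on $Q$, no correlated-frequencies model, no Gibbs
sampling. The quantities compared downstream (ancestry patterns, Evanno's
$\Delta K$) depend on the likelihood surface, not on the sampler.
Replicates are aligned across label switchings by maximizing the summed
per-individual dot product against the first run (the CLUMPP G-statistic
analogue), exhaustively over permutations for $K \le 6$, greedily beyond.
$\Delta K(K) = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}\,L(K)$
is reported alongside the max-likelihood $K$.

# Synthetic data and what the tests can show

The package ships no empirical data. `make_fixture_landscape()` provides
four toy worlds — a 30×10 corridor (15 sampled demes along its axis), two
12×12 continents joined by a one-deme isthmus (8 sampled demes each), a
four-island archipelago, and a single deme (the panmictic special case).
`make_island_genotypes()` draws island-model genotypes with a target
differentiation *F* through the standard F-model (per-population Dirichlet
with concentration $(1-F)/F$ around flat-Dirichlet ancestral frequencies
over 8 allele states), giving the $F_{ST}$ machinery an external
calibration target.

These fixtures emulate the *geometry* of continental sampling (bounded
corridors, bottleneck isthmuses, unequal distances), not real data:
sample sizes are equal by default, allele-frequency spectra are clean,
there is no genotyping error, no missing-data structure, no environmental
heterogeneity in `N` or `m`, and no ascertainment of loci. Passing tests
therefore demonstrate internal correctness and that the claimed phenomena
(clines from diffusion, clusters from pure geometry) emerge at toy scale —
not that the estimator is calibrated for any particular empirical dataset.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run a reduced version of the
study design, sized so a complete run stays desk-scale: a corridor
reference table of 1,500 simulations at 8 loci and 15 sampled demes of 10
diploids, k = 100 retained, 30 pseudo-observations for validation; the
two-continents clustering uses 100 loci and K = 1..4 with 4 replicates.
On this reduced design the onset-time prior is rescaled to
Normal(50,000, 12,000) years: a 30-deme corridor is crossed and
genetically equilibrated far faster than a planet, and simulating the
full 155,000-year prior would only append stationary generations. All
other priors are the defaults above. These sizes are fixed design choices
of the reduced study, chosen once; the corresponding full-scale design
(~1.2M simulations, 20,384-deme world, 70 populations) is out of scope.

# Known limitations

- The regulation model is a Poisson-logistic stand-in: the reference
  simulator's exact regulation formula is not public, so ours is defined
  by this document rather than by equivalence to another program.
- The admixture estimator finds local optima of the likelihood; restarts
  mitigate but do not eliminate this, and its likelihoods are not
  comparable to STRUCTURE's marginal likelihood estimates.
- HPD sets are reported as intervals (the range of the superlevel set);
  for multimodal marginals the interval can over-cover.
- Backward migration inverts *realized* counts independently per lineage,
  the standard conditional-independence approximation.
- Distances are lattice-step distances; users wanting great-circle
  geometry must encode it in their raster resolution.
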