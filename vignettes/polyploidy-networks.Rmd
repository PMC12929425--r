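---
title: "Polyploid frequency and plant-pollinator network structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyploid frequency and plant-pollinator network structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plonet)
```

## The question

Whole-genome duplication is common in flowering plants, and polyploids can
differ from their diploid relatives in floral morphology, mating system and
niche breadth. If polyploids tend to occupy broader (or narrower)
pollination niches, communities richer in polyploids should show
systematically different interaction architecture: more (or less) nested,
less (or more) modular networks. `plonet` implements the community-level
analysis of this question end to end: structural indices of weighted
bipartite visitation networks, null-model standardization, extinction
robustness, network-level trait frequencies, cohort filters, univariate
regressions with a spatial-autocorrelation check, and a piecewise
structural equation model that separates the direct association of
polyploid frequency from its indirect pathways through mating system and
floral restrictiveness. A synthetic community generator with known ground
truth makes every stage testable without any external data.

## Data model

A community is a `ppnet`: a labeled non-negative matrix of visit counts
with plants as rows and pollinators as columns. Validation drops rows and
columns with no recorded interactions (published matrices often retain
never-observed taxa) and rejects negative cells and duplicate labels.
Plant traits are one row per species: ploidy (diploid/polyploid), mating
system (self-compatible/self-incompatible) and a four-level floral
restrictiveness score; `unknown` is always an explicit value. Per-network
covariates carry coordinates and four bioclimatic variables: temperature
seasonality (BIO4), mean temperature of the warmest quarter (BIO10, degrees C),
precipitation seasonality (BIO15) and precipitation of the warmest quarter
(BIO18, mm).

Trait frequencies are computed over classified species only: %PP is the
share of polyploids among ploidy-classified plants of the network, %SC the
share of self-compatible plants among mating-classified ones, and
%Restrictive the share of restrictive-flowered plants (moderate/high
restriction, after collapsing the four-level score to a binary trait)
among restrictiveness-classified ones. A frequency whose denominator is
zero is undefined, never zero.

The retained cohort requires at least six pollinator taxa, at least six
ploidy-classified plants, ploidy classification for at least one third of
the plants (an exact rational comparison, so a network at exactly one
third passes an "at least 33%" rule), and complete climate data. The path
analysis additionally drops networks where both %SC and %Restrictive are
undefined; the per-predictor availability rule for the univariate models
is one classified species (`n_known >= 1`), configurable upward.

## Structural indices

*Connectance* is the binary fill, computed on the binarized matrix: any
positive visit count is a link.

*Nestedness* is weighted NODF on the weighted matrix. For a pair of rows,
the member with strictly larger binary fill is the richer; the pair
contributes 100 times the fraction of the poorer row's positive cells that
are strictly smaller than the richer row's corresponding cells, and pairs
with tied fills contribute zero (the decreasing-fill condition is strict).
The same applies over column pairs; the index is the mean over all row and
column pairs. This is exactly the fill-conditioned weighted NODF computed
by the standard community-ecology implementations, and the test suite
checks cell-for-cell agreement with `vegan::nestednodf(order = TRUE,
weighted = TRUE)` as an independent oracle.

*Modularity* is Barber's bipartite Q,

$$Q = \frac{1}{m}\sum_{ij}\Big(w_{ij} - \frac{r_i c_j}{m}\Big)\,\delta(g_i, h_j),$$

maximized by a seeded weighted label-propagation search with agglomerative
module merging: rows start in singleton modules (later restarts start from
random partitions), vertices greedily adopt the opposite-side label with
the best Q gain (ties broken toward the smallest label index), and module
pairs are merged while any merge increases Q. Ten restarts by default,
best Q kept; the single-module partition (Q = 0 exactly, an algebraic
identity) is always admissible, so the optimizer never reports a negative
Q. For networks with at most 12 vertices an exhaustive search over set
partitions is available; it enumerates partitions of the smaller side and
assigns each vertex of the larger side to its best module, which attains
the global optimum. Whether modularity should be computed on weighted or
binarized matrices is not settled usage; the weighted matrix is the
default here because the label-propagation module detector is inherently
weighted, and binarizing first remains possible by passing a binarized
network.

*Robustness* is the area under the extinction curve for random plant
removal. Plants are removed one at a time; a pollinator survives while it
retains at least one positive interaction. The curve starts at (0, 1),
has one point per removal step, and ends at (1, 0) because validated
networks have no empty columns; the area is the trapezoid rule over those
n + 1 points. The n-by-n one-to-one network gives exactly 0.5 under any
order, a useful closed form for testing. Ploidy-targeted policies remove
all plants of one cytotype first (in random order within the block);
plants of unknown ploidy are grouped with the non-targeted block, since a
targeted extinction can only target what is classified. The default of
100 random orders per network is a precision choice, configurable.

## Null models and delta standardization

Raw indices confound structure with size and marginal totals, so every
index is reported as `delta = raw - null_mean`: the mean is taken over
fixed-marginal null matrices drawn by Patefield's algorithm
(`stats::r2dtable`), which preserves the network's dimensions and row and
column visit totals exactly in every draw — the classic "preserve network
size" null in community ecology. Non-integer weights are rounded half-up
before marginal computation, since weights are visit counts. The null
replicate count defaults to 100 and is recorded in the output. Because the
literature's size-preserving nulls differ, a second variant is provided
behind a flag: marginal-preserving checkerboard swaps of the observed
matrix, which additionally preserve connectance. No z-scores are used;
only the null mean is subtracted.

## Regression stage

Each delta index is regressed on each predictor separately by ordinary
least squares, using every network for which that predictor is defined —
so sample sizes differ across predictors, which maximizes power per
predictor instead of discarding networks. Reported per fit: n, Pearson r,
the regression t statistic (identically $t = r\sqrt{n-2}/\sqrt{1-r^2}$;
summary tables in this literature label this standardized value "beta",
and the output carries it under both names), its two-sided p, slope and
intercept. Precipitation variables and network size are natural-log
transformed to relieve skew; the precipitation logs use log(x + 1)
because summer precipitation can be zero, and network size is plants +
pollinators (configurable). Residual spatial structure is assessed with
Moran's I under row-standardized inverse great-circle-distance weights
(expectation $-1/(n-1)$, two-sided normal-approximation p); fitting
spatial autoregressions is deliberately out of scope, the test is the
in-scope portion of that workflow.

## The piecewise path model

For one focal index Y the model is five linear equations on standardized
variables:

```
pct_pp           ~ log_bio15
pct_sc           ~ pct_pp + log_bio15
pct_restrictive  ~ pct_pp + log_bio15
log_network_size ~ log_bio15
delta_Y          ~ pct_pp + pct_sc + pct_restrictive + log_bio15 + log_network_size
```

Each equation is fitted by OLS on its own complete cases: trait coverage
is very uneven across networks, and a global complete-case fit would
collapse the cohort (it remains available via `complete_cases = TRUE` as
a robustness check). Standardized coefficients are `b * sd(x)/sd(y)` on
the equation's cases.

Model adequacy uses the d-separation basis set: one claim per non-adjacent
variable pair (pairs of exogenous variables are exempt), conditioned on
the union of the pair's parents, tested as the p-value of the added term
in the corresponding regression with the later variable in topological
order as response. The base model has exactly four claims — (%SC,
%Restrictive), and network size against each plant variable — none of
which involves Y, so Fisher's
$C = -2\sum_k \ln p_k \sim \chi^2_{2k}$ is identical across the four
index models fitted to the same records, matching the single shared
adequacy p-value such analyses report. Claim p-values are treated as
independent in the chi-square reference, the standard piecewise-SEM
approximation; the suite verifies by simulation that the resulting test
is close to nominal at the cohort's sample size.

The effect of %PP on Y is decomposed by path enumeration: the direct
effect is the single-edge standardized coefficient, each mediated path
contributes the product of its standardized coefficients, and the total
is the sum — an exact identity in the decomposition, tested against an
independent dynamic-programming oracle on random DAGs. Variants swap
BIO15 for BIO10, include both, or drop either mediator.

`simulate_sem_records()` draws unit-variance Gaussian data following the
DAG exactly (error variances solved from the implied covariance), which
gives the calibration and recovery experiments a ground truth on the same
scale as the standardized coefficients.

## The synthetic community generator

`generate_study()` produces complete studies — networks, a masked trait
table, covariates and ground truth. Pollinators sit at uniform positions
on a one-dimensional niche axis; each plant has a uniform niche center
and Gaussian kernel of breadth sigma0 (diploids) or sigma0 * kappa
(polyploids); visit counts are Poisson with peak intensity lambda. kappa
is the scenario dial: above 1, polyploids are broader-niched generalists
(expected to raise nestedness and depress modularity as their frequency
grows); below 1, narrower-niched specialists with the opposite
expectations; at 1 ploidy carries no niche signal at all.

Defaults and rationale:

- Network sizes are log-normal within 6-100 plants and 6-200 pollinators,
  centered to give about 15.7 plants and 44.3 pollinators on average —
  the typical scale of assembled plant-pollinator cohorts.
- sigma0 = 0.1 and lambda = 8 give fills and visit counts in the realistic
  range (connectance roughly 0.1-0.3); with these, moderately broadened
  niches (kappa around 1.3) produce %PP-structure correlations of roughly
  |r| = 0.15 at cohort scale, the magnitude the analysis is designed to
  detect, while kappa = 2 gives unambiguous signs for scenario tests.
- The network-level polyploid fraction follows a logit model on
  standardized log BIO15 (intercept at 35%, the rough share of recently
  polyploid flowering plants; positive slope 0.5).
- Per-plant self-compatibility and restrictiveness follow ploidy-dependent
  logits with negative defaults (-0.9 and -1.6), reproducing the observed
  negative %PP-%SC and %PP-%Restrictive covariation.
- Missingness defaults (30% ploidy, 80% mating, 30% restrictiveness)
  mirror the very uneven trait coverage of real compilations, where
  mating-system data are the scarcest.
- Climate enters only through the polyploid-frequency and trait models,
  never through the structural parameters. This is deliberate: it makes
  kappa the only path from ploidy to structure, so the kappa = 1 scenario
  is an exact null for the %PP-structure association and type-I
  calibration is meaningful. Climate-structure covariation, present in
  real data, is therefore not emulated by default; users can induce it by
  varying generator settings across networks.
- One study seed drives a per-network seed sequence, so any single
  network is reproducible in isolation; networks failing the retention
  filters are redrawn with a capped retry count, so generated studies
  pass the filters by construction.

What passing tests on these synthetic studies do show: the pipeline
recovers known generative signals with correct sign and approximate
magnitude, keeps false-positive rates nominal under the null, and every
arithmetic identity holds. What they do not show: correctness of
ecological conclusions on real data, which involve phenology, spatial
structure within communities, sampling effort and taxonomic resolution —
none of which the generator emulates.

## Numerical choices

- WNODF's decreasing-fill condition is strict; tied fills contribute 0.
- Label-propagation ties break toward the smallest label index under the
  run seed; optimizer restarts default to 10 (first from singletons,
  later from random partitions); every stochastic routine takes a seed
  and is exactly reproducible.
- Weights are rounded half-up to integers for null marginals.
- The one-third coverage threshold is compared with a 1e-9 tolerance so
  exact rational boundaries pass.
- Coincident coordinates in Moran's I get the weight of the smallest
  positive distance; identical-location-only inputs are an error.
- Degenerate inputs error early and by name: zero-variance responses,
  partitions missing vertices, removal orders that are not permutations,
  targeted extinctions with no classified plants.

## Problem sizes used by the test and acceptance experiments

The suite runs the oracle-equivalence check on 200 random networks of up
to 12 vertices; Fisher's C calibration on 1,000 simulated studies of 313
records; coefficient recovery at n = 5,000; the broad-niche scenario on
100 studies of 300 networks (8 null replicates, 2 optimizer restarts);
and the null-niche calibration on 400 studies of 100 networks (5 null
replicates). These sizes are the package's chosen compromise between the
Monte-Carlo precision the assertions need and a suite that runs in
minutes; all are package-level choices and can be scaled up by editing
the corresponding arguments.

## Known limitations

- The niche model is one-dimensional and static; it cannot represent
  phenological turnover or forbidden links beyond niche distance.
- Patefield nulls sample tables from the fixed-marginal hypergeometric
  distribution; schemes that equally weight distinct tables, or preserve
  connectance, differ — the swap variant covers the latter.
- The exhaustive modularity oracle is limited to 12 vertices by design.
- Fisher's C treats basis-set p-values as independent; with heavily
  overlapping claims this is approximate (calibration is verified by
  simulation at the cohort scale used here).
- Univariate models apply no multiple-testing correction, matching the
  analysis they implement.
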