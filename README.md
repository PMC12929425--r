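# plonet

**Polyploid frequency and the structure of plant–pollinator networks.**

Roughly a third of flowering plant species are recent polyploids, and
genome duplication changes traits that matter to pollinators — flower
size and shape, mating system, niche breadth. `plonet` asks the
community-level question: do plant–pollinator networks with more
polyploid species look structurally different? It implements the full
analysis pipeline for weighted bipartite visitation networks:

- **Structural indices** — connectance (binary fill), weighted NODF
  nestedness, and Barber's bipartite modularity
  `Q = (1/m) Σ_ij (w_ij − r_i c_j / m) δ(g_i, h_j)` maximized by a seeded
  weighted label-propagation optimizer with agglomerative merging (plus
  an exhaustive-partition oracle for networks of ≤ 12 vertices).
- **Robustness** — area under the secondary-extinction curve as plants
  are sequentially removed, including ploidy-targeted removal orders
  (diploids-first / polyploids-first).
- **Null-model standardization** — every index is reported as
  `delta = raw − null mean` over fixed-marginal (Patefield) null
  matrices that preserve network dimensions and marginal visit totals
  exactly.
- **Trait frequencies and cohort filters** — %PP, %SC and %Restrictive
  computed over classified species only; retention filters (≥ 6
  pollinators, ≥ 6 ploidy-classified plants, ≥ 1/3 ploidy coverage,
  climate available) with per-network rejection reasons.
- **Regressions** — univariate OLS of each delta index on each predictor
  with per-predictor sample sizes, `t = r√(n−2)/√(1−r²)`, and a Moran's I
  residual spatial-autocorrelation test under inverse great-circle
  weights.
- **Piecewise path model** — five OLS equations linking precipitation
  seasonality, %PP, the two mediator traits, network size and one focal
  index; d-separation basis set, Fisher's C adequacy test
  (`C = −2 Σ ln p_k ~ χ²_2k`), standardized coefficients, and exact
  direct/indirect/total effect decomposition by path enumeration.
- **Synthetic communities** — a Gaussian niche-overlap generator with a
  polyploid niche-breadth ratio κ (broadened κ > 1, narrowed κ < 1,
  null κ = 1), ploidy-dependent trait logits, realistic missingness, and
  recorded ground truth for calibration and recovery experiments.

Everything is tibble-in/tibble-out and pipe-friendly; fitted path models
have `tidy()`/`glance()` methods and result types have
`autoplot()`/`plot_*()` helpers.

## Worked example

Generate a synthetic study under the broadened-polyploid-niche scenario
and run the whole pipeline:

```r
library(plonet)

study <- generate_study(synth_config(n_networks = 40, kappa = 2, seed = 42))
out <- run_study(study$networks, study$traits, study$covariates,
                 n_null = 25, n_orders = 25, restarts = 5, seed = 42,
                 sem_indices = c("nestedness", "modularity"))

dplyr::filter(out$univariate, predictor == "pct_pp")
#>   predictor response              n      r t_stat         p   slope
#> 1 pct_pp    delta_connectance    40  0.480   3.37 0.00172    0.136
#> 2 pct_pp    delta_nestedness     40  0.535   3.91 0.000373  12.2
#> 3 pct_pp    delta_modularity     40 -0.500  -3.56 0.00102   -0.173
#> 4 pct_pp    delta_robustness     40  0.605   4.68 0.0000358  0.0906
```

With broader polyploid niches (κ = 2), networks richer in polyploids are
more nested and less modular — the generator's planted signal, recovered
with the expected signs. The path model separates how much of the
nestedness association is direct versus mediated by the two floral
traits:

```r
out$sem_summary
#>   fisher_c df adequacy_p  n n_claims index      variant
#> 1     10.7  8      0.217 40        4 nestedness base
#> 2     10.7  8      0.217 40        4 modularity base

dplyr::filter(out$effects, index == "nestedness")
#>   effect                         value
#> 1 direct                        0.416
#> 2 indirect via pct_sc           0.0141
#> 3 indirect via pct_restrictive -0.0156
#> 4 total                         0.415
```

Fisher's C is shared across the index models (no basis-set claim involves
the focal index), the adequacy test does not reject the generating
structure, and the total effect is exactly the direct effect plus the two
mediated products. `plot_associations(out$records)` draws the
frequency-versus-structure panels and `plot_effects(out$effects)` the
decomposition.

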