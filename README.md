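# fuzzyarchetypes

Soft classification of multimodal cell-phenotype tables — continuous
electrophysiological/anatomical measurements plus boolean molecular
markers — under the explicit assumption that cell types form a *structured
continuum* rather than crisply separated classes. The package is aimed at
quantitative neuroscientists and cytometrists who have a cells × features
table and want not only the types it contains but also a principled account
of the cells *between* the types.

## The method

Cells are z-scored and partitioned by fuzzy c-means: memberships
`1/m_ia = Σ_l (d_ia/d_il)^(2/(μ−1))` and centroids
`u_a = Σ_i m_ia^μ f_i / Σ_i m_ia^μ` alternate until convergence, minimizing
`J = Σ_i Σ_l m_il^μ d_il²`. The fit is deliberately over-provisioned
(`c_max = 20` clusters by default); converged centroids closer than
`ε = 0.001` coalesce, so the effective number of archetypes `c*` is an
output, and sweeping the fuzziness `μ` charts the order in which archetypes
emerge. Each cell gets a typicality coefficient `d = m(1st) − m(2nd)`;
thresholds derived from the sample (`d̄ ± Δ`, with `Δ` the halved mean
absolute deviation) split cells into archetypal / intermediate / atypical,
and cells with `d ≤ Δ` are flagged as *edge cells* straddling two
archetypes. Archetypes are profiled by membership-weighted means and SDs
(reducing to the ordinary mean and unbiased SD under equal weights),
compared pairwise by Mann–Whitney and Fisher exact tests, and features are
ranked by the cost increase `ΔJ%` after randomly permuting their column —
a measure of how much each feature's *correlation structure* supports the
classification. A synthetic phenotype-continuum generator with known mixing
weights makes the whole pipeline testable end to end.

## Worked example

```r
library(fuzzyarchetypes)

ds   <- generate_synthetic(synthetic_spec(rng_seed = 1))   # 4 archetypes + edge cells
part <- fcm_fit(ds$fm, fcm_config(mu = 1.349, rng_seed = 1, c_max = 20))
part
#> fuzzy_partition: 190 cells, c* = 4 (mu = 1.349, J = 2449.66, 62 iterations)
#>   coalescence: 4 merge group(s)

spec <- typicality_spectrum(part)
spec
#> typicality_spectrum: 190 cells, d_bar = 0.762, Delta = 0.086
#>   archetypal 98 (52%), atypical 35 (18%), intermediate 57; edge cells 7

head(spec$cells[spec$cells$edge_flag, ], 3)
#>       cell_id main_type secondary_type          d    label edge_flag
#> 164 cell_0164         1              4 0.02889682 atypical      TRUE
#> 165 cell_0165         1              4 0.03896642 atypical      TRUE
#> 172 cell_0172         1              3 0.06666858 atypical      TRUE

recovery_metrics(ds, part)$ari
#> [1] 0.942
```

Reading this: the 20 provisional clusters coalesced to `c* = 4`, matching
the 4 planted archetypes; about half the cells are strictly archetypal; the
7 edge-flagged cells have near-tied memberships between two archetypes
(`d ≈ 0.03–0.07`), i.e. they sit on the boundary the generator planted them
on; and the argmax classification agrees with the ground truth at adjusted
Rand index 0.94 (the shortfall from 1.0 is the 50/50 edge cells, whose true
label is intrinsically ambiguous).

Further entry points: `mu_sweep()` / `robust_ranges()` / `emergence_mu()`
for the fuzziness sweep, `weighted_profile()` / `compare_all_archetypes()` /
`feature_color_code()` for archetype characterization, `rank_features()` /
`reduced_classification()` for relevance analysis, and `pair_projection()`
for plot-ready membership coordinates. A command-line wrapper is installed
as `exec/fuzzyarchetypes` with subcommands `simulate`, `fit`, `sweep`,
`typicality`, `profile`, `relevance` and `reduce`; every output directory
contains a manifest with the seeds needed to reproduce it bit for bit.

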