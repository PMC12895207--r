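# divdim

Taxonomic, phylogenetic and functional diversity — and how those three
components relate to each other — for plot-based vegetation surveys under
contrasting land use (grazing pressure gradients and grassland
abandonment).

Ecologists studying grazed and abandoned grasslands need more than species
counts: habitat filtering and limiting similarity leave their signatures in
the *phylogenetic* and *functional* structure of communities, and the three
diversity components need not move together. `divdim` implements the full
chain for such analyses:

* **Per-plot metrics.** Gini–Simpson taxonomic diversity
  `D = 1 − Σ pᵢ²`; Rao's quadratic entropy `Q = Σᵢⱼ pᵢ pⱼ dᵢⱼ` with
  phylogenetic divergences (raoD, time since MRCA) or Gower trait
  distances (raoQ); community-weighted means `CWMₜ = Σᵢ pᵢ xᵢₜ` of six
  log-scale traits (SLA, LDMC, LNC, LA, SM, PH).
* **Phylogeny handling.** Species missing from the reference tree are
  grafted at random points within their genus (or family) clade;
  phylogenetic quantities are averaged over a set of alternative grafted
  topologies. Blomberg's K with a tip-permutation test quantifies the
  phylogenetic signal of each trait.
* **Null models.** Standardized effect sizes
  `SES = (obs − null mean)/null SD` for raoD (tip shuffles), raoQ and CWMs
  (trait-row permutations), with per-category one-sample *t* tests:
  negative SES = convergence/filtering, positive = divergence/limiting
  similarity.
* **Group comparisons.** Kruskal–Wallis plus Holm-adjusted pairwise
  Wilcoxon tests with compact letter displays across the five land-use
  categories (intensive/intermediate/extensive grazing, recent/past
  abandonment).
* **Dimensionality of biodiversity.** Per category, a PCA on the
  correlation matrix of (D, raoD, raoQ) yields the evenness of eigenvalues
  (EE: complementarity vs redundancy of the diversity components) and the
  importance value (IV) of each metric, plus the Camargo evenness of the
  IVs with a bootstrap CI.
* **Synthetic studies.** A generator (Yule trees, Brownian-motion traits
  with tunable signal, neutral / filtering / limiting-similarity assembly)
  produces full four-file studies for testing, calibration and power
  analysis.

See `vignettes/diversity-dimensionality-methods.Rmd` for the models,
assumptions and design choices.

## Worked example

```r
library(divdim)

# a synthetic 120-plot study: 292-species pool, 6 traits, 5 land-use
# categories assembled under different filtering strengths
study <- simulate_study(default_study_config(seed = 42))

cfg <- run_config(study$comm, study$traits, study$tree, study$design,
                  n_topologies = 1, n_rand = 199, n_boot = 199, seed = 42)
res <- run_pipeline(cfg)

head(res$profile[, 1:6], 3)
#>      plot  category     D raoD raoD_sd  raoQ
#> 1 plot001 intensive 0.885 69.9       0 0.129
#> 2 plot002 intensive 0.948 71.3       0 0.174
#> 3 plot003 intensive 0.925 78.6       0 0.161

subset(res$ses_summary, metric == "raoQ")
#>            category metric  n mean_ses      t  p_value
#>           extensive   raoQ 24   -0.623 -3.484 2.01e-03
#>           intensive   raoQ 24   -1.590 -7.826 6.24e-08
#>        intermediate   raoQ 24   -1.295 -9.183 3.72e-09
#>    past_abandonment   raoQ 24   -0.985 -5.242 2.57e-05
#>  recent_abandonment   raoQ 24    0.183  0.831 4.15e-01
```

Each plot's row gives its Simpson diversity (`D`, unitless), phylogenetic
Rao entropy (`raoD`, on the tree's time scale; `raoD_sd` is the spread
across grafted topologies, 0 here because the simulated tree is complete)
and functional Rao entropy (`raoQ`, Gower units in [0, 1]). The SES
summary recovers the generating process: functional convergence (negative
mean SES, small p) deepens with the filtering strength used for each
category — strongest under intensive grazing — while the neutrally
assembled recent-abandonment plots are indistinguishable from random
(mean SES 0.18, p = 0.42).

```r
res$dimensionality[, c("category", "EE", "IV_D", "IV_raoD", "IV_raoQ")]
#>            category   EE IV_D IV_raoD IV_raoQ
#>           intensive 0.68 0.35    0.34    0.31
#>        intermediate 0.66 0.37    0.29    0.35
#>           extensive 0.70 0.35    0.35    0.29
#>  recent_abandonment 0.89 0.34    0.34    0.32
#>    past_abandonment 0.48 0.37    0.33    0.30
```

EE near 1 means the three diversity components are complementary (several
dimensions needed); near 1/3, redundant. IVs (summing to 1 per row) give
each metric's share of the biodiversity-space variation.

A thin command-line wrapper covers the same flow:

```sh
inst/scripts/divdim simulate --seed 7 --out study/
inst/scripts/divdim run --community study/community.csv --traits study/traits.csv \
    --tree study/tree.nwk --design study/design.csv --out results/ --seed 7
```

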