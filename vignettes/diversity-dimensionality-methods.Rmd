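---
title: "Methods: diversity metrics, null models, and the dimensionality of biodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity metrics, null models, and the dimensionality of biodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divdim)
```

## The analysis in one paragraph

`divdim` analyses plot-based vegetation surveys collected under contrasting
land use — three grazing intensities plus recent (< 10 y) and past (> 10 y)
abandonment. For every plot it computes three diversity components:
taxonomic diversity as the Gini–Simpson index, phylogenetic diversity as
Rao's quadratic entropy on divergence times (raoD), and functional
diversity as Rao's entropy on Gower trait distances (raoQ), together with
the community-weighted mean (CWM) of six functional traits. Permutation
null models convert raoD, raoQ and the CWMs into standardized effect sizes
(SES) that indicate convergence (negative) or divergence (positive) of
lineages and traits, the classical signatures of habitat filtering and
limiting similarity. Metrics and CWMs are compared across land-use
categories with Kruskal–Wallis and pairwise Wilcoxon tests, and the
relationship *among* the diversity components is summarized per category by
the dimensionality analysis: eigenvalue evenness (EE) and importance values
(IV) from a PCA of the metric correlation matrix.

## Inputs and conventions

Four files describe a study: a plots x species abundance matrix (cover or
counts; CSV), a species x traits table (CSV), a rooted phylogeny with
branch lengths (Newick), and a plot-to-category design table (CSV).

* **Traits.** The default trait set is SLA (mm²/mg), LDMC (mg/g), LNC
  (mg/g), LA (mm²), SM (mg) and PH (cm). All trait values are stored on
  the natural-log scale; `read_traits(..., log_transform = TRUE)` performs
  the transform and rejects non-positive raw values. Natural log was
  chosen because back-transforming typical grassland CWMs (e.g. an LDMC
  CWM of 5.7 gives roughly 300 mg/g, a PH CWM of 3.2 roughly 25 cm) yields
  biologically plausible values under these conventional units.
* **Gap filling.** Missing trait cells are imputed by the genus mean,
  falling back to the family mean (when a taxonomy is supplied) and then
  the global mean. This deliberately simple tiered scheme replaces
  hierarchical matrix-factorization gap-filling; every filled cell's tier
  is recorded so the imputation can be audited.
* **Phylogeny.** Divergence between two species defaults to half the
  patristic distance — the time since their most recent common ancestor on
  an ultrametric tree — so raoD is on the timescale of the tree (about
  70–100 for Myr-scale angiosperm phylogenies). The full patristic
  convention is available (`convention = "patristic"`) because published
  Rao values do not always state which was used.
* **Species missing from the tree** are grafted into the smallest clade
  spanning their congeners: an edge of that clade (including its stem) is
  chosen with probability proportional to its length and the new tip is
  attached at a uniform position along it, extended to the depth of the
  deepest tip so ultrametric trees stay ultrametric. Uniform-along-branch
  is the least informative placement consistent with "somewhere in its
  genus". Repeating the draw (default 1000 topologies) yields a set of
  alternative trees; all phylogenetic quantities are averaged across the
  set and their across-topology SD is reported. Species with neither
  congeners nor (when a taxonomy is given) a family clade are dropped with
  a warning: there is no defensible placement for them.

## The metrics

For relative abundances \(p_i\) within a plot:

* Gini–Simpson \(D = 1 - \sum_i p_i^2\). The inverse-Simpson form is
  available via `simpson_variant`; the Gini–Simpson form is the default
  because its [0, 1) range matches values typically reported for grassland
  plots (0.7–0.85).
* Rao's quadratic entropy \(Q = \sum_{i,j} p_i p_j d_{ij}\), the expected
  dissimilarity of two random individuals. With the 0/1 distance it
  collapses exactly to the Gini–Simpson index — a useful internal
  consistency check that the test suite exercises.
* Functional distances default to Gower dissimilarity on the log traits
  (mean over traits of |difference|/range), bounding raoQ by 1.
  `euclidean_z` and `euclidean_log` scalings are provided because Rao
  values above 1 in the literature imply unscaled trait distances; on any
  particular data set the option can be calibrated against published
  magnitudes.
* CWM per trait, \( \mathrm{CWM}_t = \sum_i p_i x_{it} \), always within
  the range of the contributing species' values.

Within-species trait distance is taken as zero (no intraspecific
variability), the standard comparative-ecology assumption; this is a known
limitation for traits with strong local plasticity.

## Null models and standardized effect sizes

SES = (observed − null mean)/null SD, with 999 randomizations by default.

* **raoD:** species labels are shuffled across the tips of the phylogeny.
* **raoQ:** trait rows are permuted across species.
* **CWM:** trait rows are permuted jointly (all columns together), which
  preserves the trait covariance structure in every draw. Permuting each
  trait independently would test a subtly different null; the joint
  permutation was chosen because CWMs of correlated traits should share
  their null variation.

The shuffle pool is the species set actually present in the community
matrix, not the full megaphylogeny: the SES then asks "is this plot
assembled non-randomly *from the study pool*", which is the standard
plot-level reading. A label shuffle acts on a precomputed distance matrix
as a simultaneous row/column permutation, so nulls are generated by
relabeling rather than recomputing distances; the equivalence is exact and
is asserted in the tests.

Degenerate nulls (SD = 0, e.g. a two-species pool where no shuffle can
change anything, or a plot containing the whole pool at equal abundance)
are reported as SES = 0 when the observed value equals the null mean and
as missing otherwise, with the reason recorded — they must not poison
category summaries as infinities. The SD comparison uses a relative
floating-point floor, since a null that only moves by round-off is
degenerate in substance.

Per category, one-sample *t* tests ask whether mean SES differs from zero;
Kruskal–Wallis plus pairwise Wilcoxon tests (Holm-adjusted by default,
configurable to BH or none; the letters derive from the adjusted p-values)
compare raw metrics and CWMs across categories. Exact rank-sum nulls are
used for tie-free groups of at most 10, the normal approximation with
continuity correction otherwise.

## Dimensionality: EE and importance values

Per land-use category, the plots x (D, raoD, raoQ) matrix is reduced by a
PCA on its Pearson correlation matrix. With eigenvalues \(\lambda_k\)
(summing to the number of metrics) and metric–component correlations
\(r_{mk}\) (loadings scaled so \(\sum_m r_{mk}^2 = \lambda_k\)):

* **EE** is the Camargo evenness of the eigenvalues,
  \(1 - \sum_{i<j} |q_i - q_j| / S\) on proportions \(q\). EE = 1 means
  the metrics are mutually uncorrelated (every dimension matters); EE =
  1/3 means one dimension carries everything.
* **IV** of metric *m* is \(\sum_k (\lambda_k/\sum\lambda) \, r_{mk}^2\),
  normalized to sum to 1: the communality-weighted share of
  biodiversity-space variation carried by that metric. Squared
  correlations are the default because they make the decomposition exact
  and sign-free; an |r| variant is provided since verbal descriptions of
  the construction are ambiguous, and the variant can be calibrated
  against published tables. Eigenvector signs are fixed (largest loading
  positive), which cannot affect the r² variant and is asserted anyway.
* **IV evenness** is the Camargo evenness of the IVs; its 95% CI comes
  from a percentile bootstrap over plots within the category (resamples
  with a zero-variance metric column are redrawn and counted). Percentile
  rather than BCa: at 24 plots per category the added complexity of BCa is
  not warranted, and the point estimate sits inside the percentile
  interval across simulated studies.

`metric_matrix` requires at least 4 plots and nonzero variance per metric;
with fewer plots a 3x3 correlation matrix is too unstable to interpret.

## The synthetic-study generator

The generator exists so that every stage is testable without field data.
Its defaults emulate a 120-plot survey: a 292-species pool on a Yule tree
rescaled to depth 100 (Myr-like, giving raoD magnitudes of about 70–80),
42 genera, six traits, and 24 plots per category with 30 species each and
lognormal(0, 1) abundances (right-skewed, cover-like). Genera are true
clades, obtained by repeatedly splitting the largest clade until the
requested number remains, so congeners are monophyletic and grafting tests
are meaningful.

Traits mix a Brownian-motion realization on the tree with white noise:
`signal * BM + (1 - signal) * noise`, both components standardized to unit
variance across tips and the noise orthogonalized against the BM component
so the mixture variance is exactly `signal^2 + (1 - signal)^2` and the
signal parameter is not blurred by sampling covariance. `signal = 1`
recovers Blomberg's K near 1 (BM), `signal = 0` gives K near 0. The
default `signal = 0.1` reproduces the weak phylogenetic signal (K of order
0.001–0.1) typical of continuous functional traits in grassland floras.

Assembly regimes:

* **neutral** — uniform sampling without replacement;
* **filtering** — weights \( \exp(-s (t_i - \mathrm{opt})^2) \) on one
  z-scored trait axis, the per-plot optimum drawn uniformly over the
  observed range. One axis (configurable) keeps recovery experiments
  interpretable;
* **limiting similarity** — greedy max–min functional spacing, each step
  greedy with probability \(1 - e^{-s}\), else uniform.

Strength 0 reduces every regime to neutral exactly. The default study
assigns filtering of decreasing strength to intensive (8), past-abandoned
(4), intermediate (2) and extensive (1) categories and leaves recent
abandonment neutral — a caricature of disturbance-driven convergence that
gives the downstream stages distinguishable categories to recover.

What the simulator does **not** emulate: spatial structure and dispersal
limitation, species-abundance correlations with traits, intraspecific
variability, succession through time, non-Brownian trait evolution, and
realistic phylogenetic imbalance. Passing recovery tests therefore show
that the chain detects the processes it models, not that field inference
is automatic.

## Numerical and design notes

* One global seed deterministically derives every stage seed by a string
  hash of (seed, stage label), so any stage can be reproduced in
  isolation; all derived seeds stay below 2^31.
* Randomization counts (1000 topologies, 999 permutations, 999 bootstrap
  resamples) are the analysis defaults; tests and the acceptance script
  run at reduced counts (tens to 199) where the Monte-Carlo error is
  already far below the effects being detected.
* Blomberg's K uses the GLS form with the Brownian expectation
  \((\mathrm{tr}(C) - n/\sum C^{-1})/(n-1)\); its permutation p-value is
  the proportion of tip shuffles with MSE at most the observed (observed
  included in numerator and denominator). A singular phylogenetic
  covariance or a constant trait is an error, not a silent NA.
* Zero-range traits are excluded from Gower distances with a warning; if
  every trait is constant the distance matrix is all-zero and downstream
  SES is reported degenerate rather than erroring.
* All-zero species columns are retained (to keep alignment with trait and
  tree inputs) but excluded from per-plot metrics and from shuffle pools.

## Reduced problem sizes used in the test suite

Unit tests use pools of 20–60 species and 5–25 plots; the stochastic
calibration tests use the full 292-species pool with 24 plots and 199
randomizations per null, 50 replicate studies for the neutrality
calibration, and 200 replicates of 50-tip trees for the K recovery check.
These sizes were chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside the asserted bounds.
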