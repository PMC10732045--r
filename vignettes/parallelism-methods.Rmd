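---
title: "Measuring gut microbiota (non)parallelism with multivariate vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gut microbiota (non)parallelism with multivariate vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paravec)
```

## The method

`paravec` asks whether independent host lineages that underwent similar
ecological shifts — for instance, two unrelated species pairs that each
split into a plant-eater and a fish-eater — show similar shifts in
their gut microbial communities. The measurement chain is:

1. **Dissimilarity.** Bray-Curtis dissimilarity between all community
   samples, `d(a,b) = 1 − 2Σmin(x_af, x_bf) / (Σx_af + Σx_bf)`, bounded
   in [0, 1].
2. **Ordination.** Principal coordinates analysis: Gower
   double-centering of −½d², eigendecomposition, coordinates =
   eigenvectors × √eigenvalue. Axes explaining more than 0.1 % of the
   variation are retained (strict inequality).
3. **Centroids and vectors.** Each species is summarised by the
   unweighted mean of its samples' retained coordinates; the community
   shift between two species is the vector between their centroids.
4. **Direction and magnitude.** The angle between two species-pair
   vectors measures shared direction (below 90° parallel, above 90°
   nonparallel, 180° anti-parallel); the Euclidean norm of a vector
   measures the magnitude of divergence.
5. **Comparison design.** Vector pairs are classified by diet:
   *parallel host trophic divergence* when both species pairs span the
   same two diet categories, *nonparallel* when the combinations
   differ; pairs whose two members share a diet are excluded from the
   angle contrast. Quartets (A₁, B₁, A₂, B₂) — two pairs spanning diets
   a ≠ b in which each within-pair duo is more closely related than any
   cross-pair duo — yield three comparison types (ecology A₁B₁-A₂B₂,
   phylogeny A₁A₂-B₁B₂, cross A₁B₂-A₂B₁) that separate diet-driven from
   ancestry-driven parallelism.
6. **Statistics.** Welch t and Wilcoxon rank-sum for two-group angle
   and length contrasts (with Shapiro-Wilk normality gates reported
   rather than silently applied), Kruskal-Wallis plus Holm-adjusted
   pairwise Wilcoxon tests with a compact letter display for the
   quartet types, and linear plus penalized-spline (GAM) trends of
   angles and lengths against host divergence time.

The reference distribution for angles is the random-vector null: the
angle between two independent standard-normal vectors in *d*
dimensions. Its mean is 90° in every dimension and it tightens and
approaches normality as *d* grows, which is why observed mean angles
are read against 90° rather than 0°.

## What the synthetic generator emulates

Real inputs (an ASV or pathway table, host metadata, a dated tree) are
not required to exercise any stage, because `simulate_dataset()`
produces data with known structure:

- an ultrametric pure-birth host tree rescaled to a chosen age
  (`simulate_tree()`), standing in for a dated supertree;
- per-feature latent log-abundances composed of a shared baseline,
  a Brownian deviation along the tree (rate `sigma_phylo` per √myr —
  variance grows as `sigma_phylo² · t`), and an additive `diet_effect`
  on a diet-specific responsive feature subset;
- per-individual Gaussian noise (`sigma_individual`), softmax to
  proportions, and multinomial counts at fixed `depth`
  (Dirichlet-multinomial when `overdispersion` is finite).

This is the minimal generative model exhibiting the three forces the
analysis is meant to detect — diet, phylogeny, and individual noise.
Design choices worth noting: the model is log-linear so phylogenetic
signal acts multiplicatively on abundances and proportions stay
positive; diet-responsive feature sets are disjoint across the six diet
categories so diet effects are identifiable; and the single master seed
is expanded into named sub-streams (baseline, phylogeny, diet sets,
group sizes, individual noise, counts) so each stage is independently
reproducible.

What it does **not** emulate: sequencing error profiles, chimeras,
compositional zero-inflation beyond what multinomial sampling induces,
strain dynamics, within-species diet variation, or any covariance
between diet assignment and tree position (diets are assigned by the
caller). Passing tests on synthetic data therefore demonstrate that the
measurement chain recovers structure that is present, not that real
gut communities contain such structure.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_sequences` | 1000 | minimum reads per sample |
| `min/max_individuals_per_species` | 3 / 20 | species retention band; beyond 20 a seeded uniform subsample is taken |
| `specialist_threshold` | 0.70 | minimum diet fraction (inclusive) defining a diet specialist |
| `min_axis_prop` | 0.001 | strict retention threshold on per-axis proportion of variation |
| `diet_effect` | 1 | latent log-abundance shift on a diet's responsive features |
| `sigma_phylo` | 0.1 | Brownian rate of latent log-abundance per √myr |
| `sigma_individual` | 0.5 | sd of individual latent noise |
| `depth` | 5000 | counts per sample |
| `responsive_fraction` | 0.1 | fraction of features responsive per diet |

The simulation defaults were chosen once for testability: at
`diet_effect = 0` the parallel-category mean angle sits near the 90°
null, at `diet_effect = 1` it drops well below it, and at 3 the effect
dominates — giving a monotone ladder that the recovery tests assert.
They are not calibrated to any real 16S data set, and no calibration is
claimed.

## Numerical and design choices

- **Negative eigenvalues.** Bray-Curtis matrices are generally
  non-Euclidean; axes with non-positive eigenvalues are discarded and
  proportions of variation are computed over the positive-eigenvalue
  sum. No Cailliez/Lingoes correction is applied, matching the dominant
  behaviour of standard PCoA implementations in community ecology.
- **Eigenvector sign.** Each axis is canonicalised so its
  largest-magnitude loading is positive. Angles are invariant to any
  *consistent* per-axis sign choice; canonicalisation makes repeated
  runs bitwise identical.
- **Eigenvalue ties** keep the decomposition's stable order
  (descending eigenvalue, original index).
- **Angle computation** clamps the cosine to [−1, 1] before `acos` to
  absorb floating-point drift; zero-length vectors are excluded from
  angle analyses (NA) but retained in length analyses.
- **Vector orientation.** Angles are meaningless without a shared
  orientation rule. Each vector points from the lower- to the
  higher-ranked diet under the fixed alphabetical category order
  (fruits < invertebrates < meat-endotherms < meat-fish < plants <
  seeds); same-diet vectors are oriented by species-name order. Within
  quartets, the ecology vectors are both oriented a → b and the
  within-diet vectors pair-1 → pair-2, so all three comparison types
  are well defined.
- **Duplicate samples** of an individual keep the lexicographically
  first sample ID — deterministic and auditable. The health filter
  keeps "healthy" and missing values; the kept vocabulary is
  configurable because source metadata rarely standardises it.
- **Filter order** is fixed (missing ID → duplicates → health → age →
  read depth → species minimum → species maximum) with the
  species-level rules last so individual counts reflect usable
  samples; the per-species subsample is seeded and the seed is recorded
  in the filter report.
- **Mean divergence time of a comparison** is not uniquely defined for
  four species; the default is the mean over all unordered pairs of the
  distinct species involved (six pairs when four are distinct), with
  the mean of the two within-vector times emitted alongside
  (`mdt_within`) and selectable.
- **Shared-species comparisons** (two vectors with a common endpoint)
  are excluded by default since their angles are not independent;
  `allow_shared_species = TRUE` restores them.
- **Quartet enumeration** takes every qualifying quartet rather than a
  maximal disjoint set; overlapping quartets share species, and
  downstream tests may subsample if independence is required.
- **Test choices.** The t-test defaults to Welch (pooled variance by
  flag); Wilcoxon p-values are exact for combined n ≤ 50 without ties
  and use the continuity-corrected normal approximation otherwise;
  post hoc correction defaults to Holm; the spline smoother uses a
  thin-plate basis of dimension 10 with smoothness chosen by
  generalized cross-validation, and both deviance explained and
  adjusted R² are reported because "variance explained" is ambiguous
  for penalized fits. Normality is reported (Shapiro-Wilk, subsampled
  to 5,000 with a seed when larger) rather than used to silently switch
  tests.

## Problem sizes used in the tests

The recovery tests run 16 species × 10 individuals at depth 5,000 over
20 seeds and three diet-effect levels; module tests use 8 species × 4–5
individuals at depths 1,000–2,000 with 60–100 features. These sizes
give stable seed-averaged means (hundreds to thousands of comparisons
per run) while keeping a full suite run in well under a minute per
file.

## Known limitations

- Angles live in the retained PCoA space; two data sets ordinated
  separately have different (and differently scaled) axes, so angles
  are comparable within one ordination, not across them.
- With only two diet categories every cross-diet comparison is
  parallel-category; nonparallel comparisons require ≥ 3 diets.
- The quartet constraint can be satisfied by zero quartets on shallow
  or diet-clumped trees; the function warns and returns an empty set.
- Phylogenetic non-independence of comparisons is not corrected
  (no PGLS-style adjustment); divergence time enters only as a
  covariate in the trend fits.
- BIOM input is supported in its JSON form via `biomformat` when that
  package is installed; TSV is the primary interchange format.
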