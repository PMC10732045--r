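# paravec

Quantifying (non)parallelism of host-associated microbial communities
with multivariate vector analysis.

## The problem

When independent host lineages repeatedly adapt to similar ecological
niches — say, two unrelated bird pairs in which one species eats plants
and the other fish — do their gut microbial communities shift in similar
directions? Most comparative studies score such parallelism as a binary.
`paravec` instead measures it: community samples are ordinated, each
host species is reduced to its mean position (centroid) in the retained
principal-coordinate space, and the community shift between two host
species becomes a vector between their centroids. For two species-pair
vectors **v₁**, **v₂**:

- **direction**: θ = arccos(⟨v₁, v₂⟩ / (‖v₁‖‖v₂‖)), in degrees.
  θ < 90° indicates parallel community change, θ > 90° nonparallel
  change, 180° anti-parallelism;
- **magnitude**: ‖v‖, the extent of community divergence between the
  two hosts.

The pipeline is: Bray-Curtis dissimilarities → principal coordinates
analysis (axes explaining > 0.1 % of variation retained) → species
centroids → divergence vectors → angles and lengths. Vector-pair
comparisons are classified by host trophic ecology (*parallel host
trophic divergence* when both pairs span the same two diet categories,
*nonparallel* otherwise, same-diet pairs excluded), and
phylogenetically constrained quartets (A₁B₁–A₂B₂ / A₁A₂–B₁B₂ /
A₁B₂–A₂B₁) separate the contributions of host ecology and host
phylogeny. A statistics layer supplies the two-sample tests,
Kruskal-Wallis + pairwise Wilcoxon post hocs, Shapiro-Wilk gates and
linear/GAM trend fits against host divergence time, and a
random-vector null gives the reference angle distribution (centred at
90°, approximately normal in high dimension).

Because the angle null and every classification rule are testable
without any external data, the package ships a synthetic-data
generator: an ultrametric host tree, per-species latent log-abundances
with Brownian phylogenetic structure, additive diet effects on
diet-specific feature subsets, individual-level noise, and
(Dirichlet-)multinomial count sampling.

## Worked example

Simulate 15 host species (5 per diet category: plants, meat-fish,
invertebrates) on a 50-myr pure-birth tree, 10 individuals per species
at 5,000 reads, with a moderate diet effect, then run the full
analysis:

```r
library(paravec)

tree  <- simulate_tree(n_species = 15, depth_myr = 50, seed = 1)
diets <- setNames(rep(c("plants", "meat-fish", "invertebrates"), 5),
                  tree$tip.label)
sim   <- simulate_dataset(tree, diets,
           simulation_params(n_species = 15, individuals_per_species = 10,
                             depth = 5000, diet_effect = 1, seed = 2))

ord  <- retain_axes(pcoa(bray_curtis(sim$table)))
cen  <- species_centroids(ord, sim$metadata)
vecs <- all_pair_vectors(cen, diets)
cmp  <- enumerate_comparisons(vecs, tree)
aggregate(angle ~ category, cmp, function(x) round(mean(x), 2))
#>              category angle
#> 1  excluded_same_diet 90.44
#> 2 nonparallel_trophic 87.85
#> 3    parallel_trophic 75.07

rep <- run_analysis(cmp, vecs, tree, build_quartets(cen, diets, tree))
rep$table[1:4, c("section", "test", "groups", "n", "statistic", "p")]
#>   section               test                  groups    n statistic        p
#> 1  angles Welch two-sample t parallel vs nonparallel 2100     -19.7 8.08e-75
#> 2  angles  Wilcoxon rank-sum parallel vs nonparallel 2100  218683.0 7.93e-76
#> 3 quartet     Kruskal-Wallis ecology/phylogeny/cross  324     229.1 1.80e-50
#> 4 lengths  Wilcoxon rank-sum  same vs different diet  105     515.0 1.54e-05
```

Comparisons in the parallel-host-trophic-divergence category average
75.1° — well below the 90° null — while nonparallel comparisons sit
near 87.9°: parallel shifts in host diet produce measurably parallel
community shifts in this simulation. The angle null at the retained
dimensionality confirms the reference point:

```r
null <- random_angle_null(dim = ncol(ord$points), n_draws = 1e5, seed = 3)
sprintf("null mean %.2f, sd %.2f", null$mean, null$sd)
#> "null mean 90.00, sd 5.89"
```

Real data enter through `read_feature_table()` (features × samples TSV
or BIOM), `read_metadata()` (sample/individual/species/age/health/diet
fraction columns) and `read_tree()` (Newick, branch lengths in myr),
then `apply_sample_filters()` and `assign_diet_specialists()` apply the
filtering rules (≥ 1,000 sequences/sample, 3–20 individuals/species,
adult-equivalent age classes, healthy individuals, ≥ 70 % diet
specialists) before the same ordination-to-statistics chain.
`run_pipeline()` (or `inst/cli/paravec.R`) orchestrates everything and
writes per-stage TSV artifacts plus a checksum manifest.

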