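# Shared fixtures, built in code.

# Balanced two-diet simulation used by several tests.
small_sim <- function(seed = 11, diet_effect = 1, n_species = 8,
                      individuals = 5, n_features = 100,
                      sigma_phylo = 0.1, sigma_individual = 0.5,
                      depth = 2000) {
  tree <- simulate_tree(n_species, 50, seed = seed)
  diets <- stats::setNames(rep(c("plants", "meat-fish"),
                               length.out = n_species),
                           tree$tip.label)
  params <- simulation_params(n_species = n_species,
                              individuals_per_species = individuals,
                              n_features = n_features, depth = depth,
                              sigma_phylo = sigma_phylo,
                              diet_effect = diet_effect,
                              sigma_individual = sigma_individual,
                              seed = seed + 1)
  sim <- simulate_dataset(tree, diets, params)
  c(sim, list(tree = tree, diets = diets, params = params))
}

# Simulation -> centroids in retained PCoA space.
sim_centroids <- function(sim) {
  ord <- retain_axes(pcoa(bray_curtis(sim$table)))
  species_centroids(ord, sim$metadata)
}

# Mean parallel-category comparison angle of a two-diet simulation.
parallel_mean_angle <- function(sim) {
  cen <- sim_centroids(sim)
  vecs <- all_pair_vectors(cen, sim$diets)
  cmp <- enumerate_comparisons(vecs, sim$tree)
  mean(cmp$angle[cmp$category == "parallel_trophic"], na.rm = TRUE)
}

# Nested quartet tree: four (A_i, B_i) cherries, two per root clade.
# Within-clade cherries split at 50 myr, cross-clade at 80 myr.
quartet_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A1:5,B1:5):45,(A2:5,B2:5):45):30,",
    "((A3:5,B3:5):45,(A4:5,B4:5):45):30);"))
}

# Star of cherries: every cross-cherry divergence is 80 myr, so only
# within-cherry ecotype pairs can satisfy the quartet constraint.
star_quartet_tree <- function() {
  ape::read.tree(text = paste0(
    "((A1:5,B1:5):75,(A2:5,B2:5):75,",
    "(A3:5,B3:5):75,(A4:5,B4:5):75);"))
}

# Brute-force quartet enumeration straight from the constraint, using
# only cophenetic divergence times (oracle for build_quartets).
quartet_oracle <- function(species_a, species_b, tree) {
  D <- ape::cophenetic.phylo(tree) / 2
  out <- character()
  for (i in seq_along(species_a)) for (j in seq_along(species_a)) {
    if (j <= i) next
    A1 <- species_a[i]; A2 <- species_a[j]
    for (B1 in species_b) for (B2 in setdiff(species_b, B1)) {
      within <- max(D[A1, B1], D[A2, B2])
      across <- min(D[A1, A2], D[A1, B2], D[B1, A2], D[B1, B2])
      if (within < across)
        out <- c(out, paste(A1, B1, A2, B2))
    }
  }
  sort(out)
}
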