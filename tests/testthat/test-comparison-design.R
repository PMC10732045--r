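test_that("comparisons are classified by diet multisets, symmetrically", {
  expect_equal(classify_comparison(c("plants", "meat-fish"),
                                   c("meat-fish", "plants")),
               "parallel_trophic")
  expect_equal(classify_comparison(c("plants", "meat-fish"),
                                   c("plants", "invertebrates")),
               "nonparallel_trophic")
  expect_equal(classify_comparison(c("plants", "plants"),
                                   c("plants", "meat-fish")),
               "excluded_same_diet")
  expect_equal(classify_comparison(c("seeds", "fruits"),
                                   c("fruits", "fruits")),
               "excluded_same_diet")
  # symmetry in the two arguments
  combos <- list(c("plants", "seeds"), c("seeds", "fruits"),
                 c("plants", "plants"))
  for (p1 in combos) for (p2 in combos)
    expect_equal(classify_comparison(p1, p2), classify_comparison(p2, p1))
  expect_error(classify_comparison(c("plants", "candy"),
                                   c("plants", "seeds")),
               class = "paravec_validation_error")
})

test_that("enumeration covers every unordered vector pair exactly once", {
  tree <- quartet_tree()
  tips <- tree$tip.label[1:4]            # A1, B1, A2, B2
  set.seed(42)
  cen <- matrix(rnorm(8, sd = 1), ncol = 2, dimnames = list(tips, NULL))
  dm <- stats::setNames(c("plants", "meat-fish", "plants", "meat-fish"),
                        tips)
  vecs <- all_pair_vectors(cen, dm)
  expect_equal(nrow(vecs$info), 6)       # C(4,2)
  raw <- enumerate_comparisons(vecs, tree, allow_shared_species = TRUE)
  expect_equal(nrow(raw), choose(6, 2))  # 15 raw comparisons
  expect_false(any(raw$vector_1 == raw$vector_2))
  key <- paste(pmin(raw$vector_1, raw$vector_2),
               pmax(raw$vector_1, raw$vector_2))
  expect_false(anyDuplicated(key) > 0)
  # default drops shared-species comparisons
  indep <- enumerate_comparisons(vecs, tree)
  expect_true(all(!indep$shares_species))
  expect_equal(nrow(indep), sum(!raw$shares_species))
})

test_that("mean divergence time follows its two definitions", {
  tree <- ape::read.tree(
    text = "((A1:5,B1:5):45,(A2:8,B2:8):42);")  # depth 50
  tips <- c("A1", "B1", "A2", "B2")
  cen <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE,
                dimnames = list(tips, NULL))
  dm <- stats::setNames(c("plants", "meat-fish", "plants", "meat-fish"),
                        tips)
  vecs <- all_pair_vectors(cen, dm)
  cmp <- enumerate_comparisons(vecs, tree)
  eco <- cmp[cmp$vector_1 == "B1|A1" & cmp$vector_2 == "B2|A2", ]
  expect_equal(nrow(eco), 1)
  # four distinct species: within-pair times 5 and 8, four cross times 50
  expect_equal(eco$mdt_all_pairs, (5 + 8 + 4 * 50) / 6)
  expect_equal(eco$mdt_within, (5 + 8) / 2)
  expect_equal(eco$mean_divergence_time, eco$mdt_all_pairs)
  alt <- enumerate_comparisons(vecs, tree, time_definition = "within-vector")
  expect_equal(alt$mean_divergence_time, alt$mdt_within)
})

test_that("quartets require within-pair ecotypes to be closest relatives", {
  # star of cherries: only within-cherry ecotype pairs qualify, so the
  # accepted set is exactly the C(4,2) cherry pairs with mate pairing
  star <- star_quartet_tree()
  set.seed(43)
  cen8 <- matrix(rnorm(16), ncol = 2,
                 dimnames = list(star$tip.label, NULL))
  # A-tips feed on fruits (first diet alphabetically), B-tips on plants
  dmap <- stats::setNames(rep(c("fruits", "plants"), 4),
                          star$tip.label)
  q <- build_quartets(cen8, dmap, star)
  expect_equal(nrow(q), choose(4, 2))
  expect_true(all(q$diet_a == "fruits" & q$diet_b == "plants"))
  for (r in seq_len(nrow(q))) {
    expect_equal(sub("A", "B", q$A1[r]), q$B1[r])
    expect_equal(sub("A", "B", q$A2[r]), q$B2[r])
  }

  # nested tree: the accepted set matches the brute-force constraint
  # oracle (cross-cherry ecotype pairs within a clade also qualify)
  nest <- quartet_tree()
  cen_n <- matrix(rnorm(16), ncol = 2,
                  dimnames = list(nest$tip.label, NULL))
  qn <- build_quartets(cen_n, dmap, nest)
  expect_setequal(paste(qn$A1, qn$B1, qn$A2, qn$B2),
                  quartet_oracle(paste0("A", 1:4), paste0("B", 1:4),
                                 nest))

  # rejected: cherries pair same-diet species -> ecotypes are not
  # closest relatives
  anti <- ape::read.tree(text = "((A1:5,A2:5):45,(B1:5,B2:5):45);")
  cen4 <- matrix(rnorm(8), ncol = 2,
                 dimnames = list(anti$tip.label, NULL))
  dmap4 <- stats::setNames(c("fruits", "fruits", "plants", "plants"),
                           anti$tip.label)
  expect_warning(q0 <- build_quartets(cen4, dmap4, anti),
                 "no quartet")
  expect_equal(nrow(q0), 0)
})

test_that("quartet angles use the prescribed orientations", {
  tree <- ape::read.tree(text = "((A1:5,B1:5):45,(A2:5,B2:5):45);")
  tips <- tree$tip.label
  cen <- rbind(A1 = c(0, 0), B1 = c(1, 0), A2 = c(0, 2), B2 = c(1, 3))
  dmap <- stats::setNames(c("fruits", "plants", "fruits", "plants"),
                          tips)
  q <- build_quartets(cen, dmap, tree)
  expect_equal(nrow(q), 1)
  # ecology: A1->B1 = (1,0) vs A2->B2 = (1,1): 45 degrees
  expect_equal(q$angle_ecology, 45)
  # phylogeny: A1->A2 = (0,2) vs B1->B2 = (0,3): 0 degrees
  expect_equal(q$angle_phylogeny, 0)
  # cross: A1->B2 = (1,3) vs A2->B1 = (1,-2)
  expect_equal(q$angle_cross,
               angle_between(c(1, 3), c(1, -2)))
})

test_that("diet contrast grouping partitions all vectors", {
  sim <- small_sim(seed = 27, individuals = 4, n_features = 60,
                   depth = 1000)
  cen <- sim_centroids(sim)
  vecs <- all_pair_vectors(cen, sim$diets)
  groups <- diet_contrast_groups(vecs, sim$tree)
  expect_equal(nrow(groups), nrow(vecs$info))
  expect_setequal(groups$group, c("same_diet", "different_diet"))
  expect_equal(sum(groups$group == "same_diet"), 2 * choose(4, 2))
  expect_true(all(is.finite(groups$divergence_time)))
  expect_true(all(groups$divergence_time > 0))
})
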