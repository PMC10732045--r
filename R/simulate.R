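#' Simulation parameters for synthetic community data
#'
#' Bundles the knobs of the generative model used by
#' [simulate_dataset()]: a log-linear latent abundance model with
#' phylogenetically correlated species effects, additive diet effects on a
#' sparse feature subset, individual-level noise, and (Dirichlet-)
#' multinomial count sampling.
#'
#' @param n_species Number of host species (tips of the simulated tree).
#' @param individuals_per_species Either a single integer (same number of
#'   individuals for every species) or a length-2 range from which a
#'   per-species count is drawn uniformly.
#' @param n_features Number of community features (ASV-like taxa or
#'   pathways); at least 2.
#' @param depth Sequencing depth per sample (total counts drawn).
#' @param sigma_phylo Brownian-motion rate of per-feature latent
#'   log-abundance along the tree; variance accrues as
#'   \code{sigma_phylo^2 * t} over \code{t} million years.
#' @param diet_effect Additive shift of latent log-abundance for the
#'   diet-responsive feature subset of a species' assigned diet category.
#' @param sigma_individual Standard deviation of per-individual,
#'   per-feature latent noise.
#' @param overdispersion Dirichlet-multinomial concentration; \code{Inf}
#'   (default) gives plain multinomial sampling.
#' @param responsive_fraction Fraction of features assigned to each diet
#'   category's disjoint responsive set.
#' @param seed Integer master RNG seed, expanded internally into
#'   per-stage sub-streams.
#' @return An object of class \code{simulation_params} (a validated list).
#' @export
simulation_params <- function(n_species = 16,
                              individuals_per_species = 10,
                              n_features = 300,
                              depth = 5000,
                              sigma_phylo = 0.1,
                              diet_effect = 1,
                              sigma_individual = 0.5,
                              overdispersion = Inf,
                              responsive_fraction = 0.1,
                              seed = 1) {
  p <- list(n_species = as.integer(n_species),
            individuals_per_species = as.integer(individuals_per_species),
            n_features = as.integer(n_features),
            depth = as.integer(depth),
            sigma_phylo = sigma_phylo,
            diet_effect = diet_effect,
            sigma_individual = sigma_individual,
            overdispersion = overdispersion,
            responsive_fraction = responsive_fraction,
            seed = as.integer(seed))
  if (p$n_species < 2)
    stop_paravec("n_species must be >= 2", "paravec_invalid_argument")
  if (p$n_features < 2)
    stop_paravec("n_features must be >= 2", "paravec_invalid_argument")
  if (p$depth < 1)
    stop_paravec("depth must be >= 1", "paravec_invalid_argument")
  if (!length(p$individuals_per_species) %in% 1:2 ||
      any(p$individuals_per_species < 1))
    stop_paravec("individuals_per_species must be a positive integer or range",
                 "paravec_invalid_argument")
  if (sigma_phylo < 0 || sigma_individual < 0)
    stop_paravec("variance parameters must be >= 0",
                 "paravec_invalid_argument")
  if (overdispersion <= 0)
    stop_paravec("overdispersion must be positive (Inf for multinomial)",
                 "paravec_invalid_argument")
  if (responsive_fraction < 0 || responsive_fraction > 1 / 6)
    stop_paravec("responsive_fraction must lie in [0, 1/6] so the six diet sets stay disjoint",
                 "paravec_invalid_argument")
  class(p) <- "simulation_params"
  p
}

#' Simulate an ultrametric host tree
#'
#' Draws a pure-birth (Yule) topology and rescales all branch lengths so
#' the root-to-tip distance equals \code{depth_myr}. Tips are labelled
#' \code{sp01, sp02, ...}. Deterministic for a given seed.
#'
#' @param n_species Number of tips; at least 2.
#' @param depth_myr Root-to-tip distance in millions of years.
#' @param seed Integer RNG seed.
#' @return An ultrametric \code{ape::phylo} tree.
#' @examples
#' tr <- simulate_tree(8, depth_myr = 50, seed = 1)
#' @export
simulate_tree <- function(n_species, depth_myr, seed = 1) {
  if (n_species < 2)
    stop_paravec("n_species must be >= 2", "paravec_invalid_argument")
  if (depth_myr <= 0)
    stop_paravec("depth_myr must be positive", "paravec_invalid_argument")
  n_species <- as.integer(n_species)
  if (n_species == 2L) {
    tree <- ape::read.tree(text = sprintf("(sp01:%g,sp02:%g);",
                                          depth_myr, depth_myr))
    return(tree)
  }
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * depth_myr / max(depths[seq_len(n_species)])
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

# Latent species-level log-abundance matrix (species x features):
# baseline + Brownian deviation along the tree + diet effect on the
# responsive feature set of each species' assigned category.
species_latents <- function(tree, diet_assignment, params, seeds) {
  n_sp <- length(tree$tip.label)
  nf <- params$n_features
  baseline <- with_seed(seeds[["baseline"]], stats::rnorm(nf, 0, 1))
  latent <- matrix(rep(baseline, each = n_sp), nrow = n_sp,
                   dimnames = list(tree$tip.label, sprintf("f%04d", seq_len(nf))))
  if (params$sigma_phylo > 0) {
    C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
    L <- t(chol(C))
    Z <- with_seed(seeds[["phylo"]],
                   matrix(stats::rnorm(n_sp * nf), nrow = n_sp))
    latent <- latent + params$sigma_phylo * (L %*% Z)
  }
  sets <- responsive_sets(nf, params$responsive_fraction, seeds[["diet_sets"]])
  if (params$diet_effect != 0) {
    for (sp in tree$tip.label) {
      set <- sets[[diet_assignment[[sp]]]]
      latent[sp, set] <- latent[sp, set] + params$diet_effect
    }
  }
  attr(latent, "responsive_sets") <- sets
  latent
}

# Disjoint diet-responsive feature index sets, one per category.
responsive_sets <- function(n_features, fraction, seed) {
  k <- floor(fraction * n_features)
  cats <- diet_categories()
  if (k == 0)
    return(stats::setNames(rep(list(integer(0)), length(cats)), cats))
  idx <- with_seed(seed, sample.int(n_features, k * length(cats)))
  sets <- split(idx, rep(cats, each = k))
  sets[cats]
}

#' Simulate a feature table and metadata on a host tree
#'
#' Generates per-sample counts under a log-linear model: each species'
#' latent log-abundance is a shared feature baseline plus a Brownian
#' deviation along the tree plus a diet effect on that diet's responsive
#' feature set; each individual adds independent Gaussian noise, the
#' latent vector is softmax-transformed to proportions, and counts are
#' drawn multinomially (or Dirichlet-multinomially) at the configured
#' depth.
#'
#' @param tree Ultrametric \code{phylo} host tree.
#' @param diet_assignment Named character vector or list mapping every tip
#'   label to one of [diet_categories()].
#' @param params A [simulation_params()] object.
#' @return A list with \code{table} (samples x features integer matrix),
#'   \code{metadata} (data frame, one row per sample) and
#'   \code{responsive_sets} (the diet-responsive feature indices).
#' @examples
#' tr <- simulate_tree(4, 50, seed = 1)
#' diets <- setNames(rep(c("plants", "meat-fish"), 2), tr$tip.label)
#' sim <- simulate_dataset(tr, diets, simulation_params(n_species = 4,
#'   individuals_per_species = 3, n_features = 50, seed = 2))
#' @export
simulate_dataset <- function(tree, diet_assignment, params) {
  stopifnot(inherits(params, "simulation_params"))
  diet_assignment <- unlist(diet_assignment)
  missing_tips <- setdiff(tree$tip.label, names(diet_assignment))
  if (length(missing_tips))
    stop_paravec(paste("tips without diet assignment:",
                       paste(missing_tips, collapse = ", ")),
                 "paravec_invalid_argument")
  bad <- setdiff(unique(diet_assignment), diet_categories())
  if (length(bad))
    stop_paravec(paste("unknown diet categories:", paste(bad, collapse = ", ")),
                 "paravec_invalid_argument")

  seeds <- substream_seeds(params$seed,
                           c("baseline", "phylo", "diet_sets",
                             "group_sizes", "individual", "counts"))
  latent <- species_latents(tree, diet_assignment, params, seeds)
  species <- tree$tip.label
  n_ind <- if (length(params$individuals_per_species) == 1L) {
    rep(params$individuals_per_species, length(species))
  } else {
    rng <- params$individuals_per_species
    with_seed(seeds[["group_sizes"]],
              sample(rng[1]:rng[2], length(species), replace = TRUE))
  }
  names(n_ind) <- species

  nf <- params$n_features
  total <- sum(n_ind)
  counts <- matrix(0L, nrow = total, ncol = nf,
                   dimnames = list(NULL, colnames(latent)))
  sample_id <- character(total)
  individual_id <- character(total)
  species_col <- character(total)

  noise <- with_seed(seeds[["individual"]],
                     matrix(stats::rnorm(total * nf, 0, params$sigma_individual),
                            nrow = total))
  row <- 0L
  with_seed(seeds[["counts"]], {
    for (sp in species) {
      for (k in seq_len(n_ind[[sp]])) {
        row <- row + 1L
        eta <- latent[sp, ] + noise[row, ]
        p <- exp(eta - max(eta))
        p <- p / sum(p)
        if (is.finite(params$overdispersion)) {
          g <- stats::rgamma(nf, shape = params$overdispersion * p)
          if (sum(g) == 0) g <- p
          p <- g / sum(g)
        }
        counts[row, ] <- as.integer(stats::rmultinom(1, params$depth, p))
        sample_id[row] <- sprintf("%s.s%02d", sp, k)
        individual_id[row] <- sprintf("%s.ind%02d", sp, k)
        species_col[row] <- sp
      }
    }
  })
  rownames(counts) <- sample_id

  diet_frac <- matrix(0, nrow = total, ncol = length(diet_categories()),
                      dimnames = list(NULL, diet_columns()))
  assigned <- diet_assignment[species_col]
  diet_frac[cbind(seq_len(total),
                  match(assigned, diet_categories()))] <- 1
  metadata <- data.frame(sample_id = sample_id,
                         individual_id = individual_id,
                         species = species_col,
                         age_category = "adult",
                         health = "healthy",
                         captive_wild = "wild",
                         seq_count = rowSums(counts),
                         diet_frac,
                         check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(table = counts, metadata = metadata,
       responsive_sets = attr(latent, "responsive_sets"))
}

#' Deterministic fixture exercising every sample/species filter rule
#'
#' Builds a small feature table and metadata containing, by construction:
#' a sample with 999 reads (below the 1,000-read cutoff), a duplicate
#' sample of one individual, a juvenile and a diseased individual, a
#' sample without an individual ID, a species with only 2 individuals, a
#' species with 25 individuals (to be subsampled to 20), a species whose
#' maximum diet fraction is 0.69 (non-specialist) and specialists at the
#' 0.70 boundary. The expected outcome of filtering is attached as the
#' \code{"expected"} attribute.
#'
#' @param seed Unused placeholder kept for interface symmetry; the fixture
#'   is fully deterministic.
#' @return List with \code{table}, \code{metadata} and an
#'   \code{"expected"} attribute describing the hand-enumerated survivors.
#' @export
make_filter_fixture <- function(seed = 1) {
  row_def <- function(id, ind, sp, age, health, seq) {
    data.frame(sample_id = id, individual_id = ind, species = sp,
               age_category = age, health = health,
               captive_wild = "wild", seq_count = seq,
               stringsAsFactors = FALSE)
  }
  md <- rbind(
    # egret: exactly 3 clean adults, one at the 1,000-read boundary
    row_def("A01", "egret.i1", "egret", "adult", "healthy", 1500),
    row_def("A02", "egret.i2", "egret", "adult", "healthy", 1000),
    row_def("A03", "egret.i3", "egret", "adult", "healthy", 2000),
    # gull: duplicates, missing ID, juvenile, diseased, low-read sample
    row_def("B01", "gull.i1", "gull", "adult", "healthy", 5000),
    row_def("B02", "gull.i1", "gull", "adult", "healthy", 5000),
    row_def("B03", "gull.i2", "gull", "adult", "healthy", 5000),
    row_def("B04", "gull.i3", "gull", "juvenile", "healthy", 5000),
    row_def("B05", "gull.i4", "gull", "adult", "diseased", 5000),
    row_def("B06", "gull.i5", "gull", "adult", "healthy", 999),
    row_def("B07", "gull.i6", "gull", "adult", "healthy", 5000),
    row_def("B08", "", "gull", "adult", "healthy", 5000),
    # vole: only 2 individuals -> dropped by the species-minimum rule
    row_def("C01", "vole.i1", "vole", "adult", "healthy", 3000),
    row_def("C02", "vole.i2", "vole", "adult", "healthy", 3000),
    # deermouse: 25 clean individuals -> subsampled to 20
    do.call(rbind, lapply(1:25, function(k)
      row_def(sprintf("D%02d", k), sprintf("deermouse.i%02d", k),
              "deermouse", "adult", "healthy", 4000))),
    # finch: clean but max diet fraction 0.69 -> non-specialist
    row_def("E01", "finch.i1", "finch", "adult", "healthy", 2500),
    row_def("E02", "finch.i2", "finch", "adult", "healthy", 2500),
    row_def("E03", "finch.i3", "finch", "adult", "healthy", 2500))

  frac <- matrix(0, nrow = nrow(md), ncol = length(diet_categories()),
                 dimnames = list(NULL, diet_columns()))
  frac_for <- function(sp) switch(sp,
    egret     = c("meat-fish" = 0.70, "plants" = 0.30),
    gull      = c("meat-fish" = 0.80, "invertebrates" = 0.20),
    vole      = c("plants" = 0.90, "seeds" = 0.10),
    deermouse = c("seeds" = 0.75, "fruits" = 0.25),
    finch     = c("seeds" = 0.69, "fruits" = 0.31))
  for (i in seq_len(nrow(md))) {
    f <- frac_for(md$species[i])
    frac[i, match(names(f), diet_categories())] <- f
  }
  md <- cbind(md, as.data.frame(frac, check.names = FALSE))

  n_feat <- 5L
  table <- matrix(1L, nrow = nrow(md), ncol = n_feat,
                  dimnames = list(md$sample_id,
                                  sprintf("f%02d", seq_len(n_feat))))
  table[, 1] <- as.integer(md$seq_count - (n_feat - 1L))

  expected <- list(
    removed_no_individual = "B08",
    removed_duplicate = "B02",
    removed_health = "B05",
    removed_age = "B04",
    removed_low_reads = "B06",
    removed_small_species = c("C01", "C02"),
    subsampled_species = "deermouse",
    subsample_pool = sprintf("D%02d", 1:25),
    n_subsampled = 20L,
    fixed_survivors = c("A01", "A02", "A03", "B01", "B03", "B07",
                        "E01", "E02", "E03"),
    specialists = c(egret = "meat-fish", gull = "meat-fish",
                    deermouse = "seeds"),
    non_specialists = "finch")
  out <- list(table = table, metadata = md)
  attr(out, "expected") <- expected
  out
}
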