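#' Filtering configuration
#'
#' Holds the sample- and species-level filter thresholds: minimum
#' per-sample sequence count (1,000), minimum (3) and maximum (20)
#' individuals per species, the retained age categories ("adult",
#' "after hatch year", "unknown"), the diet-specialist threshold (0.70)
#' and the seed used when subsampling species with too many individuals.
#'
#' @param min_sequences Minimum deblurred sequence count per sample.
#' @param min_individuals_per_species Minimum individuals a species must
#'   retain.
#' @param max_individuals_per_species Maximum individuals kept per species
#'   (random subsample beyond this).
#' @param allowed_age_categories Age categories retained.
#' @param allowed_health Health values retained (missing/blank always
#'   passes).
#' @param specialist_threshold Minimum diet fraction defining a
#'   specialist (inclusive).
#' @param subsample_seed Seed for the per-species subsampling RNG.
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(min_sequences = 1000,
                          min_individuals_per_species = 3,
                          max_individuals_per_species = 20,
                          allowed_age_categories = c("adult",
                                                     "after hatch year",
                                                     "unknown"),
                          allowed_health = c("healthy", "unknown"),
                          specialist_threshold = 0.70,
                          subsample_seed = 1) {
  cfg <- list(min_sequences = min_sequences,
              min_individuals_per_species = min_individuals_per_species,
              max_individuals_per_species = max_individuals_per_species,
              allowed_age_categories = allowed_age_categories,
              allowed_health = allowed_health,
              specialist_threshold = specialist_threshold,
              subsample_seed = as.integer(subsample_seed))
  if (cfg$specialist_threshold <= 0 || cfg$specialist_threshold > 1)
    stop_paravec("specialist_threshold must lie in (0, 1]",
                 "paravec_invalid_argument")
  if (cfg$min_individuals_per_species > cfg$max_individuals_per_species)
    stop_paravec("min individuals exceeds max individuals",
                 "paravec_invalid_argument")
  class(cfg) <- "filter_config"
  cfg
}

#' Apply the sample- and species-level filters
#'
#' Applies, in order: (1) drop samples lacking an individual ID; (2) drop
#' duplicate samples of the same individual, keeping the
#' lexicographically first sample ID; (3) drop unhealthy individuals;
#' (4) drop age categories outside the allowed set; (5) drop samples with
#' fewer sequences than the minimum; (6) drop species left with fewer
#' individuals than the minimum; (7) subsample species with more
#' individuals than the maximum, uniformly at random under the configured
#' seed. Every removal is tallied in the returned report.
#'
#' @param table Samples x features matrix.
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param config A [filter_config()].
#' @return List with filtered \code{table}, \code{metadata} and a
#'   \code{report} data frame (one row per rule: rule name, samples
#'   removed, samples remaining); the subsampling seed and per-rule
#'   removed sample IDs are attached as attributes of the report.
#' @export
apply_sample_filters <- function(table, metadata, config = filter_config()) {
  check_feature_table(table)
  if (!all(metadata$sample_id %in% rownames(table)))
    stop_paravec("metadata contains samples absent from the table",
                 "paravec_validation_error")
  md <- metadata[order(metadata$sample_id), , drop = FALSE]
  removed <- list()
  steps <- character()
  remaining <- integer()

  drop_step <- function(name, drop_idx) {
    removed[[name]] <<- md$sample_id[drop_idx]
    if (any(drop_idx)) md <<- md[!drop_idx, , drop = FALSE]
    steps <<- c(steps, name)
    remaining <<- c(remaining, nrow(md))
  }

  drop_step("missing_individual_id",
            is.na(md$individual_id) | md$individual_id == "")
  drop_step("duplicate_individual", duplicated(md$individual_id))
  health <- tolower(trimws(md$health))
  drop_step("health",
            !(health %in% tolower(config$allowed_health) |
                health == "" | is.na(md$health)))
  drop_step("age_category",
            !tolower(trimws(md$age_category)) %in%
              tolower(config$allowed_age_categories))
  drop_step("low_sequence_count", md$seq_count < config$min_sequences)
  counts <- table(md$species)
  small <- names(counts)[counts < config$min_individuals_per_species]
  drop_step("species_below_min_individuals", md$species %in% small)

  # per-species random subsample down to the maximum
  keep <- rep(TRUE, nrow(md))
  with_seed(config$subsample_seed, {
    for (sp in unique(md$species)) {
      idx <- which(md$species == sp)
      if (length(idx) > config$max_individuals_per_species) {
        kept <- sample(idx, config$max_individuals_per_species)
        keep[setdiff(idx, kept)] <- FALSE
      }
    }
  })
  drop_step("species_above_max_individuals", !keep)

  if (nrow(md) == 0)
    stop_paravec("no samples survive filtering", "paravec_empty_error")

  report <- data.frame(rule = steps,
                       samples_removed = lengths(removed[steps]),
                       samples_remaining = remaining,
                       row.names = NULL)
  attr(report, "removed_samples") <- removed
  attr(report, "subsample_seed") <- config$subsample_seed
  list(table = table[md$sample_id, , drop = FALSE],
       metadata = md,
       report = report)
}

#' Assign diet-specialist labels to species
#'
#' A species is a diet specialist when it consumes at least
#' \code{specialist_threshold} (default 70\%) of one diet category; the
#' species is labelled with that category and non-specialists are
#' dropped. Diet fractions are species-level: they must agree across a
#' species' samples within a small tolerance, otherwise an error is
#' raised.
#'
#' @param metadata Metadata data frame with the six \code{diet_*}
#'   columns.
#' @param specialist_threshold Inclusive specialist threshold in (0, 1].
#' @param tolerance Maximum allowed within-species disagreement of diet
#'   fractions.
#' @return Named character vector: species -> diet category (specialists
#'   only).
#' @examples
#' fx <- make_filter_fixture()
#' assign_diet_specialists(fx$metadata)
#' @export
assign_diet_specialists <- function(metadata, specialist_threshold = 0.70,
                                    tolerance = 1e-6) {
  cols <- diet_columns()
  out <- character()
  for (sp in unique(metadata$species)) {
    rows <- metadata[metadata$species == sp, cols, drop = FALSE]
    spread <- vapply(rows, function(x) diff(range(x)), numeric(1))
    if (any(spread > tolerance))
      stop_paravec(paste0("conflicting diet fractions within species '",
                          sp, "'"),
                   "paravec_validation_error")
    frac <- as.numeric(rows[1, ])
    if (sum(frac) > 1 + 1e-6)
      stop_paravec(paste0("diet fractions of '", sp, "' sum to > 1"),
                   "paravec_validation_error")
    if (max(frac) >= specialist_threshold)
      out[[sp]] <- diet_categories()[which.max(frac)]
  }
  out
}
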