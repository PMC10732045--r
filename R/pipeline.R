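#' Pipeline configuration
#'
#' One flat configuration for the end-to-end run: input paths, filter
#' settings, ordination threshold, comparison options, statistics options
#' and the master seed. Echoed into the output manifest for provenance.
#'
#' @param table_path Feature-table TSV (features x samples) or BIOM file.
#' @param metadata_path Metadata TSV.
#' @param tree_path Newick host tree.
#' @param out_dir Output directory (created if needed).
#' @param function_table_path Optional second feature table (e.g. pathway
#'   abundances); the ordination-through-analysis stages are re-run on it
#'   under \code{out_dir/function}.
#' @param filter A [filter_config()].
#' @param min_axis_prop Strict threshold on per-axis proportion of
#'   variation.
#' @param allow_shared_species Keep comparisons sharing a species.
#' @param time_definition Divergence-time summary for comparisons.
#' @param alpha Significance level for letter displays.
#' @param seed Master seed.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(table_path, metadata_path, tree_path, out_dir,
                            function_table_path = NULL,
                            filter = filter_config(),
                            min_axis_prop = 0.001,
                            allow_shared_species = FALSE,
                            time_definition = "all-pairs",
                            alpha = 0.05,
                            seed = 1) {
  cfg <- list(table_path = table_path, metadata_path = metadata_path,
              tree_path = tree_path, out_dir = out_dir,
              function_table_path = function_table_path,
              filter = filter, min_axis_prop = min_axis_prop,
              allow_shared_species = allow_shared_species,
              time_definition = time_definition,
              alpha = alpha, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Ordinate -> vectors -> comparisons -> quartets -> analysis on one
# feature table; writes stage outputs under `dir` and returns them.
run_branch <- function(table, metadata, diet_map, tree, dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  keep <- metadata$species %in% names(diet_map)
  metadata <- metadata[keep, , drop = FALSE]
  table <- table[metadata$sample_id, , drop = FALSE]
  table <- table[, colSums(table) > 0, drop = FALSE]

  dm <- bray_curtis(table)
  written <- c(written, write_tsv(
    data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
    file.path(dir, "distance_matrix.tsv")))

  ord <- retain_axes(pcoa(dm), cfg$min_axis_prop)
  written <- c(written, write_tsv(
    data.frame(axis = colnames(ord$points),
               eigenvalue = ord$eigenvalues,
               proportion_explained = ord$proportion_explained),
    file.path(dir, "eigenvalues.tsv")))
  written <- c(written, write_tsv(
    data.frame(sample_id = rownames(ord$points), ord$points,
               check.names = FALSE),
    file.path(dir, "coordinates.tsv")))

  centroids <- species_centroids(ord, metadata)
  written <- c(written, write_tsv(
    data.frame(species = rownames(centroids),
               n_samples = attr(centroids, "n_samples")[rownames(centroids)],
               centroids, check.names = FALSE),
    file.path(dir, "centroids.tsv")))

  vectors <- all_pair_vectors(centroids, diet_map)
  written <- c(written, write_tsv(
    cbind(vectors$info,
          as.data.frame(vectors$coords, check.names = FALSE)),
    file.path(dir, "vectors.tsv")))

  comparisons <- enumerate_comparisons(
    vectors, tree,
    allow_shared_species = cfg$allow_shared_species,
    time_definition = cfg$time_definition)
  written <- c(written, write_tsv(comparisons,
                                  file.path(dir, "comparisons.tsv")))

  quartets <- suppressWarnings(build_quartets(centroids, diet_map, tree))
  written <- c(written, write_tsv(quartets,
                                  file.path(dir, "quartets.tsv")))

  report <- run_analysis(comparisons, vectors, tree, quartets,
                         alpha = cfg$alpha, seed = cfg$seed)
  written <- c(written, write_tsv(report$table,
                                  file.path(dir, "analysis_report.tsv")))
  list(ordination = ord, centroids = centroids, vectors = vectors,
       comparisons = comparisons, quartets = quartets, report = report,
       files = written)
}

#' Run the full pipeline
#'
#' Reads the feature table, metadata and tree, applies the sample and
#' species filters and the diet-specialist rule, then runs
#' ordination, vector construction, comparison enumeration, quartet
#' construction and the statistical report, writing every stage output
#' plus a checksum manifest to the output directory. When a second
#' (function) feature table is configured, the ordination-through-
#' analysis stages are repeated on it with identical machinery.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{filtered}, \code{diet_map}, \code{taxonomic},
#'   \code{functional} branches) and the manifest data frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_feature_table(config$table_path)
  metadata <- read_metadata(config$metadata_path)
  tree <- read_tree(config$tree_path)

  filtered <- apply_sample_filters(table, metadata, config$filter)
  diet_map <- assign_diet_specialists(
    filtered$metadata, config$filter$specialist_threshold)
  if (!length(diet_map))
    stop_paravec("no diet-specialist species survive filtering",
                 "paravec_empty_error")

  files <- character()
  files <- c(files, write_tsv(filtered$report,
                              file.path(config$out_dir,
                                        "filter_report.tsv")))
  files <- c(files, write_feature_table(
    filtered$table,
    file.path(config$out_dir, "filtered_table.tsv")))
  files <- c(files, write_metadata(filtered$metadata,
                                   file.path(config$out_dir,
                                             "filtered_metadata.tsv")))
  files <- c(files, write_tsv(
    data.frame(species = names(diet_map), diet = unname(diet_map)),
    file.path(config$out_dir, "diet_map.tsv")))

  tax <- run_branch(filtered$table, filtered$metadata, diet_map, tree,
                    file.path(config$out_dir, "taxonomic"), config)
  files <- c(files, tax$files)

  fun <- NULL
  if (!is.null(config$function_table_path)) {
    ftab <- read_feature_table(config$function_table_path)
    common <- intersect(rownames(ftab), filtered$metadata$sample_id)
    if (length(common) < 3)
      stop_paravec("function table shares too few samples with metadata",
                   "paravec_validation_error")
    fun <- run_branch(ftab[common, , drop = FALSE],
                      filtered$metadata[
                        filtered$metadata$sample_id %in% common, ,
                        drop = FALSE],
                      diet_map, tree,
                      file.path(config$out_dir, "function"), config)
    files <- c(files, fun$files)
  }

  manifest <- data.frame(file = files,
                         stage = basename(dirname(files)),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(filtered = filtered, diet_map = diet_map,
                 taxonomic = tax, functional = fun,
                 manifest = manifest))
}
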