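#' Read a feature abundance table
#'
#' Reads a features-by-samples TSV (first column = feature ID, remaining
#' columns = samples) or a BIOM file, returning a samples-by-features
#' numeric matrix. Duplicate feature or sample IDs are rejected.
#'
#' @param path Path to the table.
#' @param format_hint One of \code{"tsv"} or \code{"biom"}; guessed from
#'   the file extension by default.
#' @return Samples x features numeric matrix with ID dimnames.
#' @export
read_feature_table <- function(path, format_hint = c("auto", "tsv", "biom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop_paravec(paste("no such file:", path), "paravec_io_error")
  if (format_hint == "auto")
    format_hint <- if (grepl("\\.biom$", path)) "biom" else "tsv"
  if (format_hint == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_paravec("biomformat package required for BIOM input",
                   "paravec_io_error")
    m <- as(biomformat::biom_data(biomformat::read_biom(path)), "matrix")
    table <- t(m)  # biom stores features x samples
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = NULL,
                             comment.char = "", quote = "",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2)
      stop_paravec("feature table must have an ID column and >= 1 sample",
                   "paravec_format_error")
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids))
      stop_paravec("duplicate feature IDs", "paravec_validation_error")
    if (anyDuplicated(colnames(raw)[-1]))
      stop_paravec("duplicate sample columns", "paravec_validation_error")
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop_paravec("non-numeric abundances in feature table",
                   "paravec_format_error")
    rownames(m) <- ids
    table <- t(m)
  }
  check_feature_table(table)
}

#' Write a feature table as TSV (features as rows)
#'
#' @param table Samples x features matrix.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  out <- data.frame(feature_id = colnames(table), t(table),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample host metadata
#'
#' Expects a TSV with columns \code{sample_id, individual_id, species,
#' age_category, health, captive_wild, seq_count} and the six
#' \code{diet_*} fraction columns.
#'
#' @param path Path to the metadata TSV.
#' @return Data frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop_paravec(paste("no such file:", path), "paravec_io_error")
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "individual_id", "species", "age_category",
                "health", "captive_wild", "seq_count", diet_columns())
  missing <- setdiff(required, colnames(md))
  if (length(missing))
    stop_paravec(paste("metadata lacks columns:",
                       paste(missing, collapse = ", ")),
                 "paravec_format_error")
  md$seq_count <- as.numeric(md$seq_count)
  for (col in diet_columns()) md[[col]] <- as.numeric(md[[col]])
  if (anyDuplicated(md$sample_id))
    stop_paravec("duplicate sample IDs in metadata",
                 "paravec_validation_error")
  md
}

#' Write sample metadata as TSV
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ultrametric host tree from a Newick file
#'
#' Branch lengths are interpreted as millions of years. A warning is
#' issued when tip depths differ by more than a small tolerance relative
#' to the tree depth.
#'
#' @param path Newick file.
#' @param tolerance Relative ultrametricity tolerance (fraction of tree
#'   depth).
#' @return An \code{ape::phylo} tree.
#' @export
read_tree <- function(path, tolerance = 1e-6) {
  if (!file.exists(path))
    stop_paravec(paste("no such file:", path), "paravec_io_error")
  tree <- ape::read.tree(path)
  if (is.null(tree))
    stop_paravec("could not parse Newick tree", "paravec_format_error")
  if (anyDuplicated(tree$tip.label))
    stop_paravec("duplicate tip labels in tree", "paravec_validation_error")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tolerance * max(depths))
    warning("tree is not ultrametric within tolerance; divergence times ",
            "are taken as MRCA depth below the first species")
  tree
}

#' Divergence time between two host species
#'
#' Time in millions of years since the two species shared a common
#' ancestor, computed as half the patristic path length between the tips
#' (equal to the MRCA depth on an ultrametric tree). Symmetric, and zero
#' if and only if the two species coincide.
#'
#' @param tree Ultrametric \code{phylo} tree.
#' @param sp1,sp2 Tip labels.
#' @return Divergence time in myr.
#' @examples
#' tr <- ape::read.tree(text = "(a:50,b:50);")
#' divergence_time(tr, "a", "b")  # 50
#' @export
divergence_time <- function(tree, sp1, sp2) {
  tips <- tree$tip.label
  if (!sp1 %in% tips || !sp2 %in% tips)
    stop_paravec(paste("species not in tree:",
                       paste(setdiff(c(sp1, sp2), tips), collapse = ", ")),
                 "paravec_lookup_error")
  if (sp1 == sp2) return(0)
  i <- match(sp1, tips); j <- match(sp2, tips)
  mrca <- ape::getMRCA(tree, c(i, j))
  depths <- ape::node.depth.edgelength(tree)
  depths[i] - depths[mrca]
}

# Divergence-time matrix over a set of species (myr).
divergence_time_matrix <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop_paravec(paste("species not in tree:",
                       paste(missing, collapse = ", ")),
                 "paravec_lookup_error")
  d <- ape::cophenetic.phylo(tree)[species, species, drop = FALSE] / 2
  d
}
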