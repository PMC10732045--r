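#' Diet categories recognised by the pipeline
#'
#' The six trophic specialisations used to label diet-specialist host
#' species: fruits, invertebrates, meat-endotherms, meat-fish, plants and
#' seeds.
#'
#' @return Character vector of the six category names, in alphabetical
#'   order (the global orientation order for divergence vectors).
#' @export
diet_categories <- function() {
  c("fruits", "invertebrates", "meat-endotherms", "meat-fish",
    "plants", "seeds")
}

# Metadata column names for the per-category diet fractions.
diet_columns <- function() {
  paste0("diet_", gsub("-", "_", diet_categories()))
}

#' Derive independent sub-stream seeds from one master seed
#'
#' A single user-facing seed is expanded into named per-stage seeds so
#' that each simulation stage (tree, traits, counts, subsampling) is
#' independently reproducible.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of seeds, one per stage, each < 2^31.
#' @export
substream_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max, length(stages))
  names(s) <- stages
  s
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run code under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  code
}

stop_paravec <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "paravec_error")))
}

# Validate a samples x features abundance matrix.
check_feature_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_paravec("feature table must be a numeric matrix (samples x features)",
                 "paravec_validation_error")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop_paravec("feature table needs sample rownames and feature colnames",
                 "paravec_validation_error")
  if (anyDuplicated(rownames(table)))
    stop_paravec("duplicate sample IDs in feature table",
                 "paravec_validation_error")
  if (anyDuplicated(colnames(table)))
    stop_paravec("duplicate feature IDs in feature table",
                 "paravec_validation_error")
  if (any(table < 0))
    stop_paravec("feature table contains negative abundances",
                 "paravec_validation_error")
  invisible(table)
}
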