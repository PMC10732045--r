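#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d(a,b) = 1 - 2 \sum_f \min(x_{af}, x_{bf}) /
#' (\sum_f x_{af} + \sum_f x_{bf})} between all samples, in [0, 1].
#'
#' @param table Samples x features non-negative matrix; no sample may be
#'   all zero.
#' @return A symmetric samples x samples matrix with zero diagonal and
#'   sample IDs as dimnames.
#' @examples
#' m <- rbind(a = c(2, 2), b = c(1, 3))
#' colnames(m) <- c("f1", "f2")
#' bray_curtis(m)["a", "b"]  # 0.25
#' @export
bray_curtis <- function(table) {
  check_feature_table(table)
  if (any(rowSums(table) == 0))
    stop_paravec("Bray-Curtis is undefined for all-zero samples",
                 "paravec_validation_error")
  d <- as.matrix(vegan::vegdist(table, method = "bray"))
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop_paravec("distance matrix must be square", "paravec_validation_error")
  if (max(abs(dm - t(dm))) > 1e-12)
    stop_paravec("distance matrix must be symmetric",
                 "paravec_validation_error")
  if (any(abs(diag(dm)) > 1e-12))
    stop_paravec("distance matrix must have a zero diagonal",
                 "paravec_validation_error")
  invisible(dm)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of \eqn{-\frac12 d^2} followed by
#' eigendecomposition. Axes with non-positive eigenvalues are discarded
#' (no Cailliez/Lingoes correction); coordinates are eigenvectors scaled
#' by the square root of their eigenvalue, and the proportion of
#' variation explained by axis k is \eqn{\lambda_k / \sum_{\lambda > 0}
#' \lambda}. Each axis' sign is canonicalised so its largest-magnitude
#' loading is positive, making downstream angles reproducible.
#'
#' @param dm Symmetric dissimilarity matrix with sample IDs as dimnames.
#' @return Object of class \code{paravec_ordination}: list with
#'   \code{points} (samples x axes), \code{eigenvalues} (positive,
#'   descending) and \code{proportion_explained}.
#' @export
pcoa <- function(dm) {
  check_distance_matrix(dm)
  if (nrow(dm) < 3)
    stop_paravec("PCoA needs at least 3 samples", "paravec_validation_error")
  res <- ape::pcoa(stats::as.dist(dm))
  eig <- res$values$Eigenvalues
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  if (!length(pos))
    stop_paravec("no positive eigenvalues in PCoA", "paravec_validation_error")
  pts <- res$vectors[, seq_along(pos), drop = FALSE]
  # canonical sign: largest-magnitude loading on each axis is positive
  for (k in seq_len(ncol(pts))) {
    j <- which.max(abs(pts[, k]))
    if (pts[j, k] < 0) pts[, k] <- -pts[, k]
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  ord <- list(points = pts,
              eigenvalues = eig[pos],
              proportion_explained = eig[pos] / sum(eig[pos]))
  class(ord) <- "paravec_ordination"
  ord
}

#' @export
print.paravec_ordination <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  cat("proportion explained (first 5):",
      paste(signif(utils::head(x$proportion_explained, 5), 3),
            collapse = " "), "\n")
  invisible(x)
}

#' Retain ordination axes above a variance threshold
#'
#' Keeps only axes whose proportion of explained variation is strictly
#' greater than \code{min_proportion} (default 0.1\%), preserving order.
#'
#' @param ordination A \code{paravec_ordination}.
#' @param min_proportion Strict lower bound on proportion explained.
#' @return The ordination restricted to the retained axes.
#' @export
retain_axes <- function(ordination, min_proportion = 0.001) {
  stopifnot(inherits(ordination, "paravec_ordination"))
  keep <- which(ordination$proportion_explained > min_proportion)
  if (!length(keep))
    stop_paravec("no axes exceed the variance threshold",
                 "paravec_empty_error")
  ord <- list(points = ordination$points[, keep, drop = FALSE],
              eigenvalues = ordination$eigenvalues[keep],
              proportion_explained = ordination$proportion_explained[keep])
  class(ord) <- "paravec_ordination"
  ord
}

#' Species centroids in ordination space
#'
#' Mean principal-coordinate scores across the retained axes for each
#' species (unweighted arithmetic mean of its member samples).
#'
#' @param ordination A \code{paravec_ordination} (after [retain_axes()]).
#' @param metadata Metadata mapping every sample to a species.
#' @return Species x axes matrix of centroids with an \code{n_samples}
#'   attribute (per-species sample counts).
#' @export
species_centroids <- function(ordination, metadata) {
  stopifnot(inherits(ordination, "paravec_ordination"))
  pts <- ordination$points
  missing <- setdiff(rownames(pts), metadata$sample_id)
  if (length(missing))
    stop_paravec(paste("samples without metadata:",
                       paste(utils::head(missing, 5), collapse = ", ")),
                 "paravec_lookup_error")
  sp <- metadata$species[match(rownames(pts), metadata$sample_id)]
  cent <- rowsum(pts, sp) / as.vector(table(sp)[sort(unique(sp))])
  n <- table(sp)
  attr(cent, "n_samples") <- stats::setNames(as.integer(n), names(n))
  cent
}
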