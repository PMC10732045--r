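#' Divergence vector between two species centroids
#'
#' The multivariate vector connecting two species' mean positions in
#' retained PCoA space: \code{centroid(to) - centroid(from)}. Its
#' Euclidean norm is the magnitude of gut microbiota divergence between
#' the two host species.
#'
#' @param centroids Species x axes centroid matrix from
#'   [species_centroids()].
#' @param from_species,to_species Species names (rows of
#'   \code{centroids}).
#' @param diet_map Optional named vector giving each species' diet
#'   category; carried through for orientation and classification.
#' @return List of class \code{divergence_vector}: \code{from}, \code{to},
#'   \code{from_diet}, \code{to_diet}, \code{coords}, \code{length}.
#' @export
divergence_vector <- function(centroids, from_species, to_species,
                              diet_map = NULL) {
  for (sp in c(from_species, to_species))
    if (!sp %in% rownames(centroids))
      stop_paravec(paste("species not in centroid set:", sp),
                   "paravec_lookup_error")
  coords <- centroids[to_species, ] - centroids[from_species, ]
  v <- list(from = from_species, to = to_species,
            from_diet = if (!is.null(diet_map)) unname(diet_map[[from_species]]) else NA_character_,
            to_diet = if (!is.null(diet_map)) unname(diet_map[[to_species]]) else NA_character_,
            coords = as.numeric(coords),
            length = sqrt(sum(coords^2)))
  class(v) <- "divergence_vector"
  v
}

#' Angle between two vectors
#'
#' \eqn{\theta = \arccos(\langle v_1, v_2\rangle / (\|v_1\| \|v_2\|))}
#' in degrees, in [0, 180]. The cosine is clamped to [-1, 1] to absorb
#' floating-point drift. Angles below 90 degrees indicate parallelism of
#' the two community shifts, angles above 90 degrees nonparallelism, and
#' 180 degrees anti-parallelism.
#'
#' @param v1,v2 Numeric vectors of equal length (or
#'   \code{divergence_vector} objects).
#' @return Angle in degrees.
#' @examples
#' angle_between(c(1, 0), c(1, 1))  # 45
#' @export
angle_between <- function(v1, v2) {
  if (inherits(v1, "divergence_vector")) v1 <- v1$coords
  if (inherits(v2, "divergence_vector")) v2 <- v2$coords
  if (length(v1) != length(v2))
    stop_paravec("vectors differ in dimensionality",
                 "paravec_validation_error")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop_paravec("angle undefined for zero-length vector",
                 "paravec_undefined_angle")
  cosv <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

#' Null distribution of angles between random vectors
#'
#' Draws pairs of independent standard-normal vectors in \code{dim}
#' dimensions and returns the angles between them. In any dimension the
#' distribution is centred at 90 degrees, and it concentrates (smaller
#' spread, approximately normal) as the dimension grows — the reference
#' null against which observed community-shift angles are judged.
#'
#' @param dim Dimensionality (>= 2).
#' @param n_draws Number of vector pairs.
#' @param seed Integer RNG seed.
#' @return List with \code{angles} (degrees), \code{mean} and \code{sd}.
#' @examples
#' random_angle_null(5, 1000, seed = 1)$mean
#' @export
random_angle_null <- function(dim, n_draws, seed = 1) {
  if (dim < 2)
    stop_paravec("dim must be >= 2", "paravec_invalid_argument")
  if (n_draws < 1)
    stop_paravec("n_draws must be >= 1", "paravec_invalid_argument")
  angles <- with_seed(seed, {
    z1 <- matrix(stats::rnorm(n_draws * dim), nrow = n_draws)
    z2 <- matrix(stats::rnorm(n_draws * dim), nrow = n_draws)
    cosv <- rowSums(z1 * z2) /
      (sqrt(rowSums(z1^2)) * sqrt(rowSums(z2^2)))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  })
  list(angles = angles, mean = mean(angles), sd = stats::sd(angles))
}

#' Divergence vectors for all species pairs
#'
#' One vector per unordered species pair, oriented deterministically:
#' under the default \code{"global-order"} rule each vector points from
#' the lower-ranked to the higher-ranked diet in the fixed alphabetical
#' diet ordering, so vectors spanning the same two diets are co-oriented;
#' same-diet pairs are oriented by species-name order.
#'
#' @param centroids Species x axes centroid matrix.
#' @param diet_map Named vector: species -> diet category.
#' @param orientation_rule Currently \code{"global-order"}.
#' @return Object of class \code{divergence_vectors}: a list with
#'   \code{info} (data frame: from, to, diets, length) and \code{coords}
#'   (vectors x axes matrix, rows aligned with \code{info}).
#' @export
all_pair_vectors <- function(centroids, diet_map,
                             orientation_rule = "global-order") {
  orientation_rule <- match.arg(orientation_rule, "global-order")
  species <- rownames(centroids)
  if (length(species) < 2)
    stop_paravec("need at least 2 species", "paravec_invalid_argument")
  missing <- setdiff(species, names(diet_map))
  if (length(missing))
    stop_paravec(paste("species without diet:",
                       paste(missing, collapse = ", ")),
                 "paravec_lookup_error")
  rank <- match(unname(diet_map[species]), diet_categories())
  if (anyNA(rank))
    stop_paravec("unknown diet category in diet_map",
                 "paravec_validation_error")
  names(rank) <- species

  pairs <- utils::combn(sort(species), 2)
  orient <- function(a, b) {
    if (rank[[a]] < rank[[b]]) c(a, b)
    else if (rank[[a]] > rank[[b]]) c(b, a)
    else c(a, b)  # same diet: species-name order (pairs are sorted)
  }
  n <- ncol(pairs)
  from <- character(n); to <- character(n)
  for (i in seq_len(n)) {
    ft <- orient(pairs[1, i], pairs[2, i])
    from[i] <- ft[1]; to[i] <- ft[2]
  }
  coords <- centroids[to, , drop = FALSE] - centroids[from, , drop = FALSE]
  rownames(coords) <- paste(from, to, sep = "|")
  info <- data.frame(vector_id = rownames(coords),
                     from = from, to = to,
                     from_diet = unname(diet_map[from]),
                     to_diet = unname(diet_map[to]),
                     length = sqrt(rowSums(coords^2)),
                     row.names = NULL,
                     stringsAsFactors = FALSE)
  out <- list(info = info, coords = coords)
  class(out) <- "divergence_vectors"
  out
}

#' @export
print.divergence_vectors <- function(x, ...) {
  cat("divergence vectors:", nrow(x$info), "species pairs,",
      ncol(x$coords), "axes\n")
  invisible(x)
}
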