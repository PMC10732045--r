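#' Classify a vector-pair comparison by host trophic divergence
#'
#' A comparison of two species-pair vectors is \emph{parallel host
#' trophic divergence} when both pairs span the same two diet categories,
#' \emph{nonparallel} when they span different diet combinations, and is
#' excluded when either pair has two members with the same diet.
#'
#' @param diets_pair1,diets_pair2 Length-2 character vectors of diet
#'   categories (unordered).
#' @return One of \code{"parallel_trophic"}, \code{"nonparallel_trophic"},
#'   \code{"excluded_same_diet"}.
#' @examples
#' classify_comparison(c("plants", "meat-fish"), c("meat-fish", "plants"))
#' @export
classify_comparison <- function(diets_pair1, diets_pair2) {
  all_d <- c(diets_pair1, diets_pair2)
  bad <- setdiff(all_d, diet_categories())
  if (length(bad))
    stop_paravec(paste("unknown diet label:", paste(bad, collapse = ", ")),
                 "paravec_validation_error")
  if (diets_pair1[1] == diets_pair1[2] || diets_pair2[1] == diets_pair2[2])
    return("excluded_same_diet")
  if (setequal(diets_pair1, diets_pair2)) "parallel_trophic"
  else "nonparallel_trophic"
}

#' Enumerate all comparisons between divergence vectors
#'
#' Every unordered pair of distinct species-pair vectors, with its
#' trophic-divergence category, the angle between the two vectors (NA
#' when either vector has zero length) and the mean host divergence time.
#' Two divergence-time summaries are emitted: the mean over all unordered
#' pairs of the distinct species involved (default definition, 6 pairs
#' for 4 distinct species) and the mean of the two within-vector
#' divergence times. Comparisons whose vectors share a species are
#' excluded by default.
#'
#' @param vectors A \code{divergence_vectors} object.
#' @param tree Ultrametric host tree covering all species.
#' @param allow_shared_species Keep comparisons whose two vectors share a
#'   species (default FALSE).
#' @param time_definition Which summary fills \code{mean_divergence_time}:
#'   \code{"all-pairs"} (default) or \code{"within-vector"}.
#' @return Data frame, one row per comparison: vector ids, the four
#'   species, category, angle (degrees), \code{shares_species},
#'   \code{mdt_all_pairs}, \code{mdt_within} and
#'   \code{mean_divergence_time}.
#' @export
enumerate_comparisons <- function(vectors, tree,
                                  allow_shared_species = FALSE,
                                  time_definition = c("all-pairs",
                                                      "within-vector")) {
  stopifnot(inherits(vectors, "divergence_vectors"))
  time_definition <- match.arg(time_definition)
  info <- vectors$info
  nv <- nrow(info)
  if (nv < 2)
    stop_paravec("need at least 2 vectors", "paravec_invalid_argument")
  species <- sort(unique(c(info$from, info$to)))
  D <- divergence_time_matrix(tree, species)

  # pairwise angles via normalised Gram matrix (zero vectors -> NA)
  lens <- info$length
  U <- vectors$coords / ifelse(lens > 0, lens, NA_real_)
  G <- U %*% t(U)
  idx <- utils::combn(nv, 2)
  i <- idx[1, ]; j <- idx[2, ]
  ang <- acos(pmin(1, pmax(-1, G[cbind(i, j)]))) * 180 / pi

  f1 <- info$from[i]; t1 <- info$to[i]
  f2 <- info$from[j]; t2 <- info$to[j]
  shares <- (f1 == f2) | (f1 == t2) | (t1 == f2) | (t1 == t2)

  category <- mapply(function(a, b, c, d)
    classify_comparison(c(a, b), c(c, d)),
    info$from_diet[i], info$to_diet[i],
    info$from_diet[j], info$to_diet[j])

  mdt_within <- (D[cbind(f1, t1)] + D[cbind(f2, t2)]) / 2
  # mean over unordered pairs of distinct species involved
  mdt_all <- (D[cbind(f1, t1)] + D[cbind(f1, f2)] + D[cbind(f1, t2)] +
                D[cbind(t1, f2)] + D[cbind(t1, t2)] + D[cbind(f2, t2)]) / 6
  if (any(shares)) {
    for (k in which(shares)) {
      sp <- unique(c(f1[k], t1[k], f2[k], t2[k]))
      pr <- utils::combn(sp, 2)
      mdt_all[k] <- mean(D[cbind(pr[1, ], pr[2, ])])
    }
  }

  out <- data.frame(vector_1 = info$vector_id[i],
                    vector_2 = info$vector_id[j],
                    from_1 = f1, to_1 = t1, from_2 = f2, to_2 = t2,
                    category = unname(category),
                    angle = ang,
                    shares_species = shares,
                    mdt_all_pairs = mdt_all,
                    mdt_within = mdt_within,
                    length_1 = lens[i], length_2 = lens[j],
                    stringsAsFactors = FALSE)
  out$mean_divergence_time <- if (time_definition == "all-pairs")
    out$mdt_all_pairs else out$mdt_within
  if (!allow_shared_species)
    out <- out[!out$shares_species, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build phylogenetically constrained quartets
#'
#' A quartet (A1, B1, A2, B2) consists of two species pairs spanning the
#' same two diet categories (diet(A1) = diet(A2) = a, diet(B1) = diet(B2)
#' = b, a != b), in which the two ecotypes within each pair are more
#' closely related to each other than to any member of the other pair:
#' \code{max(t(A1,B1), t(A2,B2)) < min(t(A1,A2), t(A1,B2), t(B1,A2),
#' t(B1,B2))}. For each accepted quartet three angles are computed:
#' the ecology comparison A1B1-A2B2 (both vectors oriented a -> b), the
#' phylogeny comparison A1A2-B1B2 and the cross comparison A1B2-A2B1
#' (within-diet vectors oriented pair 1 -> pair 2).
#'
#' @param centroids Species x axes centroid matrix.
#' @param diet_map Named vector: species -> diet category.
#' @param tree Ultrametric host tree.
#' @return Data frame, one row per quartet: the four species, the two
#'   diets, and \code{angle_ecology}, \code{angle_phylogeny},
#'   \code{angle_cross}; zero rows (with a warning) when no quartet
#'   qualifies.
#' @export
build_quartets <- function(centroids, diet_map, tree) {
  species <- rownames(centroids)
  diet_map <- diet_map[species]
  D <- divergence_time_matrix(tree, species)
  diets <- sort(unique(unname(diet_map)))
  rows <- list()
  for (da_i in seq_along(diets)) {
    for (db_i in seq_along(diets)) {
      if (db_i <= da_i) next
      a <- diets[da_i]; b <- diets[db_i]
      A <- sort(names(diet_map)[diet_map == a])
      B <- sort(names(diet_map)[diet_map == b])
      if (length(A) < 2 || length(B) < 2) next
      Apairs <- utils::combn(A, 2)
      for (k in seq_len(ncol(Apairs))) {
        A1 <- Apairs[1, k]; A2 <- Apairs[2, k]
        for (B1 in B) for (B2 in setdiff(B, B1)) {
          within <- max(D[A1, B1], D[A2, B2])
          across <- min(D[A1, A2], D[A1, B2], D[B1, A2], D[B1, B2])
          if (within >= across) next
          v_e1 <- centroids[B1, ] - centroids[A1, ]
          v_e2 <- centroids[B2, ] - centroids[A2, ]
          v_pA <- centroids[A2, ] - centroids[A1, ]
          v_pB <- centroids[B2, ] - centroids[B1, ]
          v_x1 <- centroids[B2, ] - centroids[A1, ]
          v_x2 <- centroids[B1, ] - centroids[A2, ]
          rows[[length(rows) + 1L]] <- data.frame(
            A1 = A1, B1 = B1, A2 = A2, B2 = B2,
            diet_a = a, diet_b = b,
            angle_ecology = angle_between(v_e1, v_e2),
            angle_phylogeny = angle_between(v_pA, v_pB),
            angle_cross = angle_between(v_x1, v_x2),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    warning("no quartet satisfies the relatedness constraint")
    return(data.frame(A1 = character(), B1 = character(),
                      A2 = character(), B2 = character(),
                      diet_a = character(), diet_b = character(),
                      angle_ecology = numeric(),
                      angle_phylogeny = numeric(),
                      angle_cross = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Same-diet versus different-diet vector grouping
#'
#' Partitions all species-pair divergence vectors by whether the two
#' member species feed on the same diet category, carrying vector length
#' and (optionally) the pair's host divergence time — the grouping used
#' to contrast the magnitude of community divergence.
#'
#' @param vectors A \code{divergence_vectors} object.
#' @param tree Optional host tree for divergence times.
#' @return Data frame: vector id, species, diets, \code{group}
#'   (\code{"same_diet"} or \code{"different_diet"}), \code{length} and
#'   \code{divergence_time} (NA without a tree).
#' @export
diet_contrast_groups <- function(vectors, tree = NULL) {
  stopifnot(inherits(vectors, "divergence_vectors"))
  info <- vectors$info
  out <- data.frame(vector_id = info$vector_id,
                    from = info$from, to = info$to,
                    from_diet = info$from_diet, to_diet = info$to_diet,
                    group = ifelse(info$from_diet == info$to_diet,
                                   "same_diet", "different_diet"),
                    length = info$length,
                    divergence_time = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    D <- divergence_time_matrix(tree, sort(unique(c(info$from, info$to))))
    out$divergence_time <- D[cbind(info$from, info$to)]
  }
  out
}
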