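#' Two-group location test
#'
#' Unpaired two-sample comparison: Welch's t-test (pooled variance via
#' \code{var_equal}) or the Wilcoxon rank-sum test, two-sided. Wilcoxon
#' p-values are exact for combined n <= 50 without ties and use the
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param method \code{"t"} or \code{"wilcoxon"}.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return List of class \code{paravec_test}: test name, statistic,
#'   p-value, group sizes, effect direction (sign of the mean
#'   difference x - y).
#' @export
compare_two_groups <- function(x, y, method = c("t", "wilcoxon"),
                               var_equal = FALSE) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2)
    stop_paravec("each group needs >= 2 observations",
                 "paravec_validation_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_paravec("non-finite values in groups", "paravec_validation_error")
  if (method == "t") {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    name <- if (var_equal) "two-sample t (pooled)" else "Welch two-sample t"
  } else {
    exact <- (length(x) + length(y) <= 50) &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    name <- "Wilcoxon rank-sum"
  }
  res <- list(test = name,
              statistic = unname(ht$statistic),
              p_value = ht$p.value,
              n = c(length(x), length(y)),
              direction = sign(mean(x) - mean(y)))
  class(res) <- "paravec_test"
  res
}

#' @export
print.paravec_test <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 5),
      ", p = ", format.pval(x$p_value), ", n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis test with pairwise post hoc Wilcoxon tests
#'
#' Rank-based k-group test (tie-corrected H statistic) followed by
#' pairwise Wilcoxon rank-sum tests with multiplicity adjustment and a
#' compact-letter display: groups sharing a letter do not differ at the
#' chosen alpha.
#'
#' @param groups Named list of numeric vectors, each of size >= 2.
#' @param posthoc_correction \code{"holm"} (default), \code{"bonferroni"}
#'   or \code{"none"}.
#' @param alpha Significance level for the letter display.
#' @return List of class \code{paravec_kgroups}: the Kruskal-Wallis
#'   statistic and p-value, matrix of adjusted pairwise p-values, and
#'   \code{letters} (compact letter display).
#' @export
compare_k_groups <- function(groups,
                             posthoc_correction = c("holm", "bonferroni",
                                                    "none"),
                             alpha = 0.05) {
  posthoc_correction <- match.arg(posthoc_correction)
  if (length(groups) < 2)
    stop_paravec("need >= 2 groups", "paravec_validation_error")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2))
    stop_paravec("every group needs >= 2 observations",
                 "paravec_validation_error")
  kw <- stats::kruskal.test(groups)
  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                 names(groups)))
  raw <- c()
  pairs <- utils::combn(k, 2)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    raw[m] <- compare_two_groups(groups[[i]], groups[[j]],
                                 method = "wilcoxon")$p_value
  }
  adj <- stats::p.adjust(raw, method = posthoc_correction)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    pmat[i, j] <- pmat[j, i] <- adj[m]
  }
  res <- list(test = "Kruskal-Wallis",
              statistic = unname(kw$statistic),
              df = unname(kw$parameter),
              p_value = kw$p.value,
              pairwise_p = pmat,
              correction = posthoc_correction,
              letters = compact_letters(pmat, alpha = alpha),
              n = lengths(groups))
  class(res) <- "paravec_kgroups"
  res
}

# Compact letter display by insert-and-absorb: groups sharing a letter
# are not significantly different at alpha.
compact_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  sets <- list(seq_len(k))  # candidate non-significant sets
  pairs <- utils::combn(k, 2)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  lets <- stats::setNames(rep("", k), g)
  for (s_i in seq_along(sets)) {
    for (gi in sets[[s_i]])
      lets[gi] <- paste0(lets[gi], letters[s_i])
  }
  lets
}

#' Shapiro-Wilk normality check
#'
#' Shapiro-Wilk W and p-value; samples larger than 5,000 are subsampled
#' (with the given seed) to the implementation limit, and the subsampling
#' is recorded in the result.
#'
#' @param x Numeric sample, 3 <= n.
#' @param seed Seed for the subsample when n > 5000.
#' @return List of class \code{paravec_test} with fields \code{test},
#'   \code{statistic} (W), \code{p_value}, \code{n}, \code{subsampled}.
#' @export
normality_check <- function(x, seed = 1) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    stop_paravec("need >= 3 finite observations", "paravec_validation_error")
  if (diff(range(x)) == 0)
    stop_paravec("normality check undefined for constant data",
                 "paravec_validation_error")
  subsampled <- FALSE
  if (length(x) > 5000) {
    x <- with_seed(seed, sample(x, 5000))
    subsampled <- TRUE
  }
  sw <- stats::shapiro.test(x)
  res <- list(test = "Shapiro-Wilk", statistic = unname(sw$statistic),
              p_value = sw$p.value, n = length(x),
              direction = NA_real_, subsampled = subsampled)
  class(res) <- "paravec_test"
  res
}

#' Linear and smooth trend fits against divergence time
#'
#' Fits (i) an ordinary least-squares line and (ii) a penalized
#' cubic-spline smoother (thin-plate basis, smoothness selected by
#' generalized cross-validation) of a response (angles or vector
#' lengths) against host divergence time. Both fits are returned so the
#' caller can compare the variance explained by each.
#'
#' @param x Divergence times (predictor).
#' @param y Angles or lengths (response), same length as \code{x}.
#' @param k Basis dimension of the smooth (default 10).
#' @param grid_n Number of grid points for fitted values.
#' @return List with elements \code{linear} and \code{smooth}, each of
#'   class \code{paravec_trend}: p-value of the divergence-time term,
#'   variance explained (R-squared for the line; deviance explained and
#'   adjusted R-squared for the smoother) and fitted values on an x-grid.
#'   The smooth is NULL (with a warning) when x has < 4 unique values.
#' @export
fit_trend <- function(x, y, k = 10, grid_n = 100) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10)
    stop_paravec("need >= 10 observations", "paravec_validation_error")
  grid <- seq(min(x), max(x), length.out = grid_n)

  is_const <- diff(range(y)) == 0
  lmfit <- stats::lm(y ~ x)
  sm <- summary(lmfit)
  r2 <- sm$r.squared
  # a constant response explains nothing; summary.lm's 0/0 is noise here
  if (is_const || !is.finite(r2)) r2 <- 0
  linear <- list(kind = "linear",
                 p_value = if (nrow(sm$coefficients) > 1)
                   sm$coefficients[2, 4] else NA_real_,
                 r_squared = r2,
                 fitted = data.frame(x = grid,
                                     y = stats::predict(lmfit,
                                                        data.frame(x = grid))))
  class(linear) <- "paravec_trend"

  smooth <- NULL
  gam <- NULL
  if (length(unique(x)) >= 4) {
    k_eff <- min(k, length(unique(x)) - 1)
    gam <- tryCatch(mgcv::gam(y ~ s(x, k = k_eff), method = "GCV.Cp"),
                    error = function(e) NULL)
    if (is.null(gam))
      warning("smooth fit failed to converge; linear fit only")
  } else {
    warning("fewer than 4 unique x values; smooth fit skipped")
  }
  if (!is.null(gam)) {
    sg <- summary(gam)
    dev_expl <- unname(sg$dev.expl)
    if (is_const || !is.finite(dev_expl)) dev_expl <- 0
    smooth <- list(kind = "smooth",
                   # mgcv can return p slightly outside [0,1] numerically
                   p_value = min(1, max(0, unname(sg$s.table[1, "p-value"]))),
                   deviance_explained = dev_expl,
                   r_squared = unname(sg$r.sq),
                   edf = unname(sg$s.table[1, "edf"]),
                   fitted = data.frame(x = grid,
                                       y = as.numeric(
                                         stats::predict(gam,
                                                        data.frame(x = grid)))))
    class(smooth) <- "paravec_trend"
  }
  list(linear = linear, smooth = smooth)
}

#' Full statistical report over enumerated comparisons
#'
#' Reproduces the analysis surface in one pass: the angle contrast
#' between parallel and nonparallel host-trophic-divergence categories
#' (Welch t and Wilcoxon, with Shapiro-Wilk normality gates), the
#' three-way quartet comparison (Kruskal-Wallis plus pairwise Wilcoxon
#' and compact letters), the same-diet versus different-diet vector
#' length contrast, and linear + smooth trends of angles and lengths
#' against host divergence time.
#'
#' @param comparisons Output of [enumerate_comparisons()].
#' @param vectors The \code{divergence_vectors} object.
#' @param tree Host tree.
#' @param quartets Optional output of [build_quartets()]; quartet tests
#'   are skipped when absent or empty.
#' @param alpha Significance level used in letter displays.
#' @param seed Seed for any internal subsampling.
#' @return List of class \code{paravec_report} with sections
#'   \code{parallel_vs_nonparallel}, \code{quartet}, \code{length_by_diet},
#'   \code{trend_angle}, \code{trend_length}, \code{group_means} and a
#'   long-format data frame \code{table}.
#' @export
run_analysis <- function(comparisons, vectors, tree, quartets = NULL,
                         alpha = 0.05, seed = 1) {
  sections <- list()
  rows <- list()
  add_row <- function(section, test, groups, n, statistic, p,
                      adjusted_p = NA_real_, variance_explained = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, test = test, groups = groups, n = n,
      statistic = statistic, p = p, adjusted_p = adjusted_p,
      variance_explained = variance_explained,
      stringsAsFactors = FALSE)
  }

  par_ang <- comparisons$angle[comparisons$category == "parallel_trophic"]
  non_ang <- comparisons$angle[comparisons$category == "nonparallel_trophic"]
  par_ang <- par_ang[is.finite(par_ang)]
  non_ang <- non_ang[is.finite(non_ang)]
  if (length(par_ang) >= 2 && length(non_ang) >= 2) {
    tt <- compare_two_groups(par_ang, non_ang, method = "t")
    ww <- compare_two_groups(par_ang, non_ang, method = "wilcoxon")
    sw_p <- if (length(par_ang) >= 3) normality_check(par_ang, seed)$p_value
            else NA_real_
    sw_n <- if (length(non_ang) >= 3) normality_check(non_ang, seed)$p_value
            else NA_real_
    sections$parallel_vs_nonparallel <- list(
      t = tt, wilcoxon = ww,
      shapiro_p = c(parallel = sw_p, nonparallel = sw_n),
      means = c(parallel = mean(par_ang), nonparallel = mean(non_ang)))
    add_row("angles", tt$test, "parallel vs nonparallel",
            length(par_ang) + length(non_ang), tt$statistic, tt$p_value)
    add_row("angles", ww$test, "parallel vs nonparallel",
            length(par_ang) + length(non_ang), ww$statistic, ww$p_value)
  }

  if (!is.null(quartets) && nrow(quartets) >= 2) {
    qgroups <- list(ecology = quartets$angle_ecology,
                    phylogeny = quartets$angle_phylogeny,
                    cross = quartets$angle_cross)
    kg <- compare_k_groups(qgroups, alpha = alpha)
    sections$quartet <- list(kruskal = kg,
                             means = vapply(qgroups, mean, numeric(1)))
    add_row("quartet", kg$test, "ecology/phylogeny/cross",
            sum(kg$n), kg$statistic, kg$p_value)
  }

  contrast <- diet_contrast_groups(vectors, tree)
  same_len <- contrast$length[contrast$group == "same_diet"]
  diff_len <- contrast$length[contrast$group == "different_diet"]
  if (length(same_len) >= 2 && length(diff_len) >= 2) {
    wl <- compare_two_groups(same_len, diff_len, method = "wilcoxon")
    sections$length_by_diet <- list(
      wilcoxon = wl,
      means = c(same_diet = mean(same_len),
                different_diet = mean(diff_len)))
    add_row("lengths", wl$test, "same vs different diet",
            length(same_len) + length(diff_len), wl$statistic, wl$p_value)
  }

  ang_ok <- is.finite(comparisons$angle) &
    is.finite(comparisons$mean_divergence_time)
  if (sum(ang_ok) >= 10) {
    tr <- fit_trend(comparisons$mean_divergence_time[ang_ok],
                    comparisons$angle[ang_ok])
    sections$trend_angle <- tr
    add_row("trend", "linear (angle ~ time)", "all comparisons",
            sum(ang_ok), NA_real_, tr$linear$p_value,
            variance_explained = tr$linear$r_squared)
    if (!is.null(tr$smooth))
      add_row("trend", "smooth (angle ~ time)", "all comparisons",
              sum(ang_ok), NA_real_, tr$smooth$p_value,
              variance_explained = tr$smooth$deviance_explained)
  }
  len_ok <- is.finite(contrast$length) & is.finite(contrast$divergence_time)
  if (sum(len_ok) >= 10) {
    trl <- fit_trend(contrast$divergence_time[len_ok],
                     contrast$length[len_ok])
    sections$trend_length <- trl
    add_row("trend", "linear (length ~ time)", "all vectors",
            sum(len_ok), NA_real_, trl$linear$p_value,
            variance_explained = trl$linear$r_squared)
    if (!is.null(trl$smooth))
      add_row("trend", "smooth (length ~ time)", "all vectors",
              sum(len_ok), NA_real_, trl$smooth$p_value,
              variance_explained = trl$smooth$deviance_explained)
  }

  sections$group_means <- stats::aggregate(
    angle ~ category, data = comparisons[is.finite(comparisons$angle), ],
    FUN = mean)
  sections$table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(section = character(), test = character(),
               groups = character(), n = integer(), statistic = numeric(),
               p = numeric(), adjusted_p = numeric(),
               variance_explained = numeric())
  sections$alpha <- alpha
  sections$seed <- seed
  class(sections) <- "paravec_report"
  sections
}

#' @export
print.paravec_report <- function(x, ...) {
  cat("paravec analysis report\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
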