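#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based permutation test contrasting between-group and
#' within-group dissimilarities:
#' `R = (mean_rank_between - mean_rank_within) / (M / 2)` with
#' `M = n(n-1)/2` ranks over the lower triangle (average ranks for ties).
#' R lies in `[-1, 1]`; values near 0 indicate no group structure, 1 means
#' every between-group dissimilarity exceeds every within-group one. The
#' p-value uses the add-one permutation estimator
#' `p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm)` over random relabellings
#' of the samples, and is reproducible bit-for-bit for a fixed `seed`.
#'
#' @param dist A `dist` object or symmetric zero-diagonal matrix.
#' @param groups Group labels, one per sample, in the order of the
#'   distance matrix (or named by its labels). At least 2 groups with at
#'   least 2 members each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream; the
#'   caller's RNG state is left untouched.
#' @return An object of class `barisa_anosim` with fields `statistic`,
#'   `p_value`, `n_permutations`, `seed`, `n_samples`, `groups` and the
#'   permutation null `perm_stats`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
anosim_test <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  groups <- align_groups(groups, rownames(d), n)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least 2 members; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  stopifnot(n_perm >= 0)

  lower <- lower.tri(d)
  r <- rank(d[lower])              # average ranks for ties
  M <- length(r)
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  stat_for <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  observed <- stat_for(groups)

  perm <- function() {
    vapply(seq_len(n_perm), function(k) stat_for(sample(groups)), numeric(1))
  }
  perm_stats <- if (n_perm == 0) {
    numeric(0)
  } else if (is.null(seed)) {
    perm()
  } else {
    withr::with_seed(seed, perm())
  }
  p <- if (n_perm == 0) {
    NA_real_
  } else {
    (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  }
  structure(
    list(
      statistic = observed, p_value = p, n_permutations = n_perm,
      seed = seed, n_samples = n, groups = groups, perm_stats = perm_stats
    ),
    class = "barisa_anosim"
  )
}

as_dist_matrix <- function(dist) {
  if (inherits(dist, "dist")) {
    d <- as.matrix(dist)
  } else {
    d <- as.matrix(dist)
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))) ||
        any(diag(d) != 0)) {
      stop("dist must be a 'dist' object or a symmetric matrix with a ",
           "zero diagonal", call. = FALSE)
    }
  }
  d
}

align_groups <- function(groups, labels, n) {
  g <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(labels) &&
      all(labels %in% names(groups))) {
    g <- as.character(groups[labels])
  }
  if (length(g) != n) {
    stop("groups must have one label per sample (", n, ")", call. = FALSE)
  }
  g
}

#' @export
print.barisa_anosim <- function(x, ...) {
  cat("ANOSIM: R =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname anosim_test
#' @param x A `barisa_anosim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.barisa_anosim <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    n_samples = x$n_samples,
    n_groups = length(unique(x$groups))
  )
}

#' @rdname anosim_test
#' @exportS3Method generics::glance
glance.barisa_anosim <- function(x, ...) tidy(x)

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Delegates to [vegan::metaMDS()] (Kruskal stress-1 minimized from
#' several seeded random starts) and returns centered coordinates plus the
#' final stress.
#'
#' @param dist A `dist` object or symmetric zero-diagonal matrix.
#' @param k Number of ordination dimensions (default 2).
#' @param seed Optional integer seed for the random starts.
#' @param try,trymax Minimum / maximum number of random starts.
#' @return An object of class `barisa_nmds` with `points` (n x k matrix,
#'   centered), `stress` (Kruskal stress-1, 0-1 scale), `converged` and
#'   `k`. Has `tidy()`, `glance()` and [ggplot2::autoplot()] methods.
#' @export
nmds_ordination <- function(dist, k = 2, seed = NULL, try = 20,
                            trymax = 50) {
  d <- stats::as.dist(as_dist_matrix(dist))
  n <- attr(d, "Size")
  if (n < k + 1) {
    stop("need at least k + 1 = ", k + 1, " samples for a ", k,
         "-dimensional ordination; got ", n, call. = FALSE)
  }
  run <- function() {
    suppressWarnings(
      vegan::metaMDS(d, k = k, trace = 0, try = try, trymax = trymax,
                     autotransform = FALSE, wascores = FALSE)
    )
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  pts <- scale(vegan::scores(fit, display = "sites"), scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- labels(d) %||% rownames(pts)
  structure(
    list(points = pts, stress = fit$stress, converged = fit$converged,
         k = k),
    class = "barisa_nmds"
  )
}

#' @export
print.barisa_nmds <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples in", x$k,
      "dimensions; stress =", format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' @rdname nmds_ordination
#' @param x A `barisa_nmds` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.barisa_nmds <- function(x, ...) {
  pts <- x$points
  out <- tibble::as_tibble(pts, .name_repair = "minimal")
  names(out) <- paste0("NMDS", seq_len(ncol(pts)))
  tibble::add_column(
    out,
    sample_id = rownames(pts) %||% as.character(seq_len(nrow(pts))),
    .before = 1
  )
}

#' @rdname nmds_ordination
#' @exportS3Method generics::glance
glance.barisa_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, converged = isTRUE(x$converged),
                 k = x$k, n_samples = nrow(x$points))
}

#' Correlate diversity statistics between two primer sets
#'
#' Pearson correlation (with two-sided t-test, `df = n - 2`) of per-sample
#' OTU richness and Shannon diversity obtained from the same samples
#' fingerprinted with two different primer systems.
#'
#' @param stats_a,stats_b [diversity_stats()] tibbles over identical
#'   sample sets (n >= 3).
#' @return Tibble with columns `metric` (`"richness"`, `"shannon"`),
#'   `estimate` (Pearson r), `p_value`, `n`.
#' @export
compare_primer_sets <- function(stats_a, stats_b) {
  stopifnot(is.data.frame(stats_a), is.data.frame(stats_b))
  if (!setequal(stats_a$sample_id, stats_b$sample_id) ||
      nrow(stats_a) != nrow(stats_b)) {
    stop("the two primer sets must cover identical sample sets",
         call. = FALSE)
  }
  if (nrow(stats_a) < 3) {
    stop("need at least 3 matched samples", call. = FALSE)
  }
  joined <- dplyr::inner_join(stats_a, stats_b, by = "sample_id",
                              suffix = c("_a", "_b"))
  one <- function(metric) {
    a <- joined[[paste0(metric, "_a")]]
    b <- joined[[paste0(metric, "_b")]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("zero variance in ", metric, "; correlation undefined",
           call. = FALSE)
    }
    ct <- stats::cor.test(a, b, method = "pearson",
                          alternative = "two.sided")
    tibble::tibble(metric = metric, estimate = unname(ct$estimate),
                   p_value = ct$p.value, n = length(a))
  }
  dplyr::bind_rows(one("richness"), one("shannon"))
}
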