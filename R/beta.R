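dist_metrics <- c("bray_curtis", "chao", "jaccard", "kulczynski", "mountford")

#' Sample-by-sample ecological dissimilarity matrix
#'
#' Computes one of five dissimilarities between all sample pairs of an
#' abundance table:
#' * `bray_curtis`: \eqn{\sum|x-y| / \sum(x+y)};
#' * `jaccard`: the quantitative variant `2B/(1+B)` of the Bray-Curtis
#'   value `B` (set `binary = TRUE` for the classical presence/absence
#'   form);
#' * `kulczynski`: \eqn{1 - \frac12 (W/\sum x + W/\sum y)} with
#'   \eqn{W = \sum \min(x, y)};
#' * `chao`: the abundance-based Chao-Jaccard dissimilarity with
#'   unseen-shared-species correction from shared singleton/doubleton
#'   counts (requires count data);
#' * `mountford`: a presence/absence index computed by this package's own
#'   root solver, see [mountford_theta()]; reported as the dissimilarity
#'   `1 - min(theta, log 2)/log 2`, so identical presence sets give 0 and
#'   disjoint sets give 1.
#'
#' Bray-Curtis, Jaccard and Kulczynski are delegated to
#' [vegan::vegdist()]; Mountford is computed natively because the package
#' fixes an explicit `[0, 1]` scaling convention.
#'
#' @param table An [abundance_table()] with at least two samples and
#'   positive column sums.
#' @param metric One of `"bray_curtis"`, `"chao"`, `"jaccard"`,
#'   `"kulczynski"`, `"mountford"`.
#' @param binary For `jaccard` only: use the presence/absence variant.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal and
#'   attributes `metric` and `sample_ids`.
#' @export
distance_matrix <- function(table, metric = dist_metrics, binary = FALSE) {
  metric <- match.arg(metric)
  m <- at_values(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  comm <- t(m)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(comm, method = "bray"),
    jaccard = vegan::vegdist(comm, method = "jaccard", binary = binary),
    kulczynski = vegan::vegdist(comm, method = "kulczynski"),
    chao = vegan::vegdist(comm, method = "chao"),
    mountford = mountford_dist(comm)
  )
  out <- as.matrix(d)
  diag(out) <- 0
  dimnames(out) <- list(colnames(m), colnames(m))
  structure(out, class = c("dist_matrix", "matrix"),
            metric = metric, sample_ids = colnames(m))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> metric=%s over %d samples\n", attr(x, "metric"), nrow(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], 4))
  invisible(x)
}

#' @export
as.dist.dist_matrix <- function(m, ...) stats::as.dist(unclass(m))

# lower-triangle pair values of a dist_matrix
dm_lower <- function(dm) as.vector(stats::as.dist(unclass(dm)))

#' Mountford's similarity parameter theta
#'
#' For two presence sets with `a` and `b` species and `j` shared,
#' Mountford's theta is the positive root of
#' \deqn{e^{a\theta} + e^{b\theta} = 1 + e^{(a+b-j)\theta}.}
#' Larger theta means more similar communities. The root is found by
#' bracketed bisection to 1e-10 (the upper bracket grown by doubling until
#' the sign changes). Degenerate cases are handled analytically: `j = 0`
#' gives 0 (no positive root; maximally dissimilar) and
#' `j = min(a, b)` (nested or identical sets) gives `Inf`, since the root
#' escapes to infinity in that limit.
#'
#' @param a,b Species counts of the two samples (positive integers).
#' @param j Shared species count, `0 <= j <= min(a, b)`.
#' @param tol Bisection tolerance.
#' @return The positive root theta (possibly 0 or `Inf`).
#' @export
mountford_theta <- function(a, b, j, tol = 1e-10) {
  stopifnot(a >= 1, b >= 1, j >= 0, j <= min(a, b))
  if (j == 0) return(0)
  if (j == min(a, b)) return(Inf)
  f <- function(t) exp(a * t) + exp(b * t) - 1 - exp((a + b - j) * t)
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Mountford dissimilarity over a samples-x-features occurrence matrix:
# d = 1 - min(theta, log 2) / log 2, matching vegan's log(2) - theta up to
# the 1/log(2) scaling (checked in the test-suite).
mountford_dist <- function(comm) {
  pa <- comm > 0
  n <- nrow(pa)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      a <- sum(pa[i, ]); b <- sum(pa[k, ])
      j <- sum(pa[i, ] & pa[k, ])
      theta <- mountford_theta(a, b, j)
      d[i, k] <- d[k, i] <- 1 - min(theta, log(2)) / log(2)
    }
  }
  stats::as.dist(d)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style monotone-regression stress minimisation from multiple
#' random starts (via [vegan::metaMDS()] on the precomputed dissimilarity,
#' no transformation), returning the configuration with the lowest Kruskal
#' stress-1. The final configuration is centred and rotated to principal
#' axes. Deterministic for a fixed seed.
#'
#' @param dm A [distance_matrix()] result.
#' @param k Number of ordination axes (default 2); must satisfy `k < n - 1`.
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Integer seed for the restart stream.
#' @return An object of class `nmds_ordination` with elements `coordinates`
#'   (tibble: `sample_id`, `NMDS1`, ...), `stress`, `converged`,
#'   `n_restarts`, `seed`, `metric`.
#' @export
nmds <- function(dm, k = 2, n_restarts = 50, seed = 1) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- nrow(dm)
  if (k >= n - 1) stop("k must be smaller than n - 1", call. = FALSE)
  d <- stats::as.dist(unclass(dm))
  if (all(d == 0)) stop("all dissimilarities are zero; nothing to ordinate", call. = FALSE)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        autotransform = FALSE, wascores = FALSE, trace = 0)
  coords <- vegan::scores(fit, display = "sites")
  colnames(coords) <- paste0("NMDS", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = attr(dm, "sample_ids")),
        tibble::as_tibble(coords)
      ),
      stress = fit$stress,
      converged = isTRUE(fit$converged) ||
        (is.numeric(fit$converged) && fit$converged > 0),
      n_restarts = n_restarts,
      seed = seed,
      metric = attr(dm, "metric"),
      engine = fit
    ),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("<nmds_ordination> metric=%s, k=%d, stress=%.4f, converged=%s\n",
              x$metric, ncol(x$coordinates) - 1, x$stress, x$converged))
  invisible(x)
}

#' @method tidy nmds_ordination
#' @export
tidy.nmds_ordination <- function(x, ...) x$coordinates

#' @method glance nmds_ordination
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, converged = x$converged,
                 n_restarts = x$n_restarts, seed = x$seed, metric = x$metric)
}

#' @param object An `nmds_ordination`.
#' @param grouping Optional factor (named by sample id or in sample order)
#'   used to colour points.
#' @param ... Unused.
#' @rdname nmds
#' @method autoplot nmds_ordination
#' @export
autoplot.nmds_ordination <- function(object, grouping = NULL, ...) {
  df <- object$coordinates
  if (!is.null(grouping)) {
    g <- if (!is.null(names(grouping))) grouping[df$sample_id] else grouping
    df$group <- factor(g)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2, colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("NMDS (%s), stress = %.3f", object$metric, object$stress)) +
    ggplot2::theme_minimal()
}

#' Rank concordance between two distance matrices
#'
#' Correlates the paired lower-triangle entries of two dissimilarity
#' matrices over the same samples: Spearman's rho (average ranks; two-sided
#' P from the t approximation) and Kendall's tau (two-sided P from the
#' tie-corrected normal approximation). An optional Mantel permutation test
#' (exchangeability-correct inference) is run when `mantel_permutations`
#' is given.
#'
#' @param dm_a,dm_b [distance_matrix()] results over the same sample ids in
#'   the same order.
#' @param mantel_permutations If non-`NULL`, also run a Mantel test with
#'   this many permutations (Spearman statistic) via [vegan::mantel()].
#' @param seed Seed for the Mantel permutations.
#' @return A one-row tibble: `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`, `n_pairs`, and `mantel_p` when requested.
#' @export
matrix_concordance <- function(dm_a, dm_b, mantel_permutations = NULL, seed = 1) {
  ids_a <- attr(dm_a, "sample_ids")
  ids_b <- attr(dm_b, "sample_ids")
  if (!identical(ids_a, ids_b)) {
    stop("distance matrices must cover the same samples in the same order", call. = FALSE)
  }
  va <- dm_lower(dm_a)
  vb <- dm_lower(dm_b)
  sp <- spearman_t(va, vb)
  kt <- suppressWarnings(stats::cor.test(va, vb, method = "kendall", exact = FALSE))
  out <- tibble::tibble(
    spearman_rho = sp$rho, spearman_p = sp$p,
    kendall_tau = unname(kt$estimate), kendall_p = kt$p.value,
    n_pairs = length(va)
  )
  if (!is.null(mantel_permutations)) {
    set.seed(seed)
    mt <- vegan::mantel(stats::as.dist(unclass(dm_a)), stats::as.dist(unclass(dm_b)),
                        method = "spearman", permutations = mantel_permutations)
    out$mantel_p <- mt$signif
  }
  out
}
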