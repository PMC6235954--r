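# align a grouping/metadata vector to the samples of a dist_matrix
align_to_samples <- function(x, sample_ids, what = "grouping") {
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing) > 0) {
      stop(what, " missing for sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[sample_ids]
  } else if (length(x) != length(sample_ids)) {
    stop(what, " must be named by sample id or match the number of samples", call. = FALSE)
  }
  x
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Partitions the Gower-centred squared-distance matrix into between- and
#' within-group sums of squares (McArdle-Anderson), forming the pseudo-F
#' statistic \eqn{(SS_b/df_b)/(SS_w/df_w)} whose null distribution is
#' obtained by free (unrestricted) permutation of the group labels. The
#' permutation P-value uses the `(1 + #exceedances)/(1 + n)` convention,
#' so it is never zero; its floor is `1/(n_permutations + 1)`. Delegates
#' the partition and permutations to [vegan::adonis2()]; deterministic for
#' a fixed seed.
#'
#' @param dm A [distance_matrix()] result.
#' @param grouping Group labels, named by sample id or in sample order; at
#'   least two groups with at least two samples each.
#' @param n_permutations Number of label permutations (default 9999), or an
#'   explicit permutation matrix (rows = permutations) for exhaustive
#'   enumeration on small designs.
#' @param seed Integer seed.
#' @param factor_name Label for the tested factor.
#' @return An object of class `permanova_fit` with `pseudo_F`, `R2`, `p`,
#'   `df_between`, `df_within`, `n_permutations`, and the full
#'   decomposition table.
#' @export
permanova <- function(dm, grouping, n_permutations = 9999, seed = 1,
                      factor_name = "grouping") {
  stopifnot(inherits(dm, "dist_matrix"))
  ids <- attr(dm, "sample_ids")
  g <- factor(align_to_samples(grouping, ids))
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(unclass(dm))
  degenerate <- length(unique(round(as.vector(d), 12))) == 1
  if (degenerate) {
    warning("all pairwise distances are equal; PERMANOVA is uninformative (P = 1)",
            call. = FALSE)
  }
  set.seed(seed)
  df <- data.frame(g = g)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_permutations)
  n_perm <- if (is.matrix(n_permutations)) nrow(n_permutations) else n_permutations
  p <- fit$`Pr(>F)`[1]
  if (degenerate) p <- 1
  decomposition <- tibble::tibble(
    term = c(factor_name, "Residual", "Total"),
    df = fit$Df,
    sum_of_squares = fit$SumOfSqs,
    R2 = fit$R2,
    pseudo_F = fit$F,
    p = c(p, NA, NA)
  )
  structure(
    list(factor_name = factor_name,
         pseudo_F = fit$F[1], R2 = fit$R2[1], p = p,
         df_between = fit$Df[1], df_within = fit$Df[2],
         n_permutations = n_perm, seed = seed,
         metric = attr(dm, "metric"),
         decomposition = decomposition),
    class = "permanova_fit"
  )
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("<permanova_fit> %s on %s distances: pseudo-F = %.3f, R2 = %.3f, P = %.4g (%d permutations)\n",
              x$factor_name, x$metric, x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) x$decomposition

#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p,
                 df_between = x$df_between, df_within = x$df_within,
                 n_permutations = x$n_permutations, metric = x$metric)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and applies
#' a Bonferroni adjustment over the pairs (multiplicity is counted across
#' cluster pairs only, not across distance metrics).
#'
#' @inheritParams permanova
#' @return A tibble with one row per group pair: `group_a`, `group_b`,
#'   `pseudo_F`, `R2`, `p`, `p_adjusted` (`min(1, p * n_pairs)`).
#' @export
pairwise_permanova <- function(dm, grouping, n_permutations = 9999, seed = 1) {
  ids <- attr(dm, "sample_ids")
  g <- factor(align_to_samples(grouping, ids))
  if (nlevels(g) < 3) stop("pairwise comparison needs at least 3 groups", call. = FALSE)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  res <- purrr::map_dfr(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- ids[g %in% pr]
    sub <- structure(unclass(dm)[keep, keep, drop = FALSE],
                     class = c("dist_matrix", "matrix"),
                     metric = attr(dm, "metric"), sample_ids = keep)
    fit <- permanova(sub, stats::setNames(as.character(g[g %in% pr]), keep),
                     n_permutations = n_permutations, seed = seed + i)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   pseudo_F = fit$pseudo_F, R2 = fit$R2, p = fit$p)
  })
  res$p_adjusted <- pmin(1, res$p * length(pairs))
  res
}

# z-score numeric constraint columns and check for collinearity, naming the
# first dependent column
prepare_constraints <- function(constraints, scale = TRUE) {
  constraints <- as.data.frame(constraints)
  if (any(!vapply(constraints, is.numeric, TRUE))) {
    stop("constraint variables must be numeric", call. = FALSE)
  }
  if (anyNA(constraints)) {
    stop("constraint variables must be complete for all included samples", call. = FALSE)
  }
  x <- as.matrix(constraints)
  if (scale) x <- base::scale(x)
  for (j in seq_len(ncol(x))) {
    if (qr(cbind(1, x[, seq_len(j), drop = FALSE]))$rank < j + 1) {
      stop("constraint '", colnames(x)[j],
           "' is collinear with the preceding constraints", call. = FALSE)
    }
  }
  x
}

#' Canonical correspondence analysis constrained by operational parameters
#'
#' Chi-square-standardised correspondence analysis of the community table
#' with a weighted least-squares projection onto the constraint variables
#' (delegated to [vegan::cca()]). Constraints are z-scored by default; the
#' flag is recorded in the result.
#'
#' @param table An [abundance_table()] with positive row and column sums.
#' @param constraints Data frame of numeric explanatory variables, one row
#'   per sample in the table's sample order (or with rownames matching
#'   sample ids).
#' @param scale Z-score the constraints first (default `TRUE`).
#' @return An object of class `cca_fit` with `site_scores`,
#'   `species_scores` (tibbles), `eigenvalues` (constrained, non-increasing),
#'   `total_inertia` and the underlying vegan fit.
#' @export
cca_fit <- function(table, constraints, scale = TRUE) {
  m <- at_values(table)
  if (any(rowSums(m) <= 0)) {
    stop("feature(s) with zero total abundance: ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "), call. = FALSE)
  }
  if (any(colSums(m) <= 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[colSums(m) <= 0], collapse = ", "),
         call. = FALSE)
  }
  constraints <- as.data.frame(constraints)
  if (!is.null(rownames(constraints)) &&
      all(colnames(m) %in% rownames(constraints))) {
    constraints <- constraints[colnames(m), , drop = FALSE]
  } else if (nrow(constraints) != ncol(m)) {
    stop("constraints must have one row per sample", call. = FALSE)
  }
  x <- prepare_constraints(constraints, scale = scale)
  fit <- vegan::cca(X = t(m), Y = x)
  site <- vegan::scores(fit, display = "sites", choices = seq_along(fit$CCA$eig))
  spec <- vegan::scores(fit, display = "species", choices = seq_along(fit$CCA$eig))
  structure(
    list(
      site_scores = dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                                     tibble::as_tibble(site)),
      species_scores = dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                                        tibble::as_tibble(spec)),
      eigenvalues = unname(fit$CCA$eig),
      total_inertia = fit$tot.chi,
      constrained_inertia = sum(fit$CCA$eig),
      scaled_constraints = scale,
      engine = fit
    ),
    class = "cca_fit"
  )
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> %d constrained axes; constrained inertia %.3f of total %.3f (%.1f%%)\n",
              length(x$eigenvalues), x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  invisible(x)
}

#' @method tidy cca_fit
#' @export
tidy.cca_fit <- function(x, ...) x$site_scores

#' @method glance cca_fit
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(total_inertia = x$total_inertia,
                 constrained_inertia = x$constrained_inertia,
                 constrained_fraction = x$constrained_inertia / x$total_inertia,
                 n_axes = length(x$eigenvalues))
}

# extract a samples x axes score matrix from supported ordination objects
ordination_scores <- function(ord) {
  if (inherits(ord, "nmds_ordination")) {
    as.matrix(ord$coordinates[, -1, drop = FALSE])
  } else if (inherits(ord, "cca_fit")) {
    as.matrix(ord$site_scores[, -1, drop = FALSE])
  } else if (is.matrix(ord)) {
    ord
  } else {
    stop("unsupported ordination object", call. = FALSE)
  }
}

#' Fit environmental vectors onto ordination axes
#'
#' For each variable, fits a least-squares arrow onto the ordination (or
#' CCA) axes; `R2` is the squared multiple correlation and `P` comes from
#' permuting the variable's values (seeded; floor `1/(n + 1)`). Each
#' variable is tested marginally, matching per-variable significance
#' tables. Delegated to [vegan::envfit()]; constant variables are reported
#' with `R2 = 0`, `P = 1` and a warning.
#'
#' @param ord An `nmds_ordination`, `cca_fit`, or bare score matrix
#'   (>= 5 samples).
#' @param variables Data frame of numeric variables, one row per sample.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble with one row per variable: arrow components on each
#'   axis (scaled to length `sqrt(R2)`), `R2`, `p`, `n_permutations`.
#' @export
env_fit <- function(ord, variables, n_permutations = 999, seed = 1) {
  sc <- ordination_scores(ord)
  if (nrow(sc) < 5) stop("environmental fitting needs at least 5 samples", call. = FALSE)
  variables <- as.data.frame(variables)
  if (nrow(variables) != nrow(sc)) {
    stop("variables must have one row per ordinated sample", call. = FALSE)
  }
  if (anyNA(variables)) {
    stop("variables must be complete for all included samples (drop incomplete samples first)",
         call. = FALSE)
  }
  is_const <- vapply(variables, function(v) stats::sd(v) == 0, TRUE)
  if (any(is_const)) {
    warning("constant variable(s): ", paste(names(variables)[is_const], collapse = ", "),
            "; reported with R2 = 0, P = 1", call. = FALSE)
  }
  active <- variables[, !is_const, drop = FALSE]
  rows <- list()
  if (ncol(active) > 0) {
    set.seed(seed)
    ef <- vegan::envfit(sc, active, permutations = n_permutations)
    ar <- ef$vectors$arrows
    ar <- matrix(as.numeric(ar), nrow(ar), dimnames = dimnames(ar))
    arrows <- ar * sqrt(ef$vectors$r)
    rows <- c(rows, list(dplyr::bind_cols(
      tibble::tibble(variable = rownames(arrows)),
      tibble::as_tibble(arrows),
      tibble::tibble(R2 = unname(ef$vectors$r), p = unname(ef$vectors$pvals))
    )))
  }
  if (any(is_const)) {
    zero <- matrix(0, sum(is_const), ncol(sc),
                   dimnames = list(NULL, colnames(sc)))
    rows <- c(rows, list(dplyr::bind_cols(
      tibble::tibble(variable = names(variables)[is_const]),
      tibble::as_tibble(zero),
      tibble::tibble(R2 = 0, p = 1)
    )))
  }
  out <- dplyr::bind_rows(rows)
  out$n_permutations <- n_permutations
  out[match(names(variables), out$variable), , drop = FALSE]
}
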