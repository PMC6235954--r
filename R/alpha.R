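#' Hill numbers of orders 0, 1 and 2
#'
#' With \eqn{p_i} the proportions over the positive-abundance features of a
#' sample, the first three Hill numbers are the richness
#' \eqn{H_0 = \#\{p_i > 0\}}, the exponential of the Shannon entropy
#' \eqn{H_1 = \exp(-\sum p_i \log p_i)} and the inverse Simpson
#' concentration \eqn{H_2 = 1/\sum p_i^2}. All three are in units of
#' effective taxa, and \eqn{H_0 \ge H_1 \ge H_2 \ge 1}.
#'
#' @param x Numeric vector of non-negative abundances with at least one
#'   positive entry (one sample column of an abundance table).
#' @return A named list with elements `H0`, `H1`, `H2`.
#' @examples
#' hill_numbers(c(25, 25, 25, 25))  # 4 effective taxa at every order
#' @export
hill_numbers <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative and complete", call. = FALSE)
  x <- x[x > 0]
  if (length(x) == 0) stop("sample has no positive abundance", call. = FALSE)
  p <- x / sum(x)
  list(
    H0 = length(p),
    H1 = exp(-sum(p * log(p))),
    H2 = 1 / sum(p^2)
  )
}

#' Lorenz-curve evenness summary: community organisation and Pareto value
#'
#' Features are ranked by decreasing abundance and the Lorenz curve of
#' cumulative relative abundance against cumulative feature fraction is
#' formed. Community organisation `Co` is 100 times the Gini coefficient —
#' twice the (trapezoid-rule) area between the Lorenz curve and the
#' perfect-evenness diagonal, population form without small-sample
#' correction — so a perfectly even community has `Co = 0`. The `Pareto`
#' value is 100 times the Lorenz ordinate at cumulative feature fraction
#' 0.20, i.e. the percentage of total abundance carried by the 20% most
#' abundant features, linearly interpolated when 0.2 x richness is not an
#' integer.
#'
#' @inheritParams hill_numbers
#' @return A list with `Co` (0-100), `Pareto` (20-100) and `lorenz_points`,
#'   a tibble of the polyline from (0,0) to (1,1) with columns
#'   `feature_fraction` and `abundance_fraction`.
#' @examples
#' lorenz_summary(c(96, 1, 1, 1, 1))$Pareto  # 96: one taxon in the top 20%
#' @export
lorenz_summary <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative and complete", call. = FALSE)
  x <- x[x > 0]
  if (length(x) == 0) stop("sample has no positive abundance", call. = FALSE)
  x <- sort(x, decreasing = TRUE)
  n <- length(x)
  fx <- c(0, seq_len(n) / n)
  fy <- c(0, cumsum(x) / sum(x))
  auc <- sum((fy[-1] + fy[-(n + 1)]) / 2 * diff(fx))
  gini <- 2 * (auc - 0.5)
  pareto <- 100 * stats::approx(fx, fy, xout = 0.20, rule = 2)$y
  list(
    Co = 100 * gini,
    Pareto = pareto,
    lorenz_points = tibble::tibble(feature_fraction = fx, abundance_fraction = fy)
  )
}

#' Per-sample alpha-diversity and evenness table
#'
#' Applies [hill_numbers()] and [lorenz_summary()] to every sample of an
#' abundance table.
#'
#' @param table An [abundance_table()].
#' @return A tibble with one row per sample and columns `sample_id`, `H0`,
#'   `H1`, `H2`, `Co`, `Pareto`.
#' @export
alpha_diversity <- function(table) {
  m <- at_values(table)
  purrr::map_dfr(colnames(m), function(s) {
    h <- hill_numbers(m[, s])
    l <- lorenz_summary(m[, s])
    tibble::tibble(sample_id = s, H0 = h$H0, H1 = h$H1, H2 = h$H2,
                   Co = l$Co, Pareto = l$Pareto)
  })
}

# Spearman rho with average ranks and a two-sided t-approximation P,
# the convention used throughout the package for rank correlations.
spearman_t <- function(a, b) {
  n <- length(a)
  rho <- stats::cor(rank(a), rank(b))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Compare one statistic between two profiling methods
#'
#' Pairs per-sample values of the same statistic obtained with two methods
#' (matched on sample id), computes the Spearman rank correlation between
#' them (average ranks; two-sided P from the t approximation) and a one-way
#' ANOVA P for a difference in means between the methods.
#'
#' @param values_a,values_b Named numeric vectors (names = sample ids) of
#'   the statistic under methods A and B, or tibbles with `sample_id` plus
#'   one value column.
#' @param statistic_name Label for the statistic being compared.
#' @return A one-row tibble: `statistic`, `n`, `spearman_rho`, `spearman_p`,
#'   `group_difference_p`, plus a `pairs` list-column of the matched values.
#' @export
compare_methods <- function(values_a, values_b, statistic_name = "statistic") {
  as_named <- function(v) {
    if (is.data.frame(v)) {
      stopifnot("sample_id" %in% names(v), ncol(v) >= 2)
      val_col <- setdiff(names(v), "sample_id")[1]
      stats::setNames(v[[val_col]], v$sample_id)
    } else {
      if (is.null(names(v))) stop("paired values must be named by sample id", call. = FALSE)
      v
    }
  }
  a <- as_named(values_a)
  b <- as_named(values_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 4) stop("need at least 4 matched sample pairs", call. = FALSE)
  a <- a[shared]; b <- b[shared]
  sp <- spearman_t(a, b)
  stacked <- data.frame(value = c(a, b),
                        method = factor(rep(c("A", "B"), each = length(shared))))
  aov_p <- summary(stats::aov(value ~ method, data = stacked))[[1]][["Pr(>F)"]][1]
  tibble::tibble(
    statistic = statistic_name,
    n = length(shared),
    spearman_rho = sp$rho,
    spearman_p = sp$p,
    group_difference_p = aov_p,
    pairs = list(tibble::tibble(sample_id = shared, value_a = unname(a), value_b = unname(b)))
  )
}

#' Lorenz curves for every sample of a table
#'
#' @param table An [abundance_table()].
#' @return A ggplot of per-sample Lorenz curves with the perfect-evenness
#'   diagonal; the steeper the initial rise, the more the community is
#'   dominated by few taxa.
#' @export
plot_lorenz <- function(table) {
  m <- at_values(table)
  curves <- purrr::map_dfr(colnames(m), function(s) {
    dplyr::mutate(lorenz_summary(m[, s])$lorenz_points, sample_id = s)
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$feature_fraction, .data$abundance_fraction,
                                       group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Cumulative fraction of ranked taxa",
                  y = "Cumulative relative abundance",
                  title = "Lorenz curves") +
    ggplot2::theme_minimal()
}
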