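#' Screen all feature pairs for significant Spearman co-occurrence
#'
#' Tests every unordered pair of features for monotone association across
#' samples: Spearman's rho with average ranks and a two-sided P from the t
#' approximation. An edge is kept when `|rho| > threshold_rho` and
#' `P < threshold_P` (the classical fixed cut; P-values are deliberately
#' not multiplicity-adjusted — see `adjust`). Constant feature rows cannot
#' be ranked and are excluded with a warning.
#'
#' @param table An [abundance_table()] with >= 5 samples and >= 2 features.
#' @param threshold_rho Absolute-correlation threshold (default 0.5).
#' @param threshold_p P-value threshold (default 0.001).
#' @param adjust `"none"` (default, the fixed-cut convention) or `"BH"`
#'   for Benjamini-Hochberg adjusted P-values — a deliberate deviation from
#'   the fixed-cut convention, clearly labelled in the output attribute
#'   `p_adjust`.
#' @return A tibble of edges: `feature_a`, `feature_b`, `rho`, `p`, `sign`
#'   (`"positive"`/`"negative"`), with attributes `nodes` (all testable
#'   feature ids), `threshold_rho`, `threshold_p`, `p_adjust`.
#' @export
correlation_screen <- function(table, threshold_rho = 0.5, threshold_p = 0.001,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- at_values(table)
  if (ncol(m) < 5) stop("need at least 5 samples", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 features", call. = FALSE)
  constant <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    warning("excluding constant feature(s) from correlation screen: ",
            paste(rownames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[!constant, , drop = FALSE]
  }
  n <- ncol(m)
  rk <- t(apply(m, 1, rank))
  rho <- stats::cor(t(rk))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pmat[abs(rho) >= 1 - 1e-12] <- 0
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble::tibble(
    feature_a = rownames(m)[idx[, 1]],
    feature_b = rownames(m)[idx[, 2]],
    rho = rho[idx],
    p = pmat[idx]
  )
  if (adjust == "BH") edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- dplyr::filter(edges, abs(.data$rho) > threshold_rho, .data$p < threshold_p)
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  attr(edges, "nodes") <- rownames(m)
  attr(edges, "threshold_rho") <- threshold_rho
  attr(edges, "threshold_p") <- threshold_p
  attr(edges, "p_adjust") <- adjust
  edges
}

#' Percentage of realised co-occurrence edges
#'
#' @param n_edges Number of realised edges.
#' @param n_nodes Number of nodes.
#' @return `100 * n_edges / choose(n_nodes, 2)`.
#' @examples
#' pct_of_potential(1494, 241)
#' @export
pct_of_potential <- function(n_edges, n_nodes) {
  100 * n_edges / choose(n_nodes, 2)
}

#' Node-level statistics of a co-occurrence network
#'
#' Builds the undirected, unweighted graph implied by a screened edge list
#' (edge signs are ignored for topology) and computes per-node betweenness
#' centrality (Brandes' shortest-path count, via [igraph::betweenness()])
#' and normalised degree `degree/(n_nodes - 1)`. Isolated nodes are kept
#' with zero statistics.
#'
#' @param edges Edge list from [correlation_screen()] (or any tibble with
#'   `feature_a`, `feature_b`).
#' @param nodes Character vector of all node ids; defaults to the screen's
#'   `nodes` attribute.
#' @param normalised_betweenness Also divide betweenness by
#'   `(n-1)(n-2)/2`, the count of ordered pairs a node could mediate;
#'   recommended when comparing networks of different size.
#' @return An object of class `cooccurrence_network` with `node_stats`
#'   (tibble: `feature_id`, `degree`, `normalised_degree`, `betweenness`),
#'   `edges`, and `summary` (tibble: `n_nodes`, `n_significant_edges`,
#'   `pct_of_potential`, `n_isolated_nodes`, `betweenness_normalised`).
#' @export
network_statistics <- function(edges, nodes = attr(edges, "nodes"),
                               normalised_betweenness = FALSE) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$feature_a, edges$feature_b)))
  nodes <- as.character(nodes)
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$feature_a),
                   to = as.character(edges$feature_b)),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  if (n > 0) {
    btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    if (normalised_betweenness && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
    deg <- igraph::degree(g)
    nd <- if (n > 1) deg / (n - 1) else rep(0, n)
  } else {
    btw <- deg <- nd <- numeric(0)
  }
  node_stats <- tibble::tibble(
    feature_id = nodes,
    degree = as.integer(deg[nodes]),
    normalised_degree = unname(nd[nodes]),
    betweenness = unname(btw[nodes])
  )
  structure(
    list(
      node_stats = node_stats,
      edges = edges,
      graph = g,
      summary = tibble::tibble(
        n_nodes = n,
        n_significant_edges = nrow(edges),
        pct_of_potential = if (n >= 2) pct_of_potential(nrow(edges), n) else 0,
        n_isolated_nodes = sum(node_stats$degree == 0),
        betweenness_normalised = normalised_betweenness
      )
    ),
    class = "cooccurrence_network"
  )
}

#' Construct a co-occurrence network from an abundance table
#'
#' Convenience wrapper: [correlation_screen()] followed by
#' [network_statistics()].
#'
#' @inheritParams correlation_screen
#' @inheritParams network_statistics
#' @return A `cooccurrence_network`.
#' @export
cooccurrence_network <- function(table, threshold_rho = 0.5, threshold_p = 0.001,
                                 normalised_betweenness = FALSE, adjust = "none") {
  edges <- correlation_screen(table, threshold_rho, threshold_p, adjust = adjust)
  network_statistics(edges, normalised_betweenness = normalised_betweenness)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (%.1f%% of potential), %d isolated\n",
              s$n_nodes, s$n_significant_edges, s$pct_of_potential, s$n_isolated_nodes))
  invisible(x)
}

#' @method tidy cooccurrence_network
#' @export
tidy.cooccurrence_network <- function(x, ...) x$node_stats

#' @method glance cooccurrence_network
#' @export
glance.cooccurrence_network <- function(x, ...) x$summary

#' Compare node-level statistics of two co-occurrence networks
#'
#' Two-sample Mann-Whitney (Wilcoxon rank-sum) tests on node-level
#' betweenness and normalised degree, plus summary deltas. When the two
#' networks differ in node count, compare normalised betweenness
#' (`normalised_betweenness = TRUE` in [network_statistics()]).
#'
#' @param network_a,network_b `cooccurrence_network` objects.
#' @return A list with `tests` (tibble: statistic, W, p, medians) and
#'   `summary` (per-network summary rows plus derived fractions).
#' @export
compare_networks <- function(network_a, network_b) {
  for (nw in list(network_a, network_b)) {
    if (nrow(nw$node_stats) == 0) stop("cannot compare an empty network", call. = FALSE)
  }
  test_one <- function(col, label) {
    va <- network_a$node_stats[[col]]
    vb <- network_b$node_stats[[col]]
    wt <- suppressWarnings(stats::wilcox.test(va, vb))
    tibble::tibble(statistic = label, W = unname(wt$statistic), p = wt$p.value,
                   median_a = stats::median(va), median_b = stats::median(vb))
  }
  frac_pos_btw <- function(nw) mean(nw$node_stats$betweenness > 0)
  frac_isolated <- function(nw) mean(nw$node_stats$degree == 0)
  summary <- dplyr::bind_rows(
    dplyr::mutate(network_a$summary, network = "A",
                  frac_betweenness_positive = frac_pos_btw(network_a),
                  frac_isolated = frac_isolated(network_a)),
    dplyr::mutate(network_b$summary, network = "B",
                  frac_betweenness_positive = frac_pos_btw(network_b),
                  frac_isolated = frac_isolated(network_b))
  )
  list(
    tests = dplyr::bind_rows(
      test_one("betweenness", "betweenness"),
      test_one("normalised_degree", "normalised_degree")
    ),
    summary = summary,
    delta_pct_of_potential =
      network_a$summary$pct_of_potential - network_b$summary$pct_of_potential
  )
}

#' Node-statistic comparison plot for two networks
#'
#' Side-by-side boxplots of betweenness and normalised degree for two
#' networks (e.g. amplicon vs TRFLP).
#'
#' @inheritParams compare_networks
#' @param labels Length-2 labels for the networks.
#' @return A ggplot.
#' @export
plot_network_comparison <- function(network_a, network_b,
                                    labels = c("method A", "method B")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(network_a$node_stats, network = labels[1]),
    dplyr::mutate(network_b$node_stats, network = labels[2])
  ) |>
    tidyr::pivot_longer(c("betweenness", "normalised_degree"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$network, .data$value, fill = .data$network)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Co-occurrence network node statistics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
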