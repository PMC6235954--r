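#' Run the full cross-method comparison workflow
#'
#' Orchestrates the whole pipeline for an OTU table, one or two TRF tables
#' and sample metadata: preprocessing (collation, 1% cutoff, common-scale
#' rescaling), per-sample alpha diversity and evenness with cross-method
#' Spearman/ANOVA comparisons, distance matrices with NMDS and
#' between-method concordance, PERMANOVA over the cluster labels with
#' pairwise tests, CCA plus environmental vector fitting, and signed
#' Spearman co-occurrence networks with a node-statistic comparison. Every
#' randomised stage is seeded from `seed`, so identical inputs and seed
#' give identical results.
#'
#' @param otu OTU [abundance_table()].
#' @param trf_tables Named list of TRF [abundance_table()]s (e.g.
#'   `list(trf_bacterial = ..., trf_archaeal = ...)`).
#' @param metadata Metadata tibble with `sample_id`, a `cluster` column,
#'   and the operational variables used for `env_vars`.
#' @param config A [preprocess_config()].
#' @param metrics Distance metrics to compute (default all five).
#' @param env_vars Metadata variables passed to [env_fit()].
#' @param n_permutations Permutations for PERMANOVA and envfit.
#' @param nmds_restarts Random restarts per NMDS fit.
#' @param threshold_rho,threshold_p Co-occurrence edge thresholds.
#' @param rescale Apply common-scale rescaling during preprocessing.
#' @param seed Integer master seed.
#' @return A list of class `fingerprint_comparison` with per-table and
#'   cross-method blocks (`alpha`, `alpha_comparison`, `beta`,
#'   `concordance`, `permanova`, `envfit`, `network`,
#'   `network_comparison`) plus `config`. Use [summary_json()] or
#'   [write_report()] to serialise.
#' @export
run_full_comparison <- function(otu, trf_tables, metadata,
                                config = preprocess_config(),
                                metrics = "bray_curtis",
                                env_vars = c("pH", "temperature", "TAN", "conductivity"),
                                n_permutations = 9999,
                                nmds_restarts = 20,
                                threshold_rho = 0.5, threshold_p = 0.001,
                                rescale = TRUE,
                                seed = 1) {
  if (!is.list(trf_tables) || length(trf_tables) == 0 || is.null(names(trf_tables))) {
    stop("`trf_tables` must be a non-empty named list", call. = FALSE)
  }
  metadata <- validate_metadata(metadata)
  if (!"cluster" %in% names(metadata)) {
    stop("metadata must carry a `cluster` column for PERMANOVA", call. = FALSE)
  }
  tables <- c(list(otu = otu), trf_tables)

  processed <- purrr::map(tables, function(tb) {
    aligned <- align_tables(tb, metadata)
    list(table = preprocess_table(aligned$table, config = config, rescale = rescale),
         metadata = aligned$metadata)
  })

  per_table <- purrr::imap(processed, function(pr, name) {
    tb <- pr$table
    md <- pr$metadata
    grouping <- stats::setNames(md$cluster, md$sample_id)
    dms <- purrr::map(stats::setNames(metrics, metrics),
                      function(mt) distance_matrix(tb, mt))
    ords <- purrr::map(dms, function(d) nmds(d, n_restarts = nmds_restarts, seed = seed))
    perm <- permanova(dms[[1]], grouping, n_permutations = n_permutations,
                      seed = seed, factor_name = "cluster")
    pperm <- tryCatch(
      pairwise_permanova(dms[[1]], grouping, n_permutations = n_permutations, seed = seed),
      error = function(e) NULL
    )
    vars <- md[, intersect(env_vars, names(md)), drop = FALSE]
    complete <- stats::complete.cases(vars)
    cca <- cca_fit(at_subset(tb, md$sample_id[complete]), vars[complete, , drop = FALSE])
    ef <- env_fit(cca, vars[complete, , drop = FALSE],
                  n_permutations = n_permutations, seed = seed)
    nw <- cooccurrence_network(tb, threshold_rho, threshold_p,
                               normalised_betweenness = TRUE)
    list(name = name, table = tb, metadata = md, alpha = alpha_diversity(tb),
         distances = dms, nmds = ords, permanova = perm,
         pairwise_permanova = pperm, cca = cca, envfit = ef, network = nw)
  })

  # cross-method blocks: OTU vs each TRF table
  stats_cols <- c("H0", "H1", "H2", "Co", "Pareto")
  cross <- purrr::map(names(trf_tables), function(name) {
    a <- per_table[["otu"]]
    b <- per_table[[name]]
    shared <- intersect(a$alpha$sample_id, b$alpha$sample_id)
    alpha_cmp <- purrr::map_dfr(stats_cols, function(stat) {
      compare_methods(stats::setNames(a$alpha[[stat]], a$alpha$sample_id)[shared],
                      stats::setNames(b$alpha[[stat]], b$alpha$sample_id)[shared],
                      statistic_name = stat)
    })
    conc <- purrr::map_dfr(metrics, function(mt) {
      da <- at_subset_dm(a$distances[[mt]], shared)
      db <- at_subset_dm(b$distances[[mt]], shared)
      dplyr::mutate(matrix_concordance(da, db), metric = mt, .before = 1)
    })
    nw_cmp <- compare_networks(a$network, b$network)
    list(pair = c("otu", name), alpha_comparison = alpha_cmp,
         concordance = conc, network_comparison = nw_cmp)
  })
  names(cross) <- names(trf_tables)

  structure(
    list(tables = per_table, cross = cross,
         config = list(cutoff_fraction = config$cutoff_fraction,
                       min_samples_passing = config$min_samples_passing,
                       cutoff_stage = config$cutoff_stage,
                       metrics = metrics, env_vars = env_vars,
                       n_permutations = n_permutations,
                       nmds_restarts = nmds_restarts,
                       threshold_rho = threshold_rho, threshold_p = threshold_p,
                       rescale = rescale, seed = seed)),
    class = "fingerprint_comparison"
  )
}

# subset an abundance table to given samples (order preserved as given)
at_subset <- function(table, sample_ids) {
  at_rewrap(at_values(table)[, sample_ids, drop = FALSE], table)
}

# subset a dist_matrix to given samples
at_subset_dm <- function(dm, sample_ids) {
  structure(unclass(dm)[sample_ids, sample_ids, drop = FALSE],
            class = c("dist_matrix", "matrix"),
            metric = attr(dm, "metric"), sample_ids = sample_ids)
}

#' @export
print.fingerprint_comparison <- function(x, ...) {
  cat("<fingerprint_comparison>\n")
  for (tb in x$tables) {
    cat(sprintf("  %s: %d features x %d samples; PERMANOVA(cluster) R2=%.3f P=%.4g; network %d edges (%.1f%%)\n",
                tb$name, nrow(tb$table), ncol(tb$table),
                tb$permanova$R2, tb$permanova$p,
                tb$network$summary$n_significant_edges,
                tb$network$summary$pct_of_potential))
  }
  invisible(x)
}

#' Machine-readable summary of a comparison run
#'
#' @param x A `fingerprint_comparison`.
#' @return A nested list (schema version 1) that serialises cleanly to
#'   JSON; all numbers are re-derivable from the stage tibbles.
#' @export
summary_json <- function(x) {
  stopifnot(inherits(x, "fingerprint_comparison"))
  list(
    schema_version = 1L,
    config = x$config,
    tables = purrr::map(x$tables, function(tb) {
      list(
        n_features = nrow(tb$table),
        n_samples = ncol(tb$table),
        alpha_mean = as.list(colMeans(tb$alpha[, -1])),
        nmds_stress = purrr::map_dbl(tb$nmds, "stress"),
        permanova = list(pseudo_F = tb$permanova$pseudo_F, R2 = tb$permanova$R2,
                         p = tb$permanova$p),
        pairwise_permanova = if (!is.null(tb$pairwise_permanova)) {
          as.list(tb$pairwise_permanova)
        },
        envfit = as.list(tb$envfit[, c("variable", "R2", "p")]),
        network = as.list(tb$network$summary)
      )
    }),
    cross = purrr::map(x$cross, function(cr) {
      list(
        alpha_comparison = as.list(cr$alpha_comparison[, c("statistic", "spearman_rho",
                                                           "spearman_p", "group_difference_p")]),
        concordance = as.list(cr$concordance),
        network_tests = as.list(cr$network_comparison$tests)
      )
    })
  )
}

#' Write a comparison report bundle to disk
#'
#' Emits per-stage TSVs (alpha diversity, method comparisons, distance
#' matrices, NMDS coordinates, PERMANOVA tables, envfit tables, network
#' edge/node/summary tables) plus a single machine-readable
#' `summary.json`. Deterministic column order throughout.
#'
#' @param x A `fingerprint_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "fingerprint_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (tb in x$tables) {
    tsv(tb$alpha, sprintf("alpha_%s.tsv", tb$name))
    for (mt in names(tb$distances)) {
      m <- unclass(tb$distances[[mt]])
      utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                         file.path(dir, sprintf("dist_%s_%s.tsv", tb$name, mt)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tsv(tb$nmds[[mt]]$coordinates, sprintf("nmds_%s_%s.tsv", tb$name, mt))
    }
    tsv(tidy(tb$permanova), sprintf("permanova_%s.tsv", tb$name))
    if (!is.null(tb$pairwise_permanova)) {
      tsv(tb$pairwise_permanova, sprintf("permanova_pairwise_%s.tsv", tb$name))
    }
    tsv(tb$envfit, sprintf("envfit_%s.tsv", tb$name))
    tsv(tb$network$edges, sprintf("network_edges_%s.tsv", tb$name))
    tsv(tb$network$node_stats, sprintf("network_nodes_%s.tsv", tb$name))
    tsv(tb$network$summary, sprintf("network_summary_%s.tsv", tb$name))
  }
  for (name in names(x$cross)) {
    cr <- x$cross[[name]]
    tsv(dplyr::select(cr$alpha_comparison, -"pairs"),
        sprintf("alpha_comparison_otu_vs_%s.tsv", name))
    tsv(cr$concordance, sprintf("concordance_otu_vs_%s.tsv", name))
    tsv(cr$network_comparison$tests, sprintf("network_tests_otu_vs_%s.tsv", name))
  }
  jsonlite::write_json(summary_json(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
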