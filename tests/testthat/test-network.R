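test_that("correlation screen finds perfect monotone pairs with correct signs", {
  set.seed(41)
  a <- c(1, 3, 5, 7, 9, 11, 13, 15)
  m <- rbind(A = a, B = 2 * a, C = max(a) - a, D = rlnorm(8))
  tb <- make_table(m, feature_ids = rownames(m), sample_ids = paste0("S", 1:8))
  edges <- correlation_screen(tb, 0.5, 0.001)
  ab <- dplyr::filter(edges, feature_a == "A", feature_b == "B")
  expect_equal(ab$rho, 1)
  expect_equal(ab$sign, "positive")
  ac <- dplyr::filter(edges, feature_a == "A", feature_b == "C")
  expect_equal(ac$rho, -1)
  expect_equal(ac$sign, "negative")
  expect_true(all(abs(edges$rho) > 0.5 & edges$p < 0.001))
  expect_error(correlation_screen(make_table(matrix(1:8, 2))), "5 samples")
  const <- make_table(rbind(rep(4, 8), m["A", , drop = FALSE]),
                      feature_ids = c("flat", "A"))
  expect_warning(correlation_screen(const), "flat")
})

test_that("screen is invariant to strictly monotone transforms of a feature", {
  set.seed(42)
  tb <- random_table(8, 12, zero_frac = 0)
  e1 <- correlation_screen(tb, 0.3, 0.05)
  m2 <- unclass(tb)
  m2[3, ] <- exp(m2[3, ] / max(m2[3, ]))  # strictly increasing transform
  e2 <- correlation_screen(make_table(m2), 0.3, 0.05)
  expect_equal(e1$rho, e2$rho, tolerance = 1e-12)
  expect_equal(e1[, c("feature_a", "feature_b", "sign")],
               e2[, c("feature_a", "feature_b", "sign")])
})

test_that("false-edge rate under the null matches the marginal test applied pairwise", {
  set.seed(43)
  n_samp <- 20; n_feat <- 8; thr_rho <- 0.5; thr_p <- 0.05
  # marginal rejection probability for one independent pair
  rej <- replicate(4000, {
    x <- rnorm(n_samp); y <- rnorm(n_samp)
    rho <- cor(rank(x), rank(y))
    t <- rho * sqrt((n_samp - 2) / (1 - rho^2))
    abs(rho) > thr_rho && 2 * pt(-abs(t), n_samp - 2) < thr_p
  })
  expected_edges <- choose(n_feat, 2) * mean(rej)
  edge_counts <- replicate(300, {
    tb <- make_table(matrix(rlnorm(n_feat * n_samp), n_feat, n_samp))
    nrow(correlation_screen(tb, thr_rho, thr_p))
  })
  se <- sqrt(stats::var(edge_counts) / length(edge_counts) +
               choose(n_feat, 2)^2 * stats::var(rej) / length(rej))
  expect_lt(abs(mean(edge_counts) - expected_edges), 4 * se + 0.05)
})

test_that("path and complete graphs give canonical betweenness and degree", {
  edges <- tibble::tibble(feature_a = c("A", "B"), feature_b = c("B", "C"))
  nw <- network_statistics(edges, nodes = c("A", "B", "C"))
  st <- tidy(nw)
  expect_equal(st$betweenness[st$feature_id == "B"], 1)
  expect_equal(st$betweenness[st$feature_id %in% c("A", "C")], c(0, 0))
  expect_equal(st$normalised_degree[st$feature_id == "B"], 1)
  full <- tibble::tibble(
    feature_a = c("A", "A", "A", "B", "B", "C"),
    feature_b = c("B", "C", "D", "C", "D", "D")
  )
  nw4 <- network_statistics(full, nodes = LETTERS[1:4])
  expect_equal(tidy(nw4)$betweenness, rep(0, 4))
  expect_equal(tidy(nw4)$normalised_degree, rep(1, 4))
  expect_equal(glance(nw4)$pct_of_potential, 100)
  # empty graph: all zeros, no error
  empty <- network_statistics(tibble::tibble(feature_a = character(),
                                             feature_b = character()),
                              nodes = c("A", "B"))
  expect_equal(tidy(empty)$betweenness, c(0, 0))
  expect_equal(glance(empty)$n_isolated_nodes, 2)
})

test_that("betweenness equals brute-force shortest-path enumeration on random graphs", {
  set.seed(44)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.35)
    adj <- adj + t(adj)
    ids <- paste0("N", seq_len(n))
    pairs <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    edges <- tibble::tibble(feature_a = ids[pairs[, 1]], feature_b = ids[pairs[, 2]])
    nw <- network_statistics(edges, nodes = ids)
    expect_equal(tidy(nw)$betweenness, bruteforce_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("network comparison is null for self and monotone under edge removal", {
  set.seed(45)
  tb <- random_table(10, 12, zero_frac = 0.2)
  nw <- cooccurrence_network(tb, 0.3, 0.2)
  cmp_self <- compare_networks(nw, nw)
  expect_true(all(cmp_self$tests$p > 0.9))
  expect_equal(cmp_self$delta_pct_of_potential, 0)
  sub_edges <- nw$edges[seq_len(floor(nrow(nw$edges) / 2)), ]
  attr(sub_edges, "nodes") <- attr(nw$edges, "nodes")
  sub <- network_statistics(sub_edges)
  expect_gt(nw$summary$pct_of_potential, sub$summary$pct_of_potential)
  expect_error(compare_networks(nw, network_statistics(
    tibble::tibble(feature_a = character(), feature_b = character()),
    nodes = character())), "empty")
})

test_that("pct_of_potential is the realised fraction of all node pairs", {
  expect_equal(pct_of_potential(3, 4), 50)
  expect_equal(pct_of_potential(0, 10), 0)
  set.seed(46)
  n_edges <- 17; ids <- paste0("N", 1:12)
  all_pairs <- utils::combn(ids, 2)
  pick <- sample(ncol(all_pairs), n_edges)
  edges <- tibble::tibble(feature_a = all_pairs[1, pick], feature_b = all_pairs[2, pick])
  nw <- network_statistics(edges, nodes = ids)
  # invariant to node relabelling
  relab <- setNames(sample(LETTERS[1:12]), ids)
  edges2 <- tibble::tibble(feature_a = unname(relab[edges$feature_a]),
                           feature_b = unname(relab[edges$feature_b]))
  nw2 <- network_statistics(edges2, nodes = unname(relab))
  expect_equal(nw$summary$pct_of_potential, nw2$summary$pct_of_potential)
  expect_true(nw$summary$pct_of_potential >= 0 && nw$summary$pct_of_potential <= 100)
})
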