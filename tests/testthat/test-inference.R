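euclid_dm <- function(points, ids = paste0("S", seq_len(nrow(points)))) {
  d <- as.matrix(dist(points))
  dimnames(d) <- list(ids, ids)
  structure(d, class = c("dist_matrix", "matrix"),
            metric = "bray_curtis", sample_ids = ids)
}

test_that("PERMANOVA rejects degenerate designs and floors P at maximal separation", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(16, 0), 8), matrix(rnorm(16, 50), 8))
  dm <- euclid_dm(pts)
  g <- rep(c("a", "b"), each = 8)
  expect_error(permanova(dm, rep("a", 16)), "2 groups")
  expect_error(permanova(dm, c(rep("a", 15), "b")), "singleton")
  fit <- permanova(dm, g, n_permutations = 199, seed = 4)
  expect_equal(fit$p, 1 / (199 + 1))
  expect_gt(fit$pseudo_F, 10)
  # R2 components sum to one
  expect_equal(sum(tidy(fit)$R2[1:2]), 1)
  expect_equal(tidy(fit)$R2[3], 1)
})

test_that("PERMANOVA warns on all-equal distances and reports P = 1", {
  d <- matrix(1, 6, 6); diag(d) <- 0
  dimnames(d) <- list(paste0("S", 1:6), paste0("S", 1:6))
  dm <- structure(d, class = c("dist_matrix", "matrix"),
                  metric = "bray_curtis", sample_ids = rownames(d))
  expect_warning(fit <- permanova(dm, rep(c("a", "b"), 3), n_permutations = 99),
                 "uninformative")
  expect_equal(fit$p, 1)
})

test_that("pseudo-F matches the brute-force group-mean decomposition on Euclidean embeddings", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(6:8, 1)
    pts <- matrix(rnorm(n * 2), n)
    g <- sample(rep(c("a", "b"), length.out = n))
    if (min(table(g)) < 2) next
    dm <- euclid_dm(pts)
    fit <- permanova(dm, g, n_permutations = 99, seed = i)
    expect_equal(fit$pseudo_F, bruteforce_pseudo_f(dist(pts), g), tolerance = 1e-8)
  }
})

test_that("permutation P equals exhaustive enumeration for small n", {
  set.seed(34)
  n <- 6
  pts <- matrix(rnorm(n * 2), n)
  g <- rep(c("a", "b"), each = 3)
  dm <- euclid_dm(pts)
  # all n! label permutations, passed explicitly
  perms <- do.call(rbind, combinat_perms(n))
  fit <- permanova(dm, g, n_permutations = perms, seed = 1)
  # exact enumeration with the same (1 + #exceed)/(1 + N) convention,
  # using the brute-force F oracle
  f_obs <- bruteforce_pseudo_f(dist(pts), g)
  f_perm <- apply(perms, 1, function(ix) bruteforce_pseudo_f(dist(pts), g[ix]))
  p_exact <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(fit$p, p_exact, tolerance = 2 / nrow(perms))
})

test_that("pairwise PERMANOVA separates synthetic clusters and respects Bonferroni", {
  set.seed(35)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  pts <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(16, 0, 0.6), 8), 2, centers[k, ], "+")
  }))
  g <- rep(1:4, each = 8)
  dm <- euclid_dm(pts)
  pw <- pairwise_permanova(dm, g, n_permutations = 999, seed = 3)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_adjusted >= pw$p))
  expect_true(all(pw$p_adjusted < 0.05))
  expect_error(pairwise_permanova(dm, rep(1:2, 16)), "3 groups")
})

test_that("CCA separates a binary community split and flags collinear constraints", {
  set.seed(36)
  blockA <- matrix(rpois(5 * 6, 20), 5, 6)
  blockB <- matrix(rpois(5 * 6, 20), 5, 6)
  m <- rbind(cbind(blockA, matrix(rpois(30, 1), 5)),
             cbind(matrix(rpois(30, 1), 5), blockB))
  tb <- make_table(m, sample_ids = paste0("S", 1:12))
  split <- data.frame(split = rep(c(0, 1), each = 6))
  fit <- cca_fit(tb, split)
  expect_gt(fit$eigenvalues[1], 0)
  ax1 <- fit$site_scores[[2]]
  expect_true(max(ax1[1:6]) < min(ax1[7:12]) || min(ax1[1:6]) > max(ax1[7:12]))
  # constraint carrying no community signal explains almost nothing
  noise <- data.frame(x = rnorm(12))
  fit_noise <- cca_fit(tb, noise)
  expect_lt(fit_noise$constrained_inertia / fit_noise$total_inertia,
            fit$constrained_inertia / fit$total_inertia)
  dup <- data.frame(a = split$split, b = split$split * 2)
  expect_error(cca_fit(tb, dup), "collinear")
  expect_error(cca_fit(tb, data.frame(a = c(NA, rnorm(11)))), "complete")
})

test_that("envfit recovers a perfectly aligned variable and handles constants", {
  set.seed(37)
  sc <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("NMDS1", "NMDS2")))
  vars <- data.frame(aligned = sc[, 1], noise = rnorm(15))
  ef <- env_fit(sc, vars, n_permutations = 199, seed = 5)
  expect_equal(ef$R2[ef$variable == "aligned"], 1, tolerance = 1e-8)
  expect_equal(ef$p[ef$variable == "aligned"], 1 / (199 + 1))
  expect_warning(
    ef2 <- env_fit(sc, data.frame(flat = rep(3, 15), ok = rnorm(15)),
                   n_permutations = 99),
    "constant"
  )
  expect_equal(ef2$R2[ef2$variable == "flat"], 0)
  expect_equal(ef2$p[ef2$variable == "flat"], 1)
  # arrow length is sqrt(R2)
  arrow_len <- sqrt(ef$NMDS1^2 + ef$NMDS2^2)
  expect_equal(arrow_len, sqrt(ef$R2), tolerance = 1e-8)
  expect_error(env_fit(sc[1:4, ], vars[1:4, ]), "5 samples")
})
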