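metrics_all <- c("bray_curtis", "chao", "jaccard", "kulczynski", "mountford")

test_that("all metrics return 0 for identical samples and obey hand values", {
  tb <- make_table(matrix(c(6, 2, 1, 6, 2, 1), 3), sample_ids = c("A", "B"))
  for (mt in metrics_all) {
    d <- distance_matrix(tb, mt)
    expect_equal(unclass(d)["A", "B"], 0, tolerance = 1e-9, label = mt)
    expect_equal(attr(d, "metric"), mt)
  }
  disjoint <- make_table(matrix(c(6, 2, 0, 0, 0, 0, 3, 1), 4), sample_ids = c("A", "B"))
  expect_equal(unclass(distance_matrix(disjoint, "bray_curtis"))["A", "B"], 1)
  expect_equal(unclass(distance_matrix(disjoint, "mountford"))["A", "B"], 1)
  # hand evaluation: sum|x-y| / sum(x+y) = 8/16
  bc <- make_table(matrix(c(6, 2, 0, 2, 2, 4), 3), sample_ids = c("A", "B"))
  expect_equal(unclass(distance_matrix(bc, "bray_curtis"))["A", "B"], 0.5)
  expect_error(distance_matrix(bc, "euclidean"))
  zero <- make_table(matrix(c(1, 0, 0, 0), 2), sample_ids = c("A", "B"))
  expect_error(distance_matrix(zero, "bray_curtis"), "B")
})

test_that("Mountford root solver agrees with a fine-grid scan and with vegan", {
  # frozen: fine-grid scan of exp(5t)+exp(4t)-1-exp(7t) before the solver was built
  expect_equal(mountford_theta(5, 4, 2), 0.17719105, tolerance = 1e-6)
  expect_equal(mountford_theta(7, 7, 0), 0)
  expect_identical(mountford_theta(7, 4, 4), Inf)
  set.seed(13)
  for (i in 1:60) {
    a <- sample(2:25, 1); b <- sample(2:25, 1)
    j <- sample(1:(min(a, b) - 1), 1)
    theta <- mountford_theta(a, b, j)
    grid <- seq(1e-6, max(1, 2 * theta), length.out = 2e5)
    f <- exp(a * grid) + exp(b * grid) - 1 - exp((a + b - j) * grid)
    cross <- which(diff(sign(f)) != 0)[1]
    step <- grid[2] - grid[1]
    expect_lt(abs(theta - (grid[cross] + grid[cross + 1]) / 2), step)
  }
  # cross-check the scaling convention against vegan's mountford distance
  set.seed(14)
  m <- matrix(rbinom(60, 1, 0.55), 10, 6) + 0
  m[, 1] <- m[, 1] + 1  # no empty samples
  tb <- make_table(m)
  ours <- unclass(distance_matrix(tb, "mountford"))
  veg <- as.matrix(vegan::vegdist(t(unclass(tb)), "mountford", binary = TRUE))
  expect_equal(as.vector(unclass(ours)), as.vector(veg / log(2)), tolerance = 1e-6)
})

test_that("metric axioms hold on random tables and Jaccard dominates Bray-Curtis", {
  set.seed(21)
  for (i in 1:60) {
    tb <- random_table(10, 5)
    bray <- unclass(distance_matrix(tb, "bray_curtis"))
    jac <- unclass(distance_matrix(tb, "jaccard"))
    kul <- unclass(distance_matrix(tb, "kulczynski"))
    mnt <- unclass(distance_matrix(tb, "mountford"))
    for (d in list(bray, jac, kul, mnt)) {
      expect_equal(as.vector(d), as.vector(t(d)))
      expect_equal(unname(diag(d)), rep(0, nrow(d)))
      expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
    }
    expect_true(all(jac >= bray - 1e-12))
    expect_equal(as.vector(jac), as.vector(2 * bray / (1 + bray)), tolerance = 1e-9)
  }
})

test_that("NMDS embeds exact Euclidean configurations at near-zero stress", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  d <- as.matrix(dist(sq))
  dimnames(d) <- list(paste0("S", 1:4), paste0("S", 1:4))
  dm <- structure(d, class = c("dist_matrix", "matrix"),
                  metric = "bray_curtis", sample_ids = rownames(d))
  # a perfect embedding exists, so the stress engine warns it is ~zero
  ord <- suppressWarnings(nmds(dm, k = 2, n_restarts = 5, seed = 1))
  expect_lt(ord$stress, 0.001)
  expect_equal(dim(ord$coordinates), c(4L, 3L))
  expect_error(nmds(dm, k = 3, n_restarts = 2, seed = 1), "smaller")
})

test_that("NMDS is deterministic under a fixed seed and improves with restarts", {
  set.seed(2)
  tb <- random_table(15, 8)
  dm <- distance_matrix(tb, "bray_curtis")
  o1 <- nmds(dm, n_restarts = 1, seed = 9)
  o1b <- nmds(dm, n_restarts = 1, seed = 9)
  expect_identical(o1$stress, o1b$stress)
  expect_identical(o1$coordinates, o1b$coordinates)
  o20 <- nmds(dm, n_restarts = 20, seed = 9)
  expect_lte(o20$stress, o1$stress + 1e-9)
  expect_s3_class(glance(o20), "tbl_df")
})

test_that("matrix concordance reproduces rank-correlation contracts", {
  set.seed(4)
  tb <- random_table(12, 5)
  dm <- distance_matrix(tb, "bray_curtis")
  self <- matrix_concordance(dm, dm)
  expect_equal(self$spearman_rho, 1)
  expect_equal(self$kendall_tau, 1)
  expect_equal(self$n_pairs, choose(5, 2))
  # rank invariance under a monotone transform (element-wise square)
  sq <- structure(unclass(dm)^2, class = c("dist_matrix", "matrix"),
                  metric = "bray_curtis", sample_ids = attr(dm, "sample_ids"))
  expect_equal(matrix_concordance(dm, sq)$spearman_rho, 1)
  # fixed 5-sample pair against the brute-force rank-then-Pearson oracle
  tb2 <- random_table(12, 5)
  dm2 <- distance_matrix(tb2, "bray_curtis")
  cc <- matrix_concordance(dm, dm2)
  va <- as.vector(as.dist(unclass(dm))); vb <- as.vector(as.dist(unclass(dm2)))
  expect_equal(cc$spearman_rho, cor(rank(va), rank(vb)), tolerance = 1e-12)
  # simultaneous reordering of both matrices leaves concordance unchanged
  perm <- c(3, 1, 5, 2, 4)
  reord <- function(d) {
    ids <- attr(d, "sample_ids")[perm]
    structure(unclass(d)[perm, perm], class = c("dist_matrix", "matrix"),
              metric = attr(d, "metric"), sample_ids = ids)
  }
  cc2 <- matrix_concordance(reord(dm), reord(dm2))
  expect_equal(cc2$spearman_rho, cc$spearman_rho, tolerance = 1e-12)
  expect_equal(cc2$kendall_tau, cc$kendall_tau, tolerance = 1e-12)
  bad <- structure(unclass(dm2), class = c("dist_matrix", "matrix"),
                   metric = "bray_curtis", sample_ids = paste0("X", 1:5))
  expect_error(matrix_concordance(dm, bad), "same samples")
})
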