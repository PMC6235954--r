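# shared fixture builders: everything is generated in code at test time

make_table <- function(values, feature_ids = NULL, sample_ids = NULL, kind = "otu") {
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(feature_ids, sample_ids)
  abundance_table(values, kind = kind)
}

# random community table: n_features x n_samples log-normal abundances
random_table <- function(n_features = 12, n_samples = 6, zero_frac = 0.3) {
  m <- matrix(rlnorm(n_features * n_samples, 0, 1.5), n_features, n_samples)
  m[runif(length(m)) < zero_frac] <- 0
  # guarantee positive column and row sums
  m[1, ] <- m[1, ] + 1
  make_table(m)
}

# a compact, quick-to-generate study configuration for pipeline tests
small_config <- function(seed = 1, ...) {
  synthetic_config(
    n_plants = 8, n_samples = 10, n_clusters = 4,
    cluster_weights = c(2, 2, 2, 2),
    cluster_pH = c(7.2, 7.5, 7.8, 8.2),
    cluster_temperature = c(34, 36, 38, 52),
    n_otus = 150,
    trf_length_grid = seq(60, 300, by = 3),
    depth_meanlog = log(5000), depth_sdlog = 0.3,
    seed = seed, ...
  )
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force Euclidean-embedding PERMANOVA F: explicit group-mean sums of
# squares computed from squared distances (independent of vegan)
bruteforce_pseudo_f <- function(d, g) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in unique(g)) {
    idx <- which(g == lv)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  k <- length(unique(g))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# brute-force betweenness: enumerate all shortest paths between node pairs
bruteforce_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  # all shortest paths via BFS path enumeration
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      # BFS distances from s
      dist <- rep(Inf, n); dist[s] <- 0
      frontier <- s
      while (length(frontier) > 0) {
        nxt <- integer(0)
        for (v in frontier) {
          nb <- which(adj[v, ] > 0)
          new <- nb[dist[nb] == Inf]
          dist[new] <- dist[v] + 1
          nxt <- c(nxt, new)
        }
        frontier <- unique(nxt)
      }
      if (!is.finite(dist[t])) next
      # count shortest paths and per-node pass-throughs by DFS over DAG
      n_paths <- 0
      passes <- numeric(n)
      stack <- list(s)
      paths <- list(c(s))
      while (length(paths) > 0) {
        pth <- paths[[1]]; paths[[1]] <- NULL
        v <- pth[length(pth)]
        if (v == t) {
          n_paths <- n_paths + 1
          inner <- setdiff(pth, c(s, t))
          passes[inner] <- passes[inner] + 1
          next
        }
        for (w in which(adj[v, ] > 0)) {
          if (dist[w] == dist[v] + 1) paths[[length(paths) + 1]] <- c(pth, w)
        }
      }
      if (n_paths > 0) btw <- btw + passes / n_paths
    }
  }
  btw
}

# all permutations of 1..n (n small), as integer vectors
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (i in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = i)
  }
  out
}

# like small_config but with a 1-nt fragment grid, so the baseline
# OTU -> TRF map is close to one-to-one and collision-rate experiments
# start from nearly full resolution
fine_map_config <- function(seed = 1) {
  synthetic_config(
    n_plants = 8, n_samples = 10, n_clusters = 4,
    cluster_weights = c(2, 2, 2, 2),
    cluster_pH = c(7.2, 7.5, 7.8, 8.2),
    cluster_temperature = c(34, 36, 38, 52),
    n_otus = 150,
    trf_length_grid = seq(60, 500, by = 1),
    depth_meanlog = log(5000), depth_sdlog = 0.3,
    seed = seed
  )
}
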