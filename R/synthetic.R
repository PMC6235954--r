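#' Configuration for the synthetic paired-profile generator
#'
#' The defaults emulate a survey of full-scale anaerobic digesters profiled
#' in parallel with amplicon sequencing and TRFLP: 33 samples from 25
#' plants falling into 4 clusters driven by pH/temperature gradients, a
#' log-normal rank-abundance structure over 1,200 OTUs, sequencing depth
#' log-normal around 40,000 reads, a many-to-one OTU-to-fragment-length
#' map on a nucleotide grid with Gaussian sizing noise (sd 0.39 nt), a
#' TRFLP detection floor of 0.5% relative abundance, and a low-richness
#' archaeal profile of about 4 TRFs per sample from a pool of 12.
#'
#' @param n_plants Number of plants (default 25).
#' @param n_samples Number of samples (default 33); the surplus over
#'   `n_plants` becomes repeat samples of the first plants.
#' @param n_clusters Number of sample clusters (default 4); must not exceed
#'   `n_plants`.
#' @param cluster_weights Relative cluster sizes (plants per cluster).
#' @param cluster_pH,cluster_temperature Cluster centroids of pH and
#'   temperature (deg C); their spread is what separates the clusters.
#' @param n_otus Size of the OTU pool (default 1200).
#' @param lognormal_shape SD of per-OTU base log abundance (rank-abundance
#'   spread; default 1.2).
#' @param gradient_coefficients Named vector, SD of per-OTU response
#'   loadings on the standardised pH and temperature gradients.
#' @param sample_noise_sd SD of per-sample log-abundance noise.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters
#'   (default `log(40000)`, 0.4).
#' @param trf_length_grid Candidate fragment lengths (nt) each OTU is
#'   mapped onto, uniformly at random; a grid smaller than `n_otus`
#'   guarantees many-to-one collisions.
#' @param size_noise_sd Gaussian fragment-sizing noise in nt (default
#'   0.39) applied before binning to the 1-nt grid.
#' @param trf_detection_floor Within-sample relative abundance below which
#'   a TRF peak goes undetected (default 0.005; deliberately
#'   below the 1% analysis cutoff, since fingerprinting detects peaks the
#'   cutoff later removes).
#' @param n_archaeal_trfs Archaeal TRF pool size (default 12).
#' @param archaeal_richness Mean archaeal TRFs per sample (default 4).
#' @param seed Integer master seed; every stage derives its own stream from
#'   it, so e.g. changing archaeal parameters does not perturb the
#'   bacterial draws.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plants = 25,
                             n_samples = 33,
                             n_clusters = 4,
                             cluster_weights = c(4, 3, 10, 8),
                             cluster_pH = c(7.15, 7.50, 7.85, 8.20),
                             cluster_temperature = c(33, 36, 38, 52),
                             n_otus = 1200,
                             lognormal_shape = 1.2,
                             gradient_coefficients = c(pH = 2, temperature = 2),
                             sample_noise_sd = 0.8,
                             depth_meanlog = log(40000),
                             depth_sdlog = 0.4,
                             trf_length_grid = seq(60, 498, by = 6),
                             size_noise_sd = 0.39,
                             trf_detection_floor = 0.005,
                             n_archaeal_trfs = 12,
                             archaeal_richness = 4,
                             seed = 1) {
  stopifnot(n_clusters <= n_plants, n_samples >= n_plants,
            size_noise_sd >= 0,
            trf_detection_floor >= 0, trf_detection_floor < 1,
            length(cluster_pH) == n_clusters,
            length(cluster_temperature) == n_clusters,
            length(cluster_weights) == n_clusters,
            archaeal_richness >= 1, n_archaeal_trfs >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# deterministic per-stage sub-seed below 2^31
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 16807) %% 2147483647
}

# allocate n_plants plants to clusters proportionally to weights, >= 1 each
allocate_clusters <- function(n_plants, weights) {
  k <- length(weights)
  sizes <- pmax(1, floor(weights / sum(weights) * n_plants))
  while (sum(sizes) > n_plants) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  while (sum(sizes) < n_plants) sizes[which.max(weights / sizes)] <-
      sizes[which.max(weights / sizes)] + 1
  rep(seq_len(k), times = sizes)
}

#' Generate a paired OTU / TRFLP dataset with known ground truth
#'
#' Draws a metadata table, an OTU count table, a bacterial TRF table
#' obtained by pushing the OTU table through a many-to-one
#' fragment-length map with sizing noise and a detection floor, and an
#' independent low-richness archaeal TRF table. Cluster centroids are
#' log-scale OTU profiles shifted along the pH and temperature gradients;
#' per-sample abundances are multinomial draws at a log-normal sequencing
#' depth. Fully deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `otu`, `trf_bacterial`, `trf_archaeal`
#'   ([abundance_table()]s), `metadata` (tibble, including derived FAN and
#'   the true `cluster` label), and `truth` (list: `cluster`, `pH`,
#'   `temperature`, `otu_trf_map` tibble, `collision_counts`,
#'   `gradient_coefficients`).
#' @export
generate_paired_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config

  # --- design: plants, repeat samples, clusters -------------------------
  plant_cluster <- allocate_clusters(cfg$n_plants, cfg$cluster_weights)
  plant_ids <- sprintf("P%02d", seq_len(cfg$n_plants))
  extra <- cfg$n_samples - cfg$n_plants
  sample_plant <- c(seq_len(cfg$n_plants),
                    rep_len(seq_len(cfg$n_plants), extra))
  rep_tag <- stats::ave(sample_plant, sample_plant, FUN = seq_along)
  sample_ids <- paste0(plant_ids[sample_plant],
                       ifelse(rep_tag == 1, "", letters[rep_tag]))
  cluster <- plant_cluster[sample_plant]
  ns <- cfg$n_samples

  # --- metadata ---------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 1))
  pH <- pmin(8.6, pmax(6.9, cfg$cluster_pH[cluster] + stats::rnorm(ns, 0, 0.12)))
  temperature <- pmax(25, cfg$cluster_temperature[cluster] + stats::rnorm(ns, 0, 1.5))
  tan_meanlog <- c(5.8, 6.4, 7.3, 7.7)[pmin(cluster, 4)]
  TAN <- stats::rlnorm(ns, tan_meanlog, 0.45)
  conductivity <- stats::rlnorm(ns, c(2.0, 2.2, 2.9, 3.2)[pmin(cluster, 4)], 0.25)
  metadata <- tibble::tibble(
    sample_id = sample_ids,
    plant = plant_ids[sample_plant],
    cluster = cluster,
    pH = pH,
    temperature = temperature,
    TAN = TAN,
    FAN = free_ammonia(TAN, pH, temperature),
    conductivity = conductivity,
    TS = stats::runif(ns, 2, 12),
    VS = stats::runif(ns, 1, 8),
    total_VFA = stats::rlnorm(ns, 0, 1),
    OLR = stats::runif(ns, 1.5, 13.8),
    SRT = stats::runif(ns, 18, 124),
    biogas_rate = stats::runif(ns, 1.1, 7.5)
  )

  # --- OTU table: gradient-structured log-normal communities ------------
  set.seed(stage_seed(cfg$seed, 2))
  z_ph <- as.vector(base::scale(pH))
  z_tmp <- as.vector(base::scale(temperature))
  base_log <- stats::rnorm(cfg$n_otus, 0, cfg$lognormal_shape)
  load_ph <- stats::rnorm(cfg$n_otus, 0, cfg$gradient_coefficients[["pH"]])
  load_tmp <- stats::rnorm(cfg$n_otus, 0, cfg$gradient_coefficients[["temperature"]])
  depth <- pmax(1000, round(stats::rlnorm(ns, cfg$depth_meanlog, cfg$depth_sdlog)))
  counts <- matrix(0L, cfg$n_otus, ns)
  for (s in seq_len(ns)) {
    eta <- base_log + load_ph * z_ph[s] + load_tmp * z_tmp[s] +
      stats::rnorm(cfg$n_otus, 0, cfg$sample_noise_sd)
    p <- exp(eta - max(eta))
    counts[, s] <- stats::rmultinom(1, depth[s], p / sum(p))
  }
  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  dimnames(counts) <- list(otu_ids, sample_ids)
  keep <- rowSums(counts) > 0
  otu <- abundance_table(counts[keep, , drop = FALSE], kind = "otu")

  # --- bacterial TRF table via the OTU -> fragment-length map -----------
  set.seed(stage_seed(cfg$seed, 3))
  frag_len <- cfg$trf_length_grid[sample.int(length(cfg$trf_length_grid),
                                             cfg$n_otus, replace = TRUE)]
  names(frag_len) <- otu_ids
  trf_bacterial <- aggregate_to_trf(
    at_values(otu), frag_len[rownames(otu)],
    size_noise_sd = cfg$size_noise_sd,
    detection_floor = cfg$trf_detection_floor
  )

  # --- archaeal TRF table: small independent pool, temperature affinity -
  set.seed(stage_seed(cfg$seed, 4))
  arch_len <- sort(sample(seq(70, 350), cfg$n_archaeal_trfs))
  arch_ids <- format_trf_length(arch_len)
  affinity <- stats::rnorm(cfg$n_archaeal_trfs, 0, 1)
  arch <- matrix(0, cfg$n_archaeal_trfs, ns, dimnames = list(arch_ids, sample_ids))
  for (s in seq_len(ns)) {
    r <- max(1, min(cfg$n_archaeal_trfs, stats::rpois(1, cfg$archaeal_richness)))
    w <- exp(affinity * z_tmp[s])
    picked <- sample.int(cfg$n_archaeal_trfs, r, prob = w / sum(w))
    props <- stats::rlnorm(r, 0, 0.8)
    arch[picked, s] <- as.vector(stats::rmultinom(1, 10000, props / sum(props)))
  }
  arch <- arch[rowSums(arch) > 0, , drop = FALSE]
  trf_archaeal <- abundance_table(arch, kind = "trf_archaeal")

  truth <- list(
    cluster = stats::setNames(cluster, sample_ids),
    pH = stats::setNames(pH, sample_ids),
    temperature = stats::setNames(temperature, sample_ids),
    otu_trf_map = tibble::tibble(otu_id = otu_ids, fragment_length = unname(frag_len)),
    collision_counts = table(frag_len),
    gradient_coefficients = cfg$gradient_coefficients,
    seed = cfg$seed
  )
  list(otu = otu, trf_bacterial = trf_bacterial, trf_archaeal = trf_archaeal,
       metadata = metadata, truth = truth)
}

# Aggregate an OTU count matrix to a TRF table: jitter each OTU x sample
# measurement by Gaussian sizing noise, bin to the 1-nt grid, sum counts
# per bin, zero peaks below the within-sample detection floor, then
# renormalise each column back to its pre-threshold total.
aggregate_to_trf <- function(counts, frag_len, size_noise_sd = 0,
                             detection_floor = 0, kind = "trf_bacterial") {
  ns <- ncol(counts)
  no <- nrow(counts)
  if (size_noise_sd > 0) {
    obs <- matrix(round(frag_len + stats::rnorm(no * ns, 0, size_noise_sd)), no, ns)
  } else {
    obs <- matrix(rep(round(frag_len), ns), no, ns)
  }
  bins <- sort(unique(as.vector(obs)))
  trf <- matrix(0, length(bins), ns,
                dimnames = list(format_trf_length(bins), colnames(counts)))
  for (s in seq_len(ns)) {
    agg <- tapply(counts[, s], factor(obs[, s], levels = bins), sum, default = 0)
    trf[, s] <- agg
  }
  if (detection_floor > 0) {
    totals <- colSums(trf)
    rel <- sweep(trf, 2, totals, "/")
    trf[rel < detection_floor] <- 0
    new_tot <- colSums(trf)
    if (any(new_tot <= 0)) stop("detection floor removed every TRF in a sample", call. = FALSE)
    trf <- sweep(trf, 2, totals / new_tot, "*")
  }
  trf <- trf[rowSums(trf) > 0, , drop = FALSE]
  abundance_table(trf, kind = kind)
}

#' Degrade an OTU table's taxonomic resolution by fragment-length collision
#'
#' Re-maps a fraction `collision_rate` of OTUs onto fragment lengths that
#' other OTUs already occupy, then aggregates counts by length with no
#' sizing noise or detection floor, so column sums are conserved exactly.
#' Models the many-to-one information loss of fingerprinting: the larger
#' the collision rate, the poorer the TRF table's ability to mirror the
#' OTU table's beta-diversity structure.
#'
#' @param otu_table An OTU [abundance_table()].
#' @param truth Truth record from [generate_paired_dataset()] (uses
#'   `otu_trf_map`).
#' @param collision_rate Fraction of OTUs to re-map, in `[0, 1]`.
#' @param seed Integer seed for the choice of re-mapped OTUs and targets.
#' @return A `trf_bacterial` [abundance_table()].
#' @export
degrade_resolution <- function(otu_table, truth, collision_rate, seed = 1) {
  stopifnot(collision_rate >= 0, collision_rate <= 1)
  m <- at_values(otu_table)
  map <- truth$otu_trf_map
  frag <- stats::setNames(map$fragment_length, map$otu_id)[rownames(m)]
  if (anyNA(frag)) stop("truth map does not cover every OTU in the table", call. = FALSE)
  n_move <- round(collision_rate * length(frag))
  if (n_move > 0) {
    set.seed(seed)
    move <- sample(seq_along(frag), n_move)
    pool <- unique(unname(frag[-move]))
    if (length(pool) == 0) pool <- unname(frag[1])
    frag[move] <- pool[sample.int(length(pool), n_move, replace = TRUE)]
  }
  aggregate_to_trf(m, frag, size_noise_sd = 0, detection_floor = 0)
}
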