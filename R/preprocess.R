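#' Preprocessing configuration
#'
#' Bundles the knobs of [preprocess_table()]: the relative-abundance cutoff
#' (default 1%, evaluated within samples), the number of samples in which a
#' feature must reach the cutoff to be retained, whether the cutoff is
#' evaluated before or after common-scale rescaling, and the rounding rule
#' used during rescaling.
#'
#' @param cutoff_fraction Relative-abundance threshold in `[0, 1)`;
#'   default `0.01`.
#' @param min_samples_passing Minimum number of samples in which a feature
#'   must reach `cutoff_fraction`; default 1.
#' @param cutoff_stage `"before_rescale"` (default) evaluates the cutoff on
#'   the collated table's proportions and rescales afterwards, which avoids
#'   rounding artifacts at the threshold boundary; `"after_rescale"` applies
#'   the published order literally.
#' @param rounding_rule Only `"half_away_from_zero"` is implemented; the
#'   name records the tie-break used when rescaled proportions land on .5.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cutoff_fraction = 0.01,
                              min_samples_passing = 1L,
                              cutoff_stage = c("before_rescale", "after_rescale"),
                              rounding_rule = "half_away_from_zero") {
  stopifnot(is.numeric(cutoff_fraction), length(cutoff_fraction) == 1,
            cutoff_fraction >= 0, cutoff_fraction < 1)
  min_samples_passing <- as.integer(min_samples_passing)
  stopifnot(min_samples_passing >= 1L)
  rounding_rule <- match.arg(rounding_rule, "half_away_from_zero")
  structure(
    list(cutoff_fraction = cutoff_fraction,
         min_samples_passing = min_samples_passing,
         cutoff_stage = match.arg(cutoff_stage),
         rounding_rule = rounding_rule),
    class = "preprocess_config"
  )
}

# round half away from zero, the documented tie-break for rescaling
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Collate re-sequenced replicate libraries
#'
#' Libraries sequenced from the same sample are collated into a single
#' column by element-wise summation of their counts, preserving total
#' sequencing depth. A per-feature consistency report (the range of
#' within-library relative abundances across group members) is attached as
#' attribute `"consistency"`; it is a diagnostic for the user, not an
#' automated gate.
#'
#' @param table An [abundance_table()].
#' @param replicate_groups Named list mapping each collated sample id to the
#'   character vector of member library ids. Libraries not mentioned pass
#'   through unchanged.
#' @return An [abundance_table()] with one column per group plus all
#'   non-grouped columns, in original first-appearance order.
#' @export
collate_replicate_libraries <- function(table, replicate_groups = list()) {
  m <- at_values(table)
  if (length(replicate_groups) == 0) return(table)
  if (is.null(names(replicate_groups)) || any(names(replicate_groups) == "")) {
    stop("`replicate_groups` must be a named list (collated id -> member libraries)",
         call. = FALSE)
  }
  members <- unlist(replicate_groups, use.names = FALSE)
  unknown <- setdiff(members, colnames(m))
  if (length(unknown) > 0) {
    stop("replicate group references unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("replicate groups must partition libraries; duplicated member(s): ",
         paste(unique(members[duplicated(members)]), collapse = ", "), call. = FALSE)
  }
  consistency <- purrr::imap_dfr(replicate_groups, function(libs, id) {
    sub <- m[, libs, drop = FALSE]
    props <- sweep(sub, 2, colSums(sub), "/")
    tibble::tibble(
      group = id,
      feature_id = rownames(m),
      rel_abund_min = apply(props, 1, min),
      rel_abund_max = apply(props, 1, max)
    )
  })
  # collated column replaces its first member's position
  first_pos <- vapply(replicate_groups, function(libs) min(match(libs, colnames(m))), 1)
  collated <- vapply(replicate_groups, function(libs) rowSums(m[, libs, drop = FALSE]),
                     numeric(nrow(m)))
  keep <- setdiff(colnames(m), members)
  out <- cbind(collated, m[, keep, drop = FALSE])
  colnames(out) <- c(names(replicate_groups), keep)
  ord <- order(c(first_pos, match(keep, colnames(m))))
  out <- out[, ord, drop = FALSE]
  res <- at_rewrap(out, table)
  attr(res, "consistency") <- consistency
  res
}

#' Rescale all samples to a common depth
#'
#' Puts every sample on the common scale of the shallowest library: each
#' column is converted to proportions, multiplied by the minimum column sum
#' and rounded to the nearest integer (ties away from zero). The result is
#' integer-valued and every column sum lies within half a count per feature
#' of the minimum depth.
#'
#' @param table An [abundance_table()] with strictly positive column sums.
#' @return An integer-valued [abundance_table()].
#' @export
common_scale_rescale <- function(table) {
  m <- at_values(table)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  depth <- min(cs)
  out <- round_half_away(sweep(m, 2, cs, "/") * depth)
  at_rewrap(out, table)
}

#' Drop features below a relative-abundance cutoff
#'
#' Retains exactly the features whose within-sample relative abundance
#' reaches `cutoff_fraction` in at least `min_samples_passing` samples
#' (default: >= 1% in at least one sample). Samples are left untouched.
#'
#' @param table An [abundance_table()].
#' @param config A [preprocess_config()], or cutoff fraction shortcut.
#' @return The filtered [abundance_table()]; the number of retained features
#'   is reported via `message()`.
#' @export
abundance_cutoff <- function(table, config = preprocess_config()) {
  if (is.numeric(config)) config <- preprocess_config(cutoff_fraction = config)
  m <- at_values(table)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  props <- sweep(m, 2, cs, "/")
  keep <- rowSums(props >= config$cutoff_fraction) >= config$min_samples_passing
  if (!any(keep)) stop("abundance cutoff removed every feature", call. = FALSE)
  message(sprintf("abundance_cutoff: retained %d of %d features (>=%.3g%% in >=%d sample(s))",
                  sum(keep), nrow(m), 100 * config$cutoff_fraction, config$min_samples_passing))
  at_rewrap(m[keep, , drop = FALSE], table)
}

#' Full preprocessing pipeline
#'
#' Collates replicate libraries, applies the relative-abundance cutoff and
#' rescales all samples to the depth of the shallowest library. By default
#' the cutoff is evaluated on the collated table's proportions before
#' rescaling (relative abundance is invariant to the rescaling except at
#' rounding boundaries); set `cutoff_stage = "after_rescale"` in the config
#' for the literal rescale-then-cutoff order.
#'
#' @inheritParams collate_replicate_libraries
#' @param config A [preprocess_config()].
#' @param rescale Set `FALSE` to skip common-scale rescaling (e.g. for TRF
#'   tables already expressed as relative abundances).
#' @return A preprocessed [abundance_table()].
#' @export
preprocess_table <- function(table, replicate_groups = list(),
                             config = preprocess_config(), rescale = TRUE) {
  out <- collate_replicate_libraries(table, replicate_groups)
  if (config$cutoff_stage == "before_rescale") {
    out <- abundance_cutoff(out, config)
    if (rescale) out <- common_scale_rescale(out)
  } else {
    if (rescale) out <- common_scale_rescale(out)
    out <- abundance_cutoff(out, config)
  }
  out
}

#' Free ammonia from total ammonia nitrogen, pH and temperature
#'
#' Computes free (unionised) ammonia nitrogen from total ammonia nitrogen
#' using the ammonium/ammonia acid-base equilibrium, with the dissociation
#' constant expressed through its van 't Hoff temperature dependence
#' (Anthonisen-type constants 0.09018 and 2729.92):
#' \deqn{FAN = TAN \left(1 + \frac{10^{-pH}}{10^{-(0.09018 + 2729.92/T_K)}}\right)^{-1}}
#' with \eqn{T_K} the temperature in kelvin. The FAN/TAN fraction increases
#' with both pH and temperature.
#'
#' @param TAN Total ammonia nitrogen, mg N/L (>= 0). Vectorised.
#' @param pH pH, in (0, 14).
#' @param temperature_C Temperature in deg C, in (0, 80).
#' @return Free ammonia nitrogen in mg N/L, bounded by `[0, TAN]`.
#' @examples
#' free_ammonia(TAN = 1000, pH = 8.0, temperature_C = 35)
#' @export
free_ammonia <- function(TAN, pH, temperature_C) {
  if (any(is.na(TAN) | is.na(pH) | is.na(temperature_C))) {
    stop("free_ammonia requires complete TAN, pH and temperature", call. = FALSE)
  }
  if (any(TAN < 0)) stop("TAN must be >= 0", call. = FALSE)
  if (any(pH <= 0 | pH >= 14)) stop("pH must lie in (0, 14)", call. = FALSE)
  if (any(temperature_C <= 0 | temperature_C >= 80)) {
    stop("temperature must lie in (0, 80) deg C", call. = FALSE)
  }
  t_k <- temperature_C + 273.15
  pKa <- 0.09018 + 2729.92 / t_k
  TAN / (1 + 10^(-pH) / 10^(-pKa))
}
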