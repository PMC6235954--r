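#' Construct an abundance table
#'
#' An abundance table is the universal currency of the package: a
#' feature-by-sample matrix of non-negative abundances. Features are either
#' OTU labels (`kind = "otu"`) or terminal restriction fragment (TRF) lengths
#' in nucleotides (`kind = "trf_bacterial"` / `"trf_archaeal"`). TRF feature
#' ids are stored as decimal fragment lengths formatted to one decimal,
#' matching capillary-sequencer sizing resolution; TRF identity is string
#' identity after that canonical formatting.
#'
#' @param values Numeric matrix (features x samples) with unique rownames
#'   (feature ids) and colnames (sample ids). A data frame is coerced.
#' @param kind One of `"otu"`, `"trf_bacterial"`, `"trf_archaeal"`.
#' @return A numeric matrix of class `abundance_table` with a `kind`
#'   attribute.
#' @examples
#' m <- matrix(c(10, 0, 5, 5, 0, 20), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
#' abundance_table(m, "otu")
#' @export
abundance_table <- function(values, kind = c("otu", "trf_bacterial", "trf_archaeal")) {
  kind <- match.arg(kind)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values)) stop("abundance values must not be missing", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f) > 0) {
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (startsWith(kind, "trf_")) {
    len <- suppressWarnings(as.numeric(rownames(values)))
    if (anyNA(len) || any(len <= 0)) {
      bad <- rownames(values)[is.na(len) | len <= 0]
      stop("TRF feature ids must be positive fragment lengths (nt); offending id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    rownames(values) <- format_trf_length(len)
    if (anyDuplicated(rownames(values))) {
      stop("TRF fragment lengths collide after one-decimal formatting", call. = FALSE)
    }
  }
  structure(values, class = c("abundance_table", class(values)), kind = kind)
}

#' Canonical one-decimal formatting of TRF fragment lengths
#'
#' @param length_nt Numeric vector of fragment lengths in nucleotides.
#' @return Character vector such as `"87.4"`, `"102.0"`.
#' @export
format_trf_length <- function(length_nt) {
  formatC(length_nt, format = "f", digits = 1)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> kind=%s: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE], 6L))
  if (nrow(x) > 6L || ncol(x) > 8L) cat("...\n")
  invisible(x)
}

#' @rdname abundance_table
#' @param x Object to test.
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

#' Kind of an abundance table
#' @param table An [abundance_table()].
#' @return `"otu"`, `"trf_bacterial"` or `"trf_archaeal"`.
#' @export
table_kind <- function(table) attr(table, "kind")

# Internal: validate and return the bare numeric matrix, preserving attrs.
at_values <- function(table) {
  stopifnot(is_abundance_table(table))
  m <- unclass(table)
  attr(m, "kind") <- NULL
  m
}

# Rebuild an abundance_table from a plain matrix, inheriting kind.
at_rewrap <- function(values, template) {
  abundance_table(values, kind = attr(template, "kind"))
}

#' Long-format view of an abundance table
#'
#' @param x An [abundance_table()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `abundance`.
#' @method as_tibble abundance_table
#' @export
as_tibble.abundance_table <- function(x, ...) {
  m <- at_values(x)
  tibble::tibble(
    feature_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m)
  )
}

#' Read an abundance table from a TSV matrix
#'
#' Expects a tab-separated matrix whose first column holds feature ids and
#' whose header row holds sample ids, the layout in which OTU tables and
#' binned TRF tables are customarily deposited.
#'
#' @param path Path to the TSV file.
#' @inheritParams abundance_table
#' @return A validated [abundance_table()]; input ordering is preserved.
#' @export
read_abundance_table <- function(path, kind = c("otu", "trf_bacterial", "trf_archaeal")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a feature-id column plus at least one sample column", call. = FALSE)
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicated sample id(s) in header: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(feature_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1]]) & trimws(raw[[j + 1]]) != "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row %d (feature '%s'), column '%s': '%s'",
                   bad[1], feature_ids[bad[1]], sample_ids[j], raw[[j + 1]][bad[1]]),
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing abundance at feature '%s', column '%s'",
                   feature_ids[which(is.na(v))[1]], sample_ids[j]), call. = FALSE)
    }
    num[, j] <- v
  }
  abundance_table(num, kind = kind)
}

#' Write an abundance table as TSV
#'
#' Column order follows the table's sample order; the first column is the
#' feature id, so [read_abundance_table()] round-trips integer tables exactly.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  m <- at_values(table)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_numeric_fields <- c(
  "pH", "temperature", "TAN", "FAN", "conductivity", "TS", "VS",
  "total_VFA", "OLR", "SRT", "biogas_rate"
)

#' Read per-sample operational metadata
#'
#' Reads a TSV with one row per sample. Recognised numeric columns are
#' `pH`, `temperature` (deg C), `TAN` and `FAN` (mg N/L), `conductivity`
#' (mS/cm), `TS`, `VS`, `total_VFA` (g COD/L), `OLR` (kg COD/m3/d),
#' `SRT` (d) and `biogas_rate` (m3/m3/d), plus an optional `cluster` label
#' and `plant` id. Missing cells are preserved as `NA`, never zero-filled;
#' each downstream analysis excludes incomplete samples listwise.
#'
#' @param path Path to a tab-separated metadata file with a `sample_id`
#'   column.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(md)
}

#' Validate a metadata table
#'
#' @param md Data frame with a `sample_id` column.
#' @return The validated tibble.
#' @export
validate_metadata <- function(md) {
  md <- tibble::as_tibble(md)
  if (!"sample_id" %in% names(md)) stop("metadata must contain a `sample_id` column", call. = FALSE)
  if (anyNA(md$sample_id)) stop("metadata sample id absent in some row(s)", call. = FALSE)
  md$sample_id <- as.character(md$sample_id)
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup) > 0) stop("duplicated sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (f in intersect(metadata_numeric_fields, names(md))) {
    md[[f]] <- as.numeric(md[[f]])
  }
  if ("pH" %in% names(md)) {
    bad <- !is.na(md$pH) & (md$pH <= 0 | md$pH >= 14)
    if (any(bad)) {
      stop("pH outside (0, 14) for sample(s): ", paste(md$sample_id[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  if ("temperature" %in% names(md)) {
    bad <- !is.na(md$temperature) & md$temperature <= 0
    if (any(bad)) {
      stop("non-positive temperature for sample(s): ", paste(md$sample_id[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  if ("TAN" %in% names(md)) {
    bad <- !is.na(md$TAN) & md$TAN < 0
    if (any(bad)) stop("negative TAN for sample(s): ", paste(md$sample_id[bad], collapse = ", "),
                       call. = FALSE)
  }
  if (all(c("TAN", "FAN") %in% names(md))) {
    bad <- !is.na(md$TAN) & !is.na(md$FAN) & md$FAN > md$TAN + 1e-9
    if (any(bad)) stop("FAN exceeds TAN for sample(s): ", paste(md$sample_id[bad], collapse = ", "),
                       call. = FALSE)
  }
  md
}

#' Align an abundance table with sample metadata
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' table's sample order, and warns about anything dropped. Idempotent.
#'
#' @param table An [abundance_table()].
#' @param metadata A metadata tibble with a `sample_id` column.
#' @return A list with elements `table` and `metadata`, both restricted to
#'   the shared samples in the same order.
#' @export
align_tables <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  keep <- intersect(colnames(table), metadata$sample_id)
  if (length(keep) == 0) stop("no samples shared between table and metadata", call. = FALSE)
  dropped_t <- setdiff(colnames(table), keep)
  dropped_m <- setdiff(metadata$sample_id, keep)
  if (length(dropped_t) > 0) {
    warning("dropping table sample(s) without metadata: ", paste(dropped_t, collapse = ", "),
            call. = FALSE)
  }
  if (length(dropped_m) > 0) {
    warning("dropping metadata sample(s) without abundances: ", paste(dropped_m, collapse = ", "),
            call. = FALSE)
  }
  list(
    table = at_rewrap(at_values(table)[, keep, drop = FALSE], table),
    metadata = metadata[match(keep, metadata$sample_id), , drop = FALSE]
  )
}
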