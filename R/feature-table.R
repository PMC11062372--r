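#' ASV feature tables
#'
#' An `fmt_feature_table` is an ASV-by-sample matrix of non-negative integer
#' counts with unique row (ASV) and column (sample) identifiers. It is the
#' exchange object passed between every stage of the pipeline: rarefaction,
#' diversity, engraftment partitioning and ordination all consume one.
#'
#' @param counts integer matrix, ASVs in rows, samples in columns; must carry
#'   unique, non-empty `rownames` (ASV ids) and `colnames` (sample ids).
#' @return An `fmt_feature_table` object.
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3,
#'             dimnames = list(c("ASV1", "ASV2", "ASV3"), c("S1", "S2")))
#' ft <- feature_table(m)
#' sample_depths(ft)
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) {
    abort_validation("`counts` must be a matrix of ASV x sample counts")
  }
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_validation(sprintf(
      "counts must be non-negative integers; offending cell at ASV '%s', sample '%s'",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1],
      colnames(counts)[bad[1, 2]] %||% bad[1, 2]))
  }
  storage.mode(counts) <- "integer"
  check_unique_ids(rownames(counts), "ASV")
  check_unique_ids(colnames(counts), "sample")
  structure(counts, class = c("fmt_feature_table", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    abort_validation(sprintf("%s identifiers must be present and non-empty", what))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate %s identifier(s): %s", what,
                             paste(unique(dup), collapse = ", ")))
  }
  invisible(ids)
}

abort_validation <- function(msg, class = "fmtgraft_validation_error") {
  rlang::abort(msg, class = class)
}

abort_format <- function(msg) abort_validation(msg, "fmtgraft_format_error")
abort_linkage <- function(msg) abort_validation(msg, "fmtgraft_linkage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fmt_feature_table <- function(x, ...) {
  cat(sprintf("<fmt_feature_table> %d ASVs x %d samples; depth range [%d, %d]\n",
              nrow(x), ncol(x), min(sample_depths(x)), max(sample_depths(x))))
  invisible(x)
}

#' @rdname feature_table
#' @param x an `fmt_feature_table`.
#' @export
asv_ids <- function(x) rownames(x)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x)

#' Per-sample sequencing depth (column sums)
#'
#' @param x an `fmt_feature_table`.
#' @return Named integer vector of per-sample total counts.
#' @export
sample_depths <- function(x) {
  stopifnot(inherits(x, "fmt_feature_table"))
  colSums(unclass(x))
}

#' @importFrom tibble as_tibble
#' @method as_tibble fmt_feature_table
#' @export
as_tibble.fmt_feature_table <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    asv_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    count = as.integer(m)
  )
}

#' Read an ASV feature table from TSV
#'
#' Expects a header row (first column ASV ids, remaining columns sample ids)
#' and non-negative integer cells, the layout of a QIIME2/DADA2 feature-table
#' export. Every malformed cell is rejected with the offending row and column
#' named; a table is either fully valid or not constructed at all.
#'
#' @param path path to a tab-delimited file.
#' @return An [feature_table()] object.
#' @seealso [write_feature_table()] for the inverse; the two are exact
#'   round-trip partners (counts, ids and ordering preserved).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort_format("feature table needs an id column plus >= 1 sample column")
  ids <- as.character(raw[[1]])
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1)
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_format(sprintf(
      "cell at row '%s', column '%s' is not a non-negative integer",
      ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]]))
  }
  rownames(vals) <- ids
  feature_table(vals)
}

#' Write an ASV feature table to TSV
#'
#' @param x an `fmt_feature_table`.
#' @param path output path.
#' @param id_column header name for the ASV id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "asv_id") {
  stopifnot(inherits(x, "fmt_feature_table"))
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Subset a feature table by samples or ASVs
#'
#' @param x an `fmt_feature_table`.
#' @param samples,asvs character vectors of ids to keep (NULL keeps all).
#' @return An `fmt_feature_table`.
#' @export
subset_table <- function(x, samples = NULL, asvs = NULL) {
  stopifnot(inherits(x, "fmt_feature_table"))
  m <- unclass(x)
  if (!is.null(asvs)) {
    missing <- setdiff(asvs, rownames(m))
    if (length(missing) > 0) {
      abort_validation(paste("unknown ASV id(s):", paste(missing, collapse = ", ")))
    }
    m <- m[asvs, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing) > 0) {
      abort_validation(paste("unknown sample id(s):", paste(missing, collapse = ", ")))
    }
    m <- m[, samples, drop = FALSE]
  }
  feature_table(m)
}

#' Read a taxonomy table from TSV
#'
#' One row per ASV; an `asv_id` column plus ranked label columns
#' (kingdom ... genus, optionally species). Only labels for ASVs present in
#' the feature table are meaningful; [collapse_to_genus()] enforces this.
#'
#' @param path path to a tab-delimited file with an `asv_id` column.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"asv_id" %in% names(tax)) abort_format("taxonomy requires an 'asv_id' column")
  check_unique_ids(tax$asv_id, "taxonomy ASV")
  tax
}

#' Collapse ASV counts to genus level
#'
#' Sums member-ASV counts within each genus. ASVs without a genus label (or
#' absent from the taxonomy) are pooled into the reserved `"unassigned"`
#' genus; a real genus named "unassigned" is rejected to keep the pool
#' unambiguous. Per-sample depths are conserved exactly.
#'
#' @param x an `fmt_feature_table`.
#' @param taxonomy tibble with `asv_id` and `genus` columns (see
#'   [read_taxonomy()]).
#' @return An `fmt_feature_table` whose rows are genera.
#' @export
collapse_to_genus <- function(x, taxonomy) {
  stopifnot(inherits(x, "fmt_feature_table"))
  if (!is.data.frame(taxonomy) || nrow(taxonomy) == 0) {
    abort_validation("taxonomy is empty")
  }
  if (!all(c("asv_id", "genus") %in% names(taxonomy))) {
    abort_validation("taxonomy requires 'asv_id' and 'genus' columns")
  }
  unknown <- setdiff(taxonomy$asv_id, asv_ids(x))
  if (length(unknown) > 0) {
    abort_linkage(paste("taxonomy labels ASV(s) absent from the feature table:",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  lab <- taxonomy$genus[match(asv_ids(x), taxonomy$asv_id)]
  lab[is.na(lab) | !nzchar(lab)] <- NA_character_
  if (any(stats::na.omit(lab) == "unassigned")) {
    abort_validation("'unassigned' is a reserved genus label")
  }
  lab[is.na(lab)] <- "unassigned"
  m <- rowsum(unclass(x), group = lab, reorder = TRUE)
  feature_table(m)
}
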