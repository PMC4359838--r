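#' Construct a binary symptom matrix
#'
#' Records x symptoms matrix of clinical manifestations coded 1 (present) /
#' 0 (absent). This is the package's standard data container; all model
#' fitting operates on it.
#'
#' @param values Matrix or data.frame of 0/1 values with column names
#'   (symptom labels). With `strict = FALSE`, rows containing missing cells
#'   are dropped with a message; otherwise missing values are rejected.
#' @param ids Optional character vector of record identifiers.
#' @param strict Reject missing cells (default) or drop incomplete records.
#' @return An object of class `symptom_matrix` with elements `values`
#'   (integer matrix) and `ids`.
#' @export
symptom_matrix <- function(values, ids = NULL, strict = TRUE) {
  X <- as.matrix(values)
  if (is.null(colnames(X)))
    stop_lantree("symptom matrix requires column names", "lantree_schema_error")
  if (anyDuplicated(colnames(X)))
    stop_lantree(sprintf("duplicate symptom column name: '%s'",
                         colnames(X)[duplicated(colnames(X))][1L]),
                 "lantree_schema_error")
  suppressWarnings(storage.mode(X) <- "integer")
  if (anyNA(X)) {
    if (strict) {
      bad <- which(is.na(X), arr.ind = TRUE)
      stop_lantree(sprintf("missing/unparseable value at row %d, column '%s'",
                           bad[1L, 1L], colnames(X)[bad[1L, 2L]]),
                   "lantree_coding_error")
    }
    drop <- unique(which(is.na(X), arr.ind = TRUE)[, 1L])
    message(sprintf("dropping %d incomplete record(s)", length(drop)))
    X <- X[-drop, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[-drop]
  }
  bad <- which(X != 0L & X != 1L, arr.ind = TRUE)
  if (nrow(bad))
    stop_lantree(sprintf("non-binary value %s at row %d, column '%s'",
                         X[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                         colnames(X)[bad[1L, 2L]]),
                 "lantree_coding_error")
  if (nrow(X) < 1L)
    stop_lantree("symptom matrix needs at least one record", "lantree_schema_error")
  structure(list(values = X, ids = ids), class = "symptom_matrix")
}

#' @export
print.symptom_matrix <- function(x, ...) {
  cat(sprintf("symptom_matrix: %d records x %d symptoms\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.symptom_matrix <- function(x) dim(x$values)

#' Read a binary symptom matrix from CSV
#'
#' Expects UTF-8, comma-separated values with a mandatory header row of
#' symptom names and 0/1 body cells. Column order is preserved.
#'
#' @param path Path to a CSV file.
#' @param strict Reject missing cells (default) or drop incomplete records
#'   with a message.
#' @return A [symptom_matrix()].
#' @export
read_symptom_matrix <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop_lantree(sprintf("file not found: %s", path), "lantree_io_error")
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  X <- suppressWarnings(matrix(as.integer(as.matrix(df)), nrow = nrow(df),
                               dimnames = list(NULL, header)))
  symptom_matrix(X, strict = strict)
}

#' Write a symptom matrix to CSV
#'
#' Inverse of [read_symptom_matrix()]: comma-separated, header row, no
#' quoting.
#'
#' @param m A [symptom_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_symptom_matrix <- function(m, path) {
  stopifnot(inherits(m, "symptom_matrix"))
  utils::write.table(m$values, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Symptom frequency table
#'
#' Per-symptom count and proportion of records in which it is present,
#' ordered by descending count (ties keep original column order). This is the
#' frequency-analysis summary used to screen symptoms before modeling.
#'
#' @param m A [symptom_matrix()].
#' @return data.frame with columns `symptom`, `count`, `proportion`.
#' @export
prevalence_table <- function(m) {
  stopifnot(inherits(m, "symptom_matrix"))
  counts <- colSums(m$values)
  ord <- order(-counts, seq_along(counts))
  data.frame(symptom = colnames(m$values)[ord],
             count = as.integer(counts[ord]),
             proportion = unname(counts[ord]) / nrow(m$values),
             row.names = NULL)
}

#' Screen symptoms by frequency
#'
#' Retains exactly the columns present in at least `min_count` records,
#' preserving the original column order. The cutoff has no default: it is a
#' study-level choice that must be stated explicitly.
#'
#' @param m A [symptom_matrix()].
#' @param min_count Minimum number of records in which a symptom must occur.
#' @return A screened [symptom_matrix()].
#' @export
screen_by_frequency <- function(m, min_count) {
  stopifnot(inherits(m, "symptom_matrix"))
  if (missing(min_count) || min_count < 0)
    stop_lantree("min_count must be supplied and >= 0", "lantree_schema_error")
  keep <- colSums(m$values) >= min_count
  if (!any(keep))
    stop_lantree("frequency screen retained zero symptoms", "lantree_empty_selection")
  symptom_matrix(m$values[, keep, drop = FALSE], ids = m$ids)
}
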