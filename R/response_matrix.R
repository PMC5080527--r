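#' Persons-by-items binary response matrix
#'
#' The basic data container of the package: an integer matrix of 0/1 symptom
#' endorsements (one row per person, one column per item) together with unique
#' item labels and optional binary person covariates (e.g. sex, age group)
#' that are used only by the differential-item-functioning tests.
#'
#' Missing values are not representable: rows with missing item responses are
#' expected to be removed at load time (see [read_responses()]), mirroring the
#' complete-records convention of psychiatric survey analyses.
#'
#' @param responses integer or logical matrix (or data frame) of 0/1 values,
#'   persons in rows and items in columns.
#' @param item_labels character vector of unique item names; defaults to the
#'   column names of `responses`.
#' @param covariates optional named list (or data frame) of person-level
#'   vectors, each of length `nrow(responses)` with at most two distinct
#'   non-missing values.
#' @return An object of class `response_matrix`: the validated integer matrix
#'   with `dimnames`, plus a `covariates` attribute.
#' @examples
#' x <- response_matrix(matrix(c(1, 0, 1, 1, 0, 0), 3, 2),
#'                      item_labels = c("sad", "sleep"))
#' n_items(x)
#' @export
response_matrix <- function(responses, item_labels = colnames(responses),
                            covariates = NULL) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses))
    stop_raschval("`responses` must be a matrix or data frame")
  storage.mode(responses) <- "integer"
  bad <- which(!(responses %in% c(0L, 1L)) | is.na(responses))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(responses))
    stop_raschval(sprintf(
      "non-binary response at row %d, column %d (value %s); cells must be 0 or 1",
      i[1], i[2], deparse(responses[bad[1]])))
  }
  if (is.null(item_labels)) item_labels <- paste0("item", seq_len(ncol(responses)))
  item_labels <- as.character(item_labels)
  if (length(item_labels) != ncol(responses))
    stop_raschval("item_labels must align 1:1 with columns")
  if (anyDuplicated(item_labels))
    stop_raschval(sprintf("duplicate item label: %s",
                          item_labels[duplicated(item_labels)][1]))
  dimnames(responses) <- list(rownames(responses), item_labels)
  if (!is.null(covariates)) {
    covariates <- as.list(covariates)
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      stop_raschval("covariates must be named")
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (length(v) != nrow(responses))
        stop_raschval(sprintf("covariate '%s' has length %d, expected %d",
                              nm, length(v), nrow(responses)))
      if (length(unique(v[!is.na(v)])) > 2L)
        stop_raschval(sprintf("covariate '%s' has more than 2 distinct values", nm))
    }
  }
  structure(responses, covariates = covariates, class = c("response_matrix", "matrix"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Binary response matrix: %d persons x %d items\n", nrow(x), ncol(x)))
  cat("Items:", paste(colnames(x), collapse = ", "), "\n")
  p <- colMeans(unclass(x))
  cat("Endorsement rates:",
      paste(sprintf("%s=%.2f", colnames(x), p), collapse = ", "), "\n")
  cv <- attr(x, "covariates")
  if (!is.null(cv)) cat("Covariates:", paste(names(cv), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname response_matrix
#' @param x a `response_matrix`.
#' @export
n_items <- function(x) ncol(x)

#' @rdname response_matrix
#' @export
n_persons <- function(x) nrow(x)

#' @rdname response_matrix
#' @export
covariates <- function(x) attr(x, "covariates")

# plain integer matrix, attributes stripped
resp <- function(x) {
  y <- unclass(x)
  attr(y, "covariates") <- NULL
  y
}

# subset persons and/or items, keeping covariates aligned with persons
subset_responses <- function(x, persons = NULL, items = NULL) {
  m <- resp(x)
  if (is.null(persons)) persons <- seq_len(nrow(m))
  if (is.null(items)) items <- seq_len(ncol(m))
  if (is.character(items)) items <- match(items, colnames(m))
  cv <- attr(x, "covariates")
  if (!is.null(cv)) cv <- lapply(cv, `[`, persons)
  response_matrix(m[persons, items, drop = FALSE],
                  item_labels = colnames(m)[items], covariates = cv)
}

#' Read binary responses from CSV
#'
#' Reads a comma-separated file with a header row and builds a
#' [response_matrix()]. Rows with a missing value in any of the item columns
#' are dropped (listwise deletion) and the number of dropped rows is reported
#' via a message and the `n_dropped` attribute; no imputation is offered.
#'
#' @param path path to a CSV file (UTF-8, header row, values 0/1).
#' @param item_columns character vector of column names holding item
#'   responses.
#' @param covariate_columns optional character vector of columns to carry as
#'   binary person covariates.
#' @return A `response_matrix` with attribute `n_dropped`.
#' @export
read_responses <- function(path, item_columns, covariate_columns = character()) {
  if (!file.exists(path)) stop_raschval(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(item_columns, covariate_columns), names(df))
  if (length(missing_cols))
    stop_raschval(sprintf("columns not present in %s: %s", path,
                          paste(missing_cols, collapse = ", ")))
  items <- df[item_columns]
  complete <- stats::complete.cases(items)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("read_responses: dropped %d of %d rows with missing item responses",
                    n_dropped, nrow(df)))
  df <- df[complete, , drop = FALSE]
  for (cc in item_columns) {
    bad <- which(!(df[[cc]] %in% c(0, 1)))
    if (length(bad))
      stop_raschval(sprintf("non-binary value %s in column '%s', data row %d",
                            deparse(df[[cc]][bad[1]]), cc, bad[1]))
  }
  cov <- if (length(covariate_columns)) as.list(df[covariate_columns]) else NULL
  out <- response_matrix(as.matrix(df[item_columns]),
                         item_labels = item_columns, covariates = cov)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write binary responses to CSV
#'
#' Inverse of [read_responses()]: writes items (and covariates, if any) as a
#' comma-separated file with a header row so that reloading reproduces the
#' object exactly.
#'
#' @param x a `response_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  df <- as.data.frame(resp(x))
  cv <- covariates(x)
  if (!is.null(cv)) df <- cbind(df, as.data.frame(cv))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw disjoint calibration and validation samples
#'
#' Splits a response matrix into two disjoint simple random subsamples of
#' equal size, the first conventionally used to calibrate the scale and the
#' second to verify decisions made on the first.
#'
#' @param data a [response_matrix()].
#' @param n_per_sample persons per subsample; `2 * n_per_sample` must not
#'   exceed the number of persons.
#' @param seed integer seed making the split reproducible.
#' @return A list of class `sample_split` with elements `calibration` and
#'   `validation` (both `response_matrix`) and `seed`.
#' @export
split_samples <- function(data, n_per_sample, seed) {
  n <- n_persons(data)
  if (2 * n_per_sample > n)
    stop_raschval(sprintf(
      "population of %d persons too small: need at least %d for two samples of %d",
      n, 2 * n_per_sample, n_per_sample))
  idx <- with_seed(seed, sample.int(n, 2 * n_per_sample))
  cal <- sort(idx[seq_len(n_per_sample)])
  val <- sort(idx[n_per_sample + seq_len(n_per_sample)])
  structure(list(calibration = subset_responses(data, persons = cal),
                 validation = subset_responses(data, persons = val),
                 calibration_idx = cal, validation_idx = val,
                 seed = seed),
            class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("Sample split (seed %s): calibration n=%d, validation n=%d\n",
              format(x$seed), n_persons(x$calibration), n_persons(x$validation)))
  invisible(x)
}
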