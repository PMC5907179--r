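# l-gram spectrum features and per-column standardization.

#' Count the l-grams of a single sequence
#'
#' Counts every contiguous substring of length `l`, overlapping occurrences
#' included.  A sequence shorter than `l` yields an empty count vector.
#'
#' @param sequence a single sequence string.
#' @param l substring length, >= 1.
#' @return Named integer vector of counts (names are the observed l-mers),
#'   in lexicographic order.
#' @export
count_lgrams <- function(sequence, l) {
  if (length(l) != 1L || is.na(l) || l < 1)
    stop("l must be a positive integer")
  l <- as.integer(l)
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (n < l) return(integer(0))
  starts <- seq_len(n - l + 1L)
  grams <- substring(sequence, starts, starts + l - 1L)
  tab <- table(grams)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' Build a raw l-gram feature matrix for a set of sequences
#'
#' One row per record; columns are the union of l-mers observed across the
#' records, in lexicographic order, so the column order is deterministic.
#' Records shorter than `l` produce all-zero rows.  If no record reaches
#' length `l` the matrix has zero columns.
#'
#' @param records a [sequence_records] object (or named character vector of
#'   sequences).
#' @param l substring length, >= 1.
#' @return An object of class `feature_matrix`: list with `entity_ids`,
#'   `vocabulary`, `values` (counts matrix), `l`, `standardized = FALSE`.
#' @export
build_feature_matrix <- function(records, l) {
  seqs <- unclass(records)
  attributes(seqs) <- list(names = names(seqs))
  if (!length(seqs)) stop("no sequence records supplied")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("records must be named by entity id")
  counts <- lapply(seqs, count_lgrams, l = l)
  vocab <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  values <- matrix(0, nrow = length(seqs), ncol = length(vocab),
                   dimnames = list(names(seqs), vocab))
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    if (length(ci)) values[i, names(ci)] <- ci
  }
  structure(list(entity_ids = names(seqs), vocabulary = vocab,
                 values = values, l = as.integer(l), standardized = FALSE),
            class = "feature_matrix")
}

#' Standardize an l-gram feature matrix column-wise
#'
#' Each column x is transformed to (x - mean(x)) / sd(x).  The standard
#' deviation is the population one (divide by N) by default, matching a
#' formula with no Bessel correction; columns with zero variance are set to
#' all zeros rather than dropped so that column indices stay stable.
#'
#' @param fm a raw `feature_matrix` with at least 2 rows.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The `feature_matrix` with standardized values and
#'   `standardized = TRUE`.
#' @export
standardize_features <- function(fm, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(fm, "feature_matrix"))
  if (isTRUE(fm$standardized))
    stop("feature matrix is already standardized")
  X <- fm$values
  n <- nrow(X)
  if (n < 2L)
    stop("standardization needs at least 2 rows")
  if (ncol(X) > 0L) {
    mu <- colMeans(X)
    centered <- sweep(X, 2L, mu)
    ss <- colSums(centered^2)
    denom <- if (sd_type == "population") n else n - 1L
    sigma <- sqrt(ss / denom)
    keep <- sigma > 0
    centered[, keep] <- sweep(centered[, keep, drop = FALSE], 2L, sigma[keep], "/")
    centered[, !keep] <- 0
    fm$values <- centered
  }
  fm$standardized <- TRUE
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("%s %d-gram feature matrix: %d entities x %d l-mers\n",
              if (x$standardized) "Standardized" else "Raw",
              x$l, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Export a feature matrix as TSV
#'
#' @param fm a `feature_matrix`.
#' @param path output path; first column is the entity id, remaining columns
#'   the l-mers.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = fm$entity_ids, fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
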