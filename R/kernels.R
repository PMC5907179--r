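# Similarity kernels over standardized feature rows: RBF (the method's
# kernel) plus linear and degree-2 polynomial comparators.

new_kernel_matrix <- function(values, entity_ids, kind) {
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(list(entity_ids = entity_ids, values = values, kind = kind),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("%s kernel matrix over %d entities\n", x$kind,
              length(x$entity_ids)))
  invisible(x)
}

check_standardized <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!isTRUE(fm$standardized))
    stop("kernels expect a standardized feature matrix; call standardize_features() first")
  fm
}

#' RBF kernel similarity matrix
#'
#' Computes `K[i, j] = exp(-gamma * ||x_i - x_j||^2)` over the rows of a
#' standardized feature matrix, with bandwidth `gamma = 1 / (2 * sigma^2)`.
#' The parameter is constrained to `0 < sigma < 1`.  The diagonal is exactly
#' 1 and all entries lie in (0, 1].
#'
#' @param fm a standardized `feature_matrix`.
#' @param sigma kernel width, in (0, 1).
#' @return A `kernel_matrix` (symmetric, positive semi-definite).
#' @export
rbf_kernel <- function(fm, sigma) {
  check_standardized(fm)
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0 || sigma >= 1)
    stop("sigma must satisfy 0 < sigma < 1")
  gamma <- 1 / (2 * sigma^2)
  X <- fm$values
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0           # numerical guard
  diag(D2) <- 0             # exact self-distance
  K <- exp(-gamma * D2)
  K <- (K + t(K)) / 2       # enforce exact symmetry
  new_kernel_matrix(K, fm$entity_ids, "RBF")
}

#' Linear kernel matrix
#'
#' Plain row dot products of a standardized feature matrix.  Entries may be
#' negative since standardized features are signed; downstream layers
#' consume them as-is, without clipping.
#'
#' @param fm a standardized `feature_matrix`.
#' @return A `kernel_matrix`.
#' @export
linear_kernel <- function(fm) {
  check_standardized(fm)
  K <- tcrossprod(fm$values)
  K <- (K + t(K)) / 2
  new_kernel_matrix(K, fm$entity_ids, "linear")
}

#' Polynomial kernel matrix
#'
#' Inhomogeneous polynomial kernel `(x . y + offset)^degree` with unit scale.
#' The default is the common degree-2 form with unit offset; set
#' `offset = 0` for the homogeneous variant.
#'
#' @param fm a standardized `feature_matrix`.
#' @param degree polynomial degree, >= 1 (default 2).
#' @param offset additive constant inside the power (default 1).
#' @return A `kernel_matrix`.
#' @export
polynomial_kernel <- function(fm, degree = 2, offset = 1) {
  check_standardized(fm)
  if (length(degree) != 1L || is.na(degree) || degree < 1)
    stop("degree must be >= 1")
  K <- (tcrossprod(fm$values) + offset)^degree
  K <- (K + t(K)) / 2
  new_kernel_matrix(K, fm$entity_ids, sprintf("polynomial(%d)", as.integer(degree)))
}

#' An all-ones kernel matrix
#'
#' Neutral similarity: with this kernel the layer weights reduce to the
#' classical common-neighbour resource-allocation weights.  Mainly useful
#' for testing and for running the propagation without sequence information.
#'
#' @param entity_ids identifier vector.
#' @return A `kernel_matrix` of ones.
#' @export
ones_kernel <- function(entity_ids) {
  n <- length(entity_ids)
  new_kernel_matrix(matrix(1, n, n), entity_ids, "ones")
}

#' Compute a kernel matrix by name
#'
#' Dispatch helper used by the pipeline: `"rbf"` uses `sigma`;
#' `"linear"` and `"polynomial"` ignore it; `"ones"` is the neutral kernel.
#'
#' @param fm a standardized `feature_matrix`.
#' @param kind one of `"rbf"`, `"linear"`, `"polynomial"`, `"ones"`.
#' @param sigma RBF width (required for `"rbf"`).
#' @param degree polynomial degree.
#' @return A `kernel_matrix`.
#' @export
compute_kernel <- function(fm, kind = c("rbf", "linear", "polynomial", "ones"),
                           sigma = NULL, degree = 2) {
  kind <- match.arg(kind)
  switch(kind,
         rbf = rbf_kernel(fm, sigma),
         linear = linear_kernel(fm),
         polynomial = polynomial_kernel(fm, degree = degree),
         ones = ones_kernel(fm$entity_ids))
}

#' Export a kernel matrix as TSV
#'
#' @param km a `kernel_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel_matrix <- function(km, path) {
  df <- data.frame(id = km$entity_ids, km$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
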