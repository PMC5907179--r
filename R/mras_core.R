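# The MRAS scoring computation: kernel-modulated resource-allocation weights
# on the two bipartite layers, their combination, and the final
# disease-by-ncRNA score matrix.

as_kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

#' Layer-1 target-target weights (disease-target layer)
#'
#' `W_T[i, j] = K_target[i, j] * sum_l A_DT[l, i] * A_DT[l, j] / deg(d_l)`
#' where `deg(d_l)` is disease l's row sum in `A_DT`.  Two targets gain
#' weight for every disease they share, inversely to that disease's degree;
#' diseases of degree 0 have no incident edges and contribute nothing.
#'
#' @param A_DT binary disease x target matrix.
#' @param K_target target kernel (`kernel_matrix` or plain n x n matrix).
#' @return n x n matrix `W_T`.
#' @export
layer1_weights <- function(A_DT, K_target) {
  K <- as_kernel_values(K_target)
  A_DT <- as.matrix(A_DT)
  n <- ncol(A_DT)
  if (!identical(dim(K), c(n, n)))
    stop("K_target must be ", n, " x ", n, " to match A_DT")
  d <- rowSums(A_DT)
  scaled <- A_DT / ifelse(d > 0, d, 1)   # zero rows stay zero: masked division
  K * crossprod(A_DT, scaled)
}

#' Layer-2 ncRNA-ncRNA weights (target-ncRNA layer)
#'
#' `W_R[i, j] = K_rna[i, j] * sum_l A_TR[l, i] * A_TR[l, j] / deg'(t_l)`.
#' By default the denominator `deg'(t_l)` is target l's degree within the
#' target-ncRNA layer (its row sum in `A_TR`), the direct parallel of
#' layer 1 where the denominator is the degree within that same layer.
#' Setting `degree_from = "dt_network"` instead divides by the target's
#' degree in the disease-target layer; targets with zero degree under the
#' chosen definition are skipped.
#'
#' @param A_TR binary target x ncRNA matrix.
#' @param K_rna ncRNA kernel (`kernel_matrix` or plain p x p matrix).
#' @param degree_from `"tr_network"` (default) or `"dt_network"`.
#' @param A_DT disease x target matrix, required when
#'   `degree_from = "dt_network"`.
#' @return p x p matrix `W_R`.
#' @export
layer2_weights <- function(A_TR, K_rna,
                           degree_from = c("tr_network", "dt_network"),
                           A_DT = NULL) {
  degree_from <- match.arg(degree_from)
  K <- as_kernel_values(K_rna)
  A_TR <- as.matrix(A_TR)
  p <- ncol(A_TR)
  if (!identical(dim(K), c(p, p)))
    stop("K_rna must be ", p, " x ", p, " to match A_TR")
  d <- if (degree_from == "tr_network") {
    rowSums(A_TR)
  } else {
    if (is.null(A_DT))
      stop("A_DT is required when degree_from = \"dt_network\"")
    colSums(as.matrix(A_DT))
  }
  mask <- d > 0
  scaled <- A_TR * 0
  scaled[mask, ] <- A_TR[mask, , drop = FALSE] / d[mask]
  K * crossprod(A_TR, scaled)
}

#' Combine the two layer weights across the target-ncRNA adjacency
#'
#' `W_C = W_T %*% (A_TR %*% W_R)`, an n x p matrix giving, per target-ncRNA
#' pair, the kernel-weighted two-layer path mass linking them; paths with
#' higher frequency receive more weight.
#'
#' @param W_T n x n layer-1 weights.
#' @param A_TR binary n x p adjacency.
#' @param W_R p x p layer-2 weights.
#' @return n x p matrix `W_C`.
#' @export
combine_weights <- function(W_T, A_TR, W_R) {
  W_T <- as.matrix(W_T); A_TR <- as.matrix(A_TR); W_R <- as.matrix(W_R)
  if (ncol(W_T) != nrow(A_TR) || ncol(A_TR) != nrow(W_R))
    stop("non-conformable shapes: W_T is ", nrow(W_T), "x", ncol(W_T),
         ", A_TR is ", nrow(A_TR), "x", ncol(A_TR),
         ", W_R is ", nrow(W_R), "x", ncol(W_R))
  W_T %*% (A_TR %*% W_R)
}

#' Disease-by-ncRNA prediction scores
#'
#' `P = A_DT %*% W_C`; within each disease row, ncRNAs ranked by descending
#' score are the prediction output (higher score, higher certainty of
#' association).
#'
#' @param A_DT binary m x n adjacency.
#' @param W_C n x p combined weights.
#' @return m x p score matrix `P`.
#' @export
prediction_scores <- function(A_DT, W_C) {
  A_DT <- as.matrix(A_DT); W_C <- as.matrix(W_C)
  if (ncol(A_DT) != nrow(W_C))
    stop("non-conformable shapes: A_DT is ", nrow(A_DT), "x", ncol(A_DT),
         ", W_C is ", nrow(W_C), "x", ncol(W_C))
  A_DT %*% W_C
}

#' Score a network given precomputed kernels
#'
#' Low-level entry used by the cross-validation loop, where kernels are
#' computed once and the adjacency changes per fold.
#'
#' @param net a [tripartite_network].
#' @param K_target,K_rna kernel matrices for targets and ncRNAs.
#' @param layer2_degree passed to [layer2_weights()] as `degree_from`.
#' @return An object of class `mras_scores`: list with `disease_ids`,
#'   `ncrna_ids`, `W_T`, `W_R`, `W_C`, `P`.
#' @export
mras_score <- function(net, K_target, K_rna, layer2_degree = "tr_network") {
  W_T <- layer1_weights(net$A_DT, K_target)
  W_R <- layer2_weights(net$A_TR, K_rna, degree_from = layer2_degree,
                        A_DT = net$A_DT)
  W_C <- combine_weights(W_T, net$A_TR, W_R)
  P <- prediction_scores(net$A_DT, W_C)
  dimnames(P) <- list(net$diseases, net$ncrnas)
  structure(list(disease_ids = net$diseases, ncrna_ids = net$ncrnas,
                 W_T = W_T, W_R = W_R, W_C = W_C, P = P),
            class = "mras_scores")
}

#' @export
print.mras_scores <- function(x, ...) {
  cat(sprintf("MRAS score matrix: %d diseases x %d ncRNAs\n",
              length(x$disease_ids), length(x$ncrna_ids)))
  invisible(x)
}

#' Run the full MRAS pipeline on a network and its sequences
#'
#' Composes the stages: l-gram feature extraction for targets and ncRNAs
#' (featurized separately, two vocabularies), column standardization, kernel
#' computation, the two resource-allocation layers, their combination, and
#' the final score matrix `P = A_DT %*% W_C`.
#'
#' The RBF bandwidths follow the layer kernels' own parameter naming:
#' `sigma1` is the ncRNA kernel width and `sigma2` the target kernel width.
#' Set `sigma_assignment = "sigma1_target"` to swap them.
#'
#' @param net a [tripartite_network].
#' @param target_seqs,ncrna_seqs [sequence_records] covering every target /
#'   ncRNA in `net`.
#' @param l l-gram length (typically 1-4).
#' @param sigma1 RBF width for the ncRNA kernel, in (0, 1).
#' @param sigma2 RBF width for the target kernel, in (0, 1).
#' @param kernel kernel family: `"rbf"` (default), `"linear"`,
#'   `"polynomial"`, or `"ones"` (neutral).
#' @param sigma_assignment `"sigma1_rna"` (default) or `"sigma1_target"`.
#' @param layer2_degree denominator convention for layer 2, see
#'   [layer2_weights()].
#' @param K_target,K_rna optional precomputed kernel overrides; when given,
#'   features and `sigma` values are ignored for that side.
#' @return An `mras_scores` object.
#' @export
run_mras <- function(net, target_seqs, ncrna_seqs, l = 3,
                     sigma1 = 0.5, sigma2 = 0.5,
                     kernel = c("rbf", "linear", "polynomial", "ones"),
                     sigma_assignment = c("sigma1_rna", "sigma1_target"),
                     layer2_degree = "tr_network",
                     K_target = NULL, K_rna = NULL) {
  kernel <- match.arg(kernel)
  sigma_assignment <- match.arg(sigma_assignment)
  sig <- if (sigma_assignment == "sigma1_rna") {
    list(rna = sigma1, target = sigma2)
  } else {
    list(rna = sigma2, target = sigma1)
  }
  if (is.null(K_target)) {
    missing_t <- setdiff(net$targets, names(target_seqs))
    if (length(missing_t))
      stop("no sequence for target(s): ", paste(missing_t, collapse = ", "))
    fm_t <- build_feature_matrix(unclass(target_seqs)[net$targets], l)
    fm_t <- standardize_features(fm_t)
    K_target <- compute_kernel(fm_t, kernel, sigma = sig$target)
  }
  if (is.null(K_rna)) {
    missing_r <- setdiff(net$ncrnas, names(ncrna_seqs))
    if (length(missing_r))
      stop("no sequence for ncRNA(s): ", paste(missing_r, collapse = ", "))
    fm_r <- build_feature_matrix(unclass(ncrna_seqs)[net$ncrnas], l)
    fm_r <- standardize_features(fm_r)
    K_rna <- compute_kernel(fm_r, kernel, sigma = sig$rna)
  }
  mras_score(net, K_target, K_rna, layer2_degree = layer2_degree)
}

#' Top-ranked ncRNA associations per disease
#'
#' @param scores an `mras_scores` object.
#' @param topk number of ncRNAs to report per disease (default 10).
#' @return data.frame with columns `disease_id`, `rank`, `ncrna_id`,
#'   `score`, ncRNAs ranked by descending score within each disease (ties
#'   broken by ncRNA order).
#' @export
top_associations <- function(scores, topk = 10) {
  P <- scores$P
  k <- min(topk, ncol(P))
  rows <- lapply(seq_len(nrow(P)), function(i) {
    ord <- order(-P[i, ], seq_len(ncol(P)))[seq_len(k)]
    data.frame(disease_id = scores$disease_ids[i], rank = seq_len(k),
               ncrna_id = scores$ncrna_ids[ord], score = P[i, ord],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Export a score matrix and ranked lists as TSV
#'
#' @param scores an `mras_scores` object.
#' @param path output path for the disease x ncRNA score table.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(disease_id = scores$disease_ids, scores$P,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
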