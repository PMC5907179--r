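# Link-cut cross-validation: pair enumeration, stratified fold partitioning,
# link cutting, ROC/AUC, fold/repeat averaging and the sigma grid search.

# Evaluate expr under a temporary RNG state so library calls never disturb
# the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(index)) %% 2147483647
}

#' Enumerate all disease-ncRNA pairs with connectivity labels
#'
#' Every one of the m x p pairs is listed; a pair is labeled 1 exactly when
#' it is connected through at least one common target in the network, i.e.
#' `(A_DT %*% A_TR)[d, r] >= 1`.
#'
#' @param net a [tripartite_network].
#' @return data.frame with columns `disease_id`, `ncrna_id`, `disease_idx`,
#'   `ncrna_idx`, `label` (0/1), in disease-major order.
#' @export
enumerate_pairs <- function(net) {
  paths <- net$A_DT %*% net$A_TR
  m <- length(net$diseases); p <- length(net$ncrnas)
  data.frame(
    disease_id = rep(net$diseases, each = p),
    ncrna_id = rep(net$ncrnas, times = m),
    disease_idx = rep(seq_len(m), each = p),
    ncrna_idx = rep(seq_len(p), times = m),
    label = as.integer(t(paths) >= 1)[seq_len(m * p)],
    stringsAsFactors = FALSE
  )
}

#' Partition labeled pairs into k cross-validation folds
#'
#' Folds are label-stratified: positives are dealt round-robin across the k
#' folds after a seeded shuffle, then negatives are assigned one at a time
#' to the currently smallest fold, so positive counts differ by at most 1
#' and fold sizes differ by at most 1.  Set `stratified = FALSE` for a plain
#' random split.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param k number of folds, `2 <= k <= nrow(pairs)`.
#' @param seed RNG seed; the partition is a deterministic function of it.
#' @param stratified stratify by label (default TRUE).
#' @return Integer vector of fold ids (1..k), one per pair row.
#' @export
partition_folds <- function(pairs, k, seed, stratified = TRUE) {
  N <- nrow(pairs)
  if (k > N) stop("k = ", k, " exceeds the number of pairs (", N, ")")
  if (k < 2) stop("k must be at least 2")
  with_seed(seed, {
    fold <- integer(N)
    if (!stratified) {
      fold <- sample(rep_len(seq_len(k), N))
    } else {
      pos <- which(pairs$label == 1)
      neg <- which(pairs$label == 0)
      pos <- sample(pos)
      if (length(pos))
        fold[pos] <- rep_len(seq_len(k), length(pos))
      sizes <- tabulate(fold[fold > 0], nbins = k)
      neg <- sample(neg)
      for (i in neg) {
        j <- which.min(sizes)
        fold[i] <- j
        sizes[j] <- sizes[j] + 1L
      }
    }
    fold
  })
}

#' Cut the network links that connect held-out pairs
#'
#' For every test pair (d, r) that is connected through targets, each
#' target-ncRNA edge (t, r) with t adjacent to both d and r is removed, so
#' that after cutting no held-out positive pair retains a
#' disease-target-ncRNA path.  With `cut_mode = "both"` the disease-target
#' edges (d, t) of those connecting paths are removed as well.  The input
#' network is not modified.
#'
#' @param net a [tripartite_network].
#' @param test_pairs data.frame rows drawn from [enumerate_pairs()] output.
#' @param cut_mode `"tr_edge"` (default) or `"both"`.
#' @return A new [tripartite_network] with the cut adjacency.
#' @export
cut_links <- function(net, test_pairs, cut_mode = c("tr_edge", "both")) {
  cut_mode <- match.arg(cut_mode)
  A_DT <- net$A_DT
  A_TR <- net$A_TR
  for (i in seq_len(nrow(test_pairs))) {
    d <- test_pairs$disease_idx[i]
    r <- test_pairs$ncrna_idx[i]
    t_hit <- which(A_DT[d, ] == 1 & A_TR[, r] == 1)
    if (length(t_hit)) {
      A_TR[t_hit, r] <- 0
      if (cut_mode == "both") A_DT[d, t_hit] <- 0
    }
  }
  tripartite_network(net$diseases, net$targets, net$ncrnas, A_DT, A_TR)
}

#' ROC curve and AUC for a score vector
#'
#' The AUC is the Mann-Whitney statistic with midrank tie handling: the
#' probability that a random positive outranks a random negative, counting
#' ties as 1/2.  ROC points come from sweeping a threshold over the distinct
#' score values; the trapezoidal area under those points equals the
#' Mann-Whitney value.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length, containing both classes.
#' @return List with `auc` and `roc` (data.frame of `fpr`, `tpr` from (0,0)
#'   to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # one point per distinct threshold
  tpr <- c(0, cumsum(y)[keep] / n_pos)
  fpr <- c(0, cumsum(1 - y)[keep] / n_neg)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

# Average a list of ROC curves on a common FPR grid by linear interpolation.
average_roc <- function(rocs, grid = seq(0, 1, by = 0.01)) {
  if (!length(rocs)) return(data.frame(fpr = grid, tpr = NA_real_))
  tprs <- vapply(rocs, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

#' Link-cut k-fold cross-validation of MRAS
#'
#' Implements the evaluation protocol: all disease-ncRNA pairs are labeled
#' by target-mediated connectivity and split into k stratified folds; for
#' each fold the paths of held-out connected pairs are cut (when
#' `cut_links = TRUE`), MRAS is re-run on the cut network with kernels fixed
#' (sequences are never held out, only links, so feature standardization and
#' kernels are computed once on the full sequence sets), and only the
#' held-out pairs are scored.  Fold ROC/AUCs are averaged over folds and
#' `repeats` independent re-randomizations of the partition.
#'
#' Folds whose held-out pairs are single-class cannot form a ROC curve; they
#' are skipped with a warning and excluded from the mean.
#'
#' @param net a [tripartite_network].
#' @param target_seqs,ncrna_seqs [sequence_records] for targets / ncRNAs.
#' @param l l-gram length.
#' @param sigma1,sigma2 RBF widths (ncRNA and target kernels; see
#'   [run_mras()]).
#' @param kernel kernel family passed to [run_mras()].
#' @param k fold count (default 5).
#' @param repeats number of fold re-randomizations (default 5).
#' @param seed master seed; per-repeat sub-seeds are derived
#'   deterministically.
#' @param cut_links cut held-out links before scoring (default TRUE).
#' @param cut_mode passed to [cut_links()].
#' @param shuffle_labels permute the pair labels before folding and scoring
#'   (seeded); a null-calibration control under which AUC should sit near
#'   0.5.  Cutting still follows the network's true connectivity.
#' @param stratified stratify folds by label (default TRUE).
#' @param sigma_assignment,layer2_degree passed to [run_mras()].
#' @return An object of class `mras_cv`: list with `fold_aucs` (data.frame
#'   `repeat_id`, `fold`, `auc`), `mean_auc`, `roc` (averaged curve), and
#'   `config`.
#' @export
cross_validate <- function(net, target_seqs, ncrna_seqs, l = 3,
                           sigma1 = 0.5, sigma2 = 0.5, kernel = "rbf",
                           k = 5, repeats = 5, seed = 1,
                           cut_links = TRUE, cut_mode = "tr_edge",
                           shuffle_labels = FALSE, stratified = TRUE,
                           sigma_assignment = "sigma1_rna",
                           layer2_degree = "tr_network") {
  pairs <- enumerate_pairs(net)
  if (shuffle_labels)
    pairs$label <- with_seed(derive_seed(seed, 999983),
                             sample(pairs$label))
  # kernels are fixed across folds: only links are held out, never sequences
  kernels <- mras_cv_kernels(net, target_seqs, ncrna_seqs, l,
                             sigma1, sigma2, kernel, sigma_assignment)
  rows <- list()
  rocs <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- partition_folds(pairs, k, derive_seed(seed, rep_i),
                            stratified = stratified)
    for (f in seq_len(k)) {
      test <- pairs[fold == f, , drop = FALSE]
      if (length(unique(test$label)) < 2L) {
        warning("repeat ", rep_i, " fold ", f,
                " held-out pairs are single-class; fold skipped")
        rows[[length(rows) + 1L]] <-
          data.frame(repeat_id = rep_i, fold = f, auc = NA_real_)
        next
      }
      # the logical argument does not shadow the function in call position
      work <- if (cut_links) {
        cut_links(net, test, cut_mode = cut_mode)
      } else net
      sc <- mras_score(work, kernels$K_target, kernels$K_rna,
                       layer2_degree = layer2_degree)
      s <- sc$P[cbind(test$disease_idx, test$ncrna_idx)]
      ra <- roc_auc(s, test$label)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_id = rep_i, fold = f, auc = ra$auc)
      rocs[[length(rocs) + 1L]] <- ra$roc
    }
  }
  fold_aucs <- do.call(rbind, rows)
  structure(list(
    fold_aucs = fold_aucs,
    mean_auc = mean(fold_aucs$auc, na.rm = TRUE),
    roc = average_roc(rocs),
    config = list(l = l, sigma1 = sigma1, sigma2 = sigma2, kernel = kernel,
                  k = k, repeats = repeats, seed = seed,
                  cut_links = cut_links, cut_mode = cut_mode,
                  shuffle_labels = shuffle_labels, stratified = stratified,
                  sigma_assignment = sigma_assignment,
                  layer2_degree = layer2_degree)
  ), class = "mras_cv")
}

# Compute the fixed pair of kernels used across all folds.
mras_cv_kernels <- function(net, target_seqs, ncrna_seqs, l,
                            sigma1, sigma2, kernel, sigma_assignment) {
  sig <- if (identical(sigma_assignment, "sigma1_rna")) {
    list(rna = sigma1, target = sigma2)
  } else {
    list(rna = sigma2, target = sigma1)
  }
  missing_t <- setdiff(net$targets, names(target_seqs))
  if (length(missing_t))
    stop("no sequence for target(s): ", paste(missing_t, collapse = ", "))
  missing_r <- setdiff(net$ncrnas, names(ncrna_seqs))
  if (length(missing_r))
    stop("no sequence for ncRNA(s): ", paste(missing_r, collapse = ", "))
  fm_t <- standardize_features(
    build_feature_matrix(unclass(target_seqs)[net$targets], l))
  fm_r <- standardize_features(
    build_feature_matrix(unclass(ncrna_seqs)[net$ncrnas], l))
  list(K_target = compute_kernel(fm_t, kernel, sigma = sig$target),
       K_rna = compute_kernel(fm_r, kernel, sigma = sig$rna))
}

#' @export
print.mras_cv <- function(x, ...) {
  n_ok <- sum(!is.na(x$fold_aucs$auc))
  cat(sprintf("MRAS cross-validation: mean AUC = %.4f over %d fold evaluations",
              x$mean_auc, n_ok))
  cat(sprintf(" (k = %d, repeats = %d, link cut %s)\n",
              x$config$k, x$config$repeats,
              if (x$config$cut_links) "on" else "off"))
  invisible(x)
}

#' Grid search over the RBF bandwidths
#'
#' Evaluates cross-validated mean AUC on the full `sigma1 x sigma2` grid
#' (default `{0.1, ..., 0.9}^2`, 81 points) and returns the argmax.  All
#' grid points share the same master seed, hence identical fold partitions,
#' so AUC differences reflect the bandwidths alone.  Ties are broken by the
#' lexicographically smaller `(sigma1, sigma2)`.  Model selection uses
#' held-out-fold AUC directly, which is optimistic by construction; it is a
#' protocol replication, not an unbiased performance estimate.
#'
#' @param net,target_seqs,ncrna_seqs,l,kernel,k,repeats,seed,... as in
#'   [cross_validate()].
#' @param grid1,grid2 candidate values for `sigma1` / `sigma2`.
#' @param eval_fn optional evaluation override: a
#'   `function(sigma1, sigma2) -> mean AUC`, used in place of the
#'   cross-validation (testing hook).
#' @return List with `sigma1`, `sigma2`, `best_auc`, and `auc_grid` (matrix
#'   `length(grid1) x length(grid2)`, dimnames the sigma values).
#' @export
grid_search_sigmas <- function(net, target_seqs, ncrna_seqs, l = 3,
                               grid1 = seq(0.1, 0.9, by = 0.1),
                               grid2 = seq(0.1, 0.9, by = 0.1),
                               kernel = "rbf", k = 5, repeats = 5, seed = 1,
                               eval_fn = NULL, ...) {
  aucs <- matrix(NA_real_, length(grid1), length(grid2),
                 dimnames = list(format(grid1), format(grid2)))
  best <- list(sigma1 = NA_real_, sigma2 = NA_real_, best_auc = -Inf)
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      a <- if (is.null(eval_fn)) {
        cross_validate(net, target_seqs, ncrna_seqs, l = l,
                       sigma1 = grid1[i], sigma2 = grid2[j],
                       kernel = kernel, k = k, repeats = repeats,
                       seed = seed, ...)$mean_auc
      } else {
        eval_fn(grid1[i], grid2[j])
      }
      aucs[i, j] <- a
      if (!is.na(a) && a > best$best_auc) {
        best <- list(sigma1 = grid1[i], sigma2 = grid2[j], best_auc = a)
      }
    }
  }
  c(best, list(auc_grid = aucs))
}
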