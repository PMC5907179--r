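test_that("pair enumeration labels pairs by target-mediated connectivity", {
  pairs <- enumerate_pairs(toy_chain_network())
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$label, 1L)
  # no TR edges: all labels 0
  net0 <- tripartite_network(c("d1", "d2"), "t1", c("r1", "r2"),
                             matrix(1, 2, 1), matrix(0, 1, 2))
  expect_equal(enumerate_pairs(net0)$label, rep(0L, 4))
})

test_that("pair labels match a per-pair path-existence loop on random networks", {
  for (s in 1:5) {
    net <- generate_network(6, 5, 4, density_dt = 0.4, density_tr = 0.4,
                            seed = s)
    pairs <- enumerate_pairs(net)
    for (i in seq_len(nrow(pairs))) {
      d <- pairs$disease_idx[i]; r <- pairs$ncrna_idx[i]
      connected <- any(net$A_DT[d, ] == 1 & net$A_TR[, r] == 1)
      expect_identical(pairs$label[i] == 1L, connected)
    }
  }
})

test_that("fold partitioning is balanced, stratified, seeded and exhaustive", {
  net <- generate_network(10, 8, 5, density_dt = 0.3, density_tr = 0.3,
                          seed = 61)
  pairs <- enumerate_pairs(net)   # 50 pairs
  fold <- partition_folds(pairs, 5, seed = 7)
  expect_length(fold, nrow(pairs))
  sizes <- tabulate(fold, 5)
  expect_equal(sum(sizes), nrow(pairs))
  expect_lte(diff(range(sizes)), 1)
  pos_per_fold <- tabulate(fold[pairs$label == 1], 5)
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_identical(fold, partition_folds(pairs, 5, seed = 7))  # determinism
  expect_false(identical(fold, partition_folds(pairs, 5, seed = 8)))
  expect_error(partition_folds(pairs[1:3, ], 5, seed = 1), "exceeds")
  # N = 10, k = 5: five groups of 2
  expect_equal(unname(tabulate(partition_folds(pairs[1:10, ], 5, 1), 5)),
               rep(2L, 5))
})

test_that("link cutting removes the connecting target-ncRNA edges only", {
  net <- toy_chain_network()
  pairs <- enumerate_pairs(net)
  cut <- cut_links(net, pairs)
  expect_equal(sum(cut$A_TR), 0)
  expect_equal(sum(cut$A_DT), 1)  # disease-target evidence kept
  expect_equal(sum(net$A_TR), 1)  # original not mutated
  # a label-0 test pair changes nothing
  net0 <- tripartite_network("d1", "t1", c("r1", "r2"),
                             matrix(1, 1, 1), matrix(c(1, 0), 1, 2))
  p0 <- enumerate_pairs(net0)
  cut0 <- cut_links(net0, p0[p0$label == 0, ])
  expect_equal(cut0$A_TR, net0$A_TR)
  # cut_mode = "both" also drops the disease-target edge
  cutb <- cut_links(net, pairs, cut_mode = "both")
  expect_equal(sum(cutb$A_DT), 0)
})

test_that("after cutting, no held-out positive pair retains a path", {
  for (s in 1:5) {
    net <- generate_network(8, 6, 5, density_dt = 0.4, density_tr = 0.4,
                            seed = s)
    pairs <- enumerate_pairs(net)
    fold <- partition_folds(pairs, 3, seed = s)
    for (f in 1:3) {
      test <- pairs[fold == f, ]
      cut <- cut_links(net, test)
      relabel <- enumerate_pairs(cut)
      key <- paste(relabel$disease_id, relabel$ncrna_id)
      still <- relabel$label[match(paste(test$disease_id, test$ncrna_id), key)]
      expect_equal(still[test$label == 1], rep(0L, sum(test$label == 1)))
    }
  }
})

test_that("AUC handles perfect rankings and all-tied scores", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 1, 0))$auc, 0)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "positive and one negative")
})

test_that("trapezoid ROC area, midrank AUC, pair counting and pROC all agree", {
  skip_if_not_installed("pROC")
  set.seed(67)
  for (rep in 1:25) {
    n <- 40
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    ra <- roc_auc(scores, labels)
    expect_equal(ra$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(trapezoid_area(ra$roc), ra$auc, tolerance = 1e-12)
    proc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(ra$auc, proc, tolerance = 1e-12)
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("cross-validation is reproducible and reports every repeat x fold", {
  sim <- simulate_dataset(12, 10, 8, density_dt = 0.25, density_tr = 0.25,
                          signal = 2, seed = 71)
  cv1 <- cross_validate(sim$network, sim$target_seqs, sim$ncrna_seqs, l = 2,
                        k = 4, repeats = 2, seed = 5)
  cv2 <- cross_validate(sim$network, sim$target_seqs, sim$ncrna_seqs, l = 2,
                        k = 4, repeats = 2, seed = 5)
  expect_identical(cv1$fold_aucs, cv2$fold_aucs)
  expect_equal(nrow(cv1$fold_aucs), 8)
  expect_true(all(stats::na.omit(cv1$fold_aucs$auc) >= 0 &
                  stats::na.omit(cv1$fold_aucs$auc) <= 1))
  expect_equal(cv1$mean_auc, mean(cv1$fold_aucs$auc, na.rm = TRUE))
  # averaged ROC is a curve on [0,1]^2 ending at (1,1)
  expect_equal(cv1$roc$tpr[nrow(cv1$roc)], 1, tolerance = 1e-9)
})

test_that("link cutting lowers the planted-signal AUC below the uncut one", {
  sim <- simulate_dataset(20, 15, 15, density_dt = 0.15, density_tr = 0.15,
                          signal = 4, seed = 73)
  args <- list(sim$network, sim$target_seqs, sim$ncrna_seqs, l = 3,
               k = 5, repeats = 2, seed = 9)
  cv_cut <- do.call(cross_validate, c(args, cut_links = TRUE))
  cv_uncut <- do.call(cross_validate, c(args, cut_links = FALSE))
  expect_gt(cv_uncut$mean_auc, cv_cut$mean_auc)
  expect_gt(cv_uncut$mean_auc, 0.9)  # memorized connectivity is near-perfect
})

test_that("grid search returns the singleton point and honours an injected scorer", {
  sim <- simulate_dataset(8, 6, 5, density_dt = 0.4, density_tr = 0.4,
                          signal = 1, seed = 79)
  gs <- grid_search_sigmas(sim$network, sim$target_seqs, sim$ncrna_seqs,
                           l = 2, grid1 = 0.5, grid2 = 0.5, k = 3,
                           repeats = 1, seed = 3)
  cv <- cross_validate(sim$network, sim$target_seqs, sim$ncrna_seqs, l = 2,
                       sigma1 = 0.5, sigma2 = 0.5, k = 3, repeats = 1, seed = 3)
  expect_equal(gs$best_auc, cv$mean_auc)
  expect_equal(c(gs$sigma1, gs$sigma2), c(0.5, 0.5))
  # unimodal synthetic objective: argmax recovered, ties broken lexicographically
  fake <- function(s1, s2) 1 - (s1 - 0.6)^2 - (s2 - 0.3)^2
  gs2 <- grid_search_sigmas(NULL, NULL, NULL, eval_fn = fake)
  expect_equal(c(gs2$sigma1, gs2$sigma2), c(0.6, 0.3))
  expect_equal(dim(gs2$auc_grid), c(9, 9))
  gs3 <- grid_search_sigmas(NULL, NULL, NULL, eval_fn = function(s1, s2) 0.5)
  expect_equal(c(gs3$sigma1, gs3$sigma2), c(0.1, 0.1))
})

test_that("single-class held-out folds are skipped with a warning, not fatal", {
  # a network with a single connected pair: most folds see one class only
  net <- tripartite_network(c("d1", "d2", "d3"), c("t1", "t2"), c("r1", "r2"),
                            rbind(c(1, 0), c(0, 0), c(0, 0)),
                            rbind(c(1, 0), c(0, 0)))
  seqs <- generate_sequences(net, signal = 0, seed = 83)
  warns <- testthat::capture_warnings(
    cv <- cross_validate(net, seqs$target_seqs, seqs$ncrna_seqs, l = 1,
                         k = 3, repeats = 1, seed = 1, stratified = FALSE))
  expect_true(any(grepl("single-class", warns)))
  expect_true(any(is.na(cv$fold_aucs$auc)))
})
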