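# Shared fixtures and independent nested-loop oracles.

# Tiny hand-built chain network: d1-t1, t1-r1 (plus spare nodes on demand).
toy_chain_network <- function() {
  tripartite_network("d1", "t1", "r1",
                     A_DT = matrix(1, 1, 1),
                     A_TR = matrix(1, 1, 1))
}

random_instance <- function(m, n, p, density = 0.5) {
  A_DT <- matrix(rbinom(m * n, 1, density), m, n)
  A_TR <- matrix(rbinom(n * p, 1, density), n, p)
  sym <- function(q) { M <- matrix(runif(q * q), q, q); (M + t(M)) / 2 }
  list(A_DT = A_DT, A_TR = A_TR, K_T = sym(n), K_R = sym(p))
}

# Scalar nested-loop oracles, independent of the matrix-algebra path.
oracle_layer1 <- function(A_DT, K_T) {
  m <- nrow(A_DT); n <- ncol(A_DT)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(m)) {
      dl <- sum(A_DT[l, ])
      if (dl > 0) s <- s + A_DT[l, i] * A_DT[l, j] / dl
    }
    W[i, j] <- K_T[i, j] * s
  }
  W
}

oracle_layer2 <- function(A_TR, K_R) {
  n <- nrow(A_TR); p <- ncol(A_TR)
  W <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- 0
    for (l in seq_len(n)) {
      dl <- sum(A_TR[l, ])
      if (dl > 0) s <- s + A_TR[l, i] * A_TR[l, j] / dl
    }
    W[i, j] <- K_R[i, j] * s
  }
  W
}

oracle_combine <- function(W_T, A_TR, W_R) {
  n <- nrow(W_T); p <- ncol(W_R)
  W <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    s <- 0
    for (t in seq_len(n)) {
      inner <- 0
      for (r in seq_len(p)) inner <- inner + A_TR[t, r] * W_R[r, j]
      s <- s + W_T[i, t] * inner
    }
    W[i, j] <- s
  }
  W
}

oracle_scores <- function(A_DT, W_C) {
  m <- nrow(A_DT); p <- ncol(W_C)
  P <- matrix(0, m, p)
  for (i in seq_len(m)) for (j in seq_len(p))
    P[i, j] <- sum(A_DT[i, ] * W_C[, j])
  P
}

# Brute-force concordant-pair AUC with ties counted as 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# Standardized feature matrix from explicit values (kernel tests).
fm_from_matrix <- function(X, standardized = TRUE) {
  structure(list(entity_ids = paste0("e", seq_len(nrow(X))),
                 vocabulary = paste0("v", seq_len(ncol(X))),
                 values = X, l = 1L, standardized = standardized),
            class = "feature_matrix")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
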