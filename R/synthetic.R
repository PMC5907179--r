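# Synthetic tripartite networks and sequences with a plantable signal:
# sequence-similar ncRNAs share targets, the statistical premise the
# kernel-weighted propagation exploits.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Generate a synthetic tripartite network
#'
#' Disease-target edges are sampled independently at `density_dt`.
#' Target-ncRNA edges are sampled at `density_tr`; with `signal > 0` the
#' ncRNAs are first grouped into `n_clusters` clusters, each cluster is
#' assigned a preferred target set, and the odds of an edge between a
#' cluster member and a preferred target are multiplied by `exp(signal)`
#' (an additive shift of `signal` on the log-odds scale).  `signal = 0`
#' recovers fully independent Bernoulli edges.
#'
#' Exact-count mode (`edges_dt` / `edges_tr`) instead draws a uniform random
#' subset of cells with exactly the requested number of edges; it ignores
#' the planted signal for the layer it is applied to and exists to construct
#' networks with prescribed edge counts and hence prescribed average degree.
#'
#' @param m,n,p counts of diseases, targets, ncRNAs (all >= 1).
#' @param density_dt,density_tr edge probabilities in `[0, 1]`.
#' @param signal log-odds boost (>= 0) tying cluster members to their
#'   preferred targets.
#' @param n_clusters number of ncRNA clusters; default `ceiling(p / 10)`.
#' @param edges_dt,edges_tr optional exact edge counts.
#' @param seed RNG seed.
#' @return A [tripartite_network] with ids `d1..dm`, `t1..tn`, `r1..rp` and
#'   attributes `cluster` (ncRNA cluster assignment) and
#'   `preferred_targets` (per-cluster target index sets).
#' @export
generate_network <- function(m, n, p, density_dt = 0.05, density_tr = 0.05,
                             signal = 0, n_clusters = ceiling(p / 10),
                             edges_dt = NULL, edges_tr = NULL, seed = 1) {
  if (m < 1 || n < 1 || p < 1) stop("m, n and p must all be >= 1")
  if (density_dt < 0 || density_dt > 1 || density_tr < 0 || density_tr > 1)
    stop("densities must lie in [0, 1]")
  if (signal < 0) stop("signal must be >= 0")
  with_seed(seed, {
    cluster <- if (p > 0) rep_len(seq_len(max(n_clusters, 1L)), p) else integer(0)
    cluster <- sample(cluster)
    pref_size <- max(1L, ceiling(density_tr * n))
    preferred <- lapply(seq_len(max(n_clusters, 1L)), function(c)
      sample.int(n, min(pref_size, n)))

    A_DT <- if (!is.null(edges_dt)) {
      exact_edges(m, n, edges_dt)
    } else {
      matrix(stats::rbinom(m * n, 1, density_dt), m, n)
    }

    A_TR <- if (!is.null(edges_tr)) {
      exact_edges(n, p, edges_tr)
    } else if (signal == 0 || density_tr %in% c(0, 1)) {
      matrix(stats::rbinom(n * p, 1, density_tr), n, p)
    } else {
      prob <- matrix(density_tr, n, p)
      base_logit <- stats::qlogis(density_tr)
      for (j in seq_len(p)) {
        tgt <- preferred[[cluster[j]]]
        prob[tgt, j] <- stats::plogis(base_logit + signal)
      }
      matrix(stats::rbinom(n * p, 1, as.vector(prob)), n, p)
    }

    net <- tripartite_network(paste0("d", seq_len(m)),
                              paste0("t", seq_len(n)),
                              paste0("r", seq_len(p)),
                              A_DT, A_TR)
    attr(net, "cluster") <- stats::setNames(cluster, net$ncrnas)
    attr(net, "preferred_targets") <- preferred
    net
  })
}

# Uniform random subset of an m x n grid with exactly k ones.
exact_edges <- function(m, n, k) {
  if (k > m * n) stop("requested ", k, " edges but only ", m * n, " cells")
  A <- matrix(0, m, n)
  A[sample.int(m * n, k)] <- 1
  A
}

random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

mutate_seq <- function(sequence, rate, alphabet) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate sequences for a synthetic network
#'
#' Target sequences are i.i.d. uniform over the amino-acid alphabet.  ncRNA
#' sequences are uniform over the nucleotide alphabet when `signal = 0`;
#' with `signal > 0`, ncRNAs in the same cluster (as assigned by
#' [generate_network()]) are mutated copies of a common cluster ancestor,
#' with per-position mutation probability `exp(-signal)`, so that sequence
#' similarity correlates with shared-target structure.  At `signal = 0` the
#' mutation rate is 1 and every position is resampled, i.e. sequences are
#' independent.
#'
#' @param network a network from [generate_network()] (its `cluster`
#'   attribute drives the ancestry).
#' @param signal same interpretation as in [generate_network()].
#' @param target_length_range,ncrna_length_range inclusive length ranges.
#' @param target_alphabet,ncrna_alphabet character sets.
#' @param seed RNG seed.
#' @return List with `target_seqs` and `ncrna_seqs`, both
#'   [sequence_records].
#' @export
generate_sequences <- function(network, signal = 0,
                               target_length_range = c(80, 300),
                               ncrna_length_range = c(60, 400),
                               target_alphabet = AA_ALPHABET,
                               ncrna_alphabet = RNA_ALPHABET,
                               seed = 1) {
  if (signal < 0) stop("signal must be >= 0")
  if (min(target_length_range) < 1 || min(ncrna_length_range) < 1)
    stop("sequence lengths must be >= 1")
  cluster <- attr(network, "cluster")
  if (is.null(cluster))
    cluster <- stats::setNames(seq_along(network$ncrnas), network$ncrnas)
  with_seed(seed, {
    t_len <- sample(seq(target_length_range[1], target_length_range[2]),
                    length(network$targets), replace = TRUE)
    tseqs <- vapply(t_len, random_seq, "", alphabet = target_alphabet)

    rate <- exp(-signal)
    if (signal == 0) {
      r_len <- sample(seq(ncrna_length_range[1], ncrna_length_range[2]),
                      length(network$ncrnas), replace = TRUE)
      rseqs <- vapply(r_len, random_seq, "", alphabet = ncrna_alphabet)
    } else {
      ks <- sort(unique(cluster))
      anc_len <- stats::setNames(
        sample(seq(ncrna_length_range[1], ncrna_length_range[2]),
               length(ks), replace = TRUE), ks)
      ancestors <- stats::setNames(
        vapply(anc_len, random_seq, "", alphabet = ncrna_alphabet), ks)
      rseqs <- vapply(seq_along(network$ncrnas), function(j) {
        mutate_seq(ancestors[[as.character(cluster[j])]], rate, ncrna_alphabet)
      }, "")
    }
    list(target_seqs = sequence_records(network$targets, tseqs, "target"),
         ncrna_seqs = sequence_records(network$ncrnas, rseqs, "ncrna"))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: a network plus matching sequences, sharing one seed
#' and one signal level.
#'
#' @inheritParams generate_network
#' @param ... passed on to [generate_sequences()].
#' @return List with `network`, `target_seqs`, `ncrna_seqs`, and `config`
#'   (the generating parameters).
#' @export
simulate_dataset <- function(m, n, p, density_dt = 0.05, density_tr = 0.05,
                             signal = 0, n_clusters = ceiling(p / 10),
                             edges_dt = NULL, edges_tr = NULL, seed = 1, ...) {
  net <- generate_network(m, n, p, density_dt, density_tr, signal,
                          n_clusters, edges_dt, edges_tr, seed)
  seqs <- generate_sequences(net, signal = signal,
                             seed = derive_seed(seed, 2), ...)
  list(network = net,
       target_seqs = seqs$target_seqs,
       ncrna_seqs = seqs$ncrna_seqs,
       config = list(m = m, n = n, p = p, density_dt = density_dt,
                     density_tr = density_tr, signal = signal,
                     n_clusters = n_clusters, edges_dt = edges_dt,
                     edges_tr = edges_tr, seed = seed))
}
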