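# Domain types and I/O: sequence records, interaction tables, tripartite
# network construction, degree statistics.

#' Create a set of sequence records
#'
#' A sequence record pairs a unique identifier with a sequence string.
#' Sequences are upper-cased on ingest; no alphabet conversion is performed
#' (in particular T is never rewritten to U or vice versa), because targets
#' are typically proteins while ncRNAs are nucleotide sequences.
#'
#' @param ids character vector of unique, non-empty identifiers.
#' @param sequences character vector of sequences, same length as `ids`,
#'   each of length >= 1.
#' @param entity_class `"target"` or `"ncrna"`.
#' @return An object of class `sequence_records`: a named character vector of
#'   upper-cased sequences with attribute `entity_class`.
#' @export
sequence_records <- function(ids, sequences, entity_class = c("target", "ncrna")) {
  entity_class <- match.arg(entity_class)
  ids <- as.character(ids)
  sequences <- as.character(sequences)
  if (length(ids) != length(sequences))
    stop("ids and sequences must have equal length")
  if (any(!nzchar(ids)))
    stop("empty identifier in sequence records")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  empty <- ids[!nzchar(sequences)]
  if (length(empty))
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "))
  out <- toupper(sequences)
  names(out) <- ids
  structure(out, entity_class = entity_class, class = "sequence_records")
}

#' Read sequences from a FASTA file
#'
#' The identifier is the header token before the first whitespace; wrapped
#' sequence lines are concatenated and upper-cased.
#'
#' @param path path to a FASTA file.
#' @param entity_class `"target"` or `"ncrna"`.
#' @return A [sequence_records] object, one record per FASTA entry in file
#'   order.
#' @export
read_fasta <- function(path, entity_class = c("target", "ncrna")) {
  entity_class <- match.arg(entity_class)
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(set))
  sequence_records(ids, as.character(set), entity_class)
}

#' Write sequence records to a FASTA file
#'
#' @param records a [sequence_records] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(unclass(records))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column interaction table as a binary adjacency matrix
#'
#' Edge lists are tab-separated with one `left_id<TAB>right_id` edge per
#' line.  An optional header line is tolerated: ids unknown to both lists are
#' an error anywhere except on line 1, where they are treated as column
#' names.  Repeated edges collapse to a single 1.
#'
#' @param path path to the edge-list file.
#' @param left_ids,right_ids ordered identifier vectors indexing the rows and
#'   columns of the result.
#' @return A binary `length(left_ids) x length(right_ids)` matrix with
#'   dimnames.
#' @export
read_interactions <- function(path, left_ids, right_ids) {
  if (!file.exists(path))
    stop("interaction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  A <- matrix(0, length(left_ids), length(right_ids),
              dimnames = list(left_ids, right_ids))
  if (!length(lines)) return(A)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("line ", bad[1L], " of ", path, " does not have two tab-separated columns")
  left <- trimws(vapply(parts, `[[`, "", 1L))
  right <- trimws(vapply(parts, `[[`, "", 2L))
  # header detection: unknown ids are only permitted on line 1
  if (length(left) >= 1L &&
      (!(left[1L] %in% left_ids) || !(right[1L] %in% right_ids))) {
    left <- left[-1L]
    right <- right[-1L]
    if (!length(left)) return(A)
  }
  miss_l <- setdiff(left, left_ids)
  if (length(miss_l))
    stop("unknown left id(s) in ", path, ": ", paste(unique(miss_l), collapse = ", "))
  miss_r <- setdiff(right, right_ids)
  if (length(miss_r))
    stop("unknown right id(s) in ", path, ": ", paste(unique(miss_r), collapse = ", "))
  A[cbind(match(left, left_ids), match(right, right_ids))] <- 1
  A
}

#' Write a binary adjacency matrix as a two-column edge list
#'
#' Inverse of [read_interactions()] (no header line is written).
#'
#' @param A binary matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(A, path) {
  idx <- which(A != 0, arr.ind = TRUE)
  df <- data.frame(left = rownames(A)[idx[, 1L]],
                   right = colnames(A)[idx[, 2L]])
  df <- df[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a disease-target-ncRNA tripartite network
#'
#' The network holds ordered identifier lists for the three node classes and
#' the two binary adjacency matrices: `A_DT` (diseases x targets) and `A_TR`
#' (targets x ncRNAs).  Identifier order is the order of the supplied
#' vectors and indexes all matrices consistently.
#'
#' @param diseases,targets,ncrnas ordered, duplicate-free identifier vectors.
#' @param A_DT binary matrix, `length(diseases) x length(targets)`.
#' @param A_TR binary matrix, `length(targets) x length(ncrnas)`.
#' @return An object of class `tripartite_network` with elements `diseases`,
#'   `targets`, `ncrnas`, `A_DT`, `A_TR`.
#' @export
tripartite_network <- function(diseases, targets, ncrnas, A_DT, A_TR) {
  diseases <- as.character(diseases)
  targets <- as.character(targets)
  ncrnas <- as.character(ncrnas)
  for (nm in c("diseases", "targets", "ncrnas")) {
    v <- get(nm)
    if (anyDuplicated(v))
      stop("duplicate ids in ", nm, ": ",
           paste(unique(v[duplicated(v)]), collapse = ", "))
  }
  A_DT <- as.matrix(A_DT)
  A_TR <- as.matrix(A_TR)
  if (!identical(dim(A_DT), c(length(diseases), length(targets))))
    stop("A_DT must be ", length(diseases), " x ", length(targets))
  if (!identical(dim(A_TR), c(length(targets), length(ncrnas))))
    stop("A_TR must be ", length(targets), " x ", length(ncrnas))
  if (!all(A_DT %in% c(0, 1)) || !all(A_TR %in% c(0, 1)))
    stop("adjacency matrices must be binary")
  dimnames(A_DT) <- list(diseases, targets)
  dimnames(A_TR) <- list(targets, ncrnas)
  structure(list(diseases = diseases, targets = targets, ncrnas = ncrnas,
                 A_DT = A_DT, A_TR = A_TR),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("Tripartite disease-target-ncRNA network\n")
  cat(sprintf("  %d diseases, %d targets, %d ncRNAs\n",
              length(x$diseases), length(x$targets), length(x$ncrnas)))
  cat(sprintf("  %d disease-target edges, %d target-ncRNA edges\n",
              sum(x$A_DT), sum(x$A_TR)))
  invisible(x)
}

#' Per-node degrees of a tripartite network
#'
#' A disease's degree is its row sum in `A_DT`; a target bridges both layers
#' so its degree is its column sum in `A_DT` plus its row sum in `A_TR`; an
#' ncRNA's degree is its column sum in `A_TR`.
#'
#' @param net a [tripartite_network].
#' @return Named numeric vector over all nodes (diseases, targets, ncRNAs in
#'   order).
#' @export
node_degrees <- function(net) {
  c(rowSums(net$A_DT),
    colSums(net$A_DT) + rowSums(net$A_TR),
    colSums(net$A_TR))
}

#' Degree statistics of a tripartite network
#'
#' Computes node count V, edge count E, average degree 2E/V and the
#' cumulative degree distribution (fraction of nodes with degree >= k for
#' k = 0, 1, ..., max degree).
#'
#' @param net a [tripartite_network].
#' @return An object of class `degree_summary`: list with `node_count`,
#'   `edge_count`, `average_degree`, and `cumulative_distribution` (a
#'   data.frame with columns `degree` and `fraction`).
#' @export
degree_summary <- function(net) {
  V <- length(net$diseases) + length(net$targets) + length(net$ncrnas)
  if (V == 0L) stop("empty network: no nodes")
  E <- sum(net$A_DT) + sum(net$A_TR)
  deg <- node_degrees(net)
  ks <- 0:max(deg)
  frac <- vapply(ks, function(k) mean(deg >= k), numeric(1))
  structure(list(node_count = V,
                 edge_count = E,
                 average_degree = 2 * E / V,
                 cumulative_distribution = data.frame(degree = ks,
                                                      fraction = frac)),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("Network degree summary: V = %d, E = %d, average degree = %.3f\n",
              x$node_count, x$edge_count, x$average_degree))
  invisible(x)
}

#' Export a degree summary for plotting
#'
#' Writes the cumulative degree distribution points as TSV (columns `degree`,
#' `fraction`), suitable for plotting degree-distribution curves.
#'
#' @param summary a [degree_summary] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_degree_summary <- function(summary, path) {
  utils::write.table(summary$cumulative_distribution, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
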