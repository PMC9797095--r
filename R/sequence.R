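# Sequence similarity, clustering and cluster-normalized aggregation.
#
# Benchmark metrics are averaged per sequence cluster before the global
# mean, so heavily re-deposited molecules do not dominate a benchmark.

#' Normalized global-alignment similarity of two RNA sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and linear
#' gap penalty -1, normalized by the length of the shorter sequence.  The
#' clustering distance used downstream is one minus this similarity, so a
#' distance threshold of 0.1 keeps sequences that are at least 90 percent
#' similar together.
#'
#' @param s,t RNA sequences over A, C, G, U
#' @return list with `score` (raw alignment score), `similarity`
#'   (score / min length) and `distance` (1 - similarity)
#' @export
nw_similarity <- function(s, t) {
  v1 <- check_sequence(s); v2 <- check_sequence(t)
  d1 <- Biostrings::DNAString(chartr("U", "T", paste(v1, collapse = "")))
  d2 <- Biostrings::DNAString(chartr("U", "T", paste(v2, collapse = "")))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(d1, d2, substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1,
                                       type = "global", scoreOnly = TRUE)
  sim <- aln / min(length(v1), length(v2))
  list(score = aln, similarity = sim, distance = 1 - sim)
}

#' Pairwise sequence distance matrix
#'
#' @param seqs character vector of RNA sequences (names become labels)
#' @export
sequence_distances <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- nw_similarity(seqs[i], seqs[j])$distance
  d
}

#' Complete-linkage clustering at a distance threshold
#'
#' Agglomerative complete-linkage clustering: repeatedly merges the pair of
#' clusters with the smallest complete-linkage (maximum pairwise) distance
#' while that distance stays within the threshold, so the maximum pairwise
#' distance inside any cluster never exceeds it.  Ties are broken
#' deterministically by lowest cluster index.
#'
#' @param distances symmetric distance matrix with zero diagonal
#' @param threshold complete-linkage merging threshold (default 0.1, i.e. 90
#'   percent intra-cluster similarity)
#' @return a `cluster_set`: list of member-index vectors plus the threshold
#' @export
complete_linkage <- function(distances, threshold = 0.1) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8) ||
      any(abs(diag(distances)) > 1e-12))
    stop("distances must be symmetric with zero diagonal")
  n <- nrow(distances)
  cl <- as.list(seq_len(n))
  D <- distances
  diag(D) <- Inf
  while (length(cl) > 1L) {
    m <- min(D)
    if (m > threshold) break
    hit <- which(D == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    cl[[i]] <- sort(c(cl[[i]], cl[[j]]))
    cl[[j]] <- NULL
    dnew <- pmax(D[i, ], D[j, ])[-j]
    D <- D[-j, -j, drop = FALSE]
    D[i, ] <- dnew
    D[, i] <- dnew
    D[i, i] <- Inf
  }
  clusters <- cl
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  # certificate: re-verify the similarity guarantee
  for (cl in clusters)
    if (length(cl) > 1L &&
        max(distances[cl, cl]) > threshold + 1e-12)
      stop("internal error: cluster violates the distance threshold")
  names(clusters) <- NULL
  structure(list(clusters = clusters, threshold = threshold,
                 membership = memb), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s) at complete-linkage threshold %.3g; sizes: %s\n",
              length(x$clusters), x$threshold,
              paste(lengths(x$clusters), collapse = " ")))
  invisible(x)
}

#' Cluster-normalized mean of a per-item metric
#'
#' Mean over clusters of the within-cluster means: every RNA family weighs
#' the same regardless of how many structures represent it.
#'
#' @param values named or positional numeric vector, one value per item
#' @param clusters a `cluster_set` over the same items
#' @export
cluster_normalized_mean <- function(values, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  idx <- unlist(clusters$clusters)
  if (any(idx > length(values)) || anyNA(values[idx]))
    stop("missing value for some clustered item")
  mean(vapply(clusters$clusters, function(cl) mean(values[cl]), 0))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file of RNA (or DNA; T is mapped to U) sequences
#' @return named character vector
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(chartr("Tt", "Uu", toupper(as.character(x))), names(x))
}
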