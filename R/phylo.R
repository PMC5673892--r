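# Methylation phylogenetics: Euclidean distances over CpG probes and
# distance-based trees (neighbor joining, balanced minimum evolution).

#' Euclidean distance matrix over all CpG probes
#'
#' d(i, j) = sqrt(sum over probes of (beta_i - beta_j)^2). Probes missing
#' in either member of a pair are dropped pairwise-complete; the number of
#' probes used per pair is recorded in the `"n_probes"` attribute.
#'
#' @param beta `beta_matrix` with >= 3 samples.
#' @return symmetric numeric matrix with zero diagonal and sample labels.
#' @export
beta_distances <- function(beta) {
  V <- beta$values
  if (ncol(V) < 3) stop_arg("need >= 3 samples for a distance matrix")
  if (!anyNA(V)) {
    D <- as.matrix(stats::dist(t(V)))
    attr(D, "n_probes") <- matrix(nrow(V), ncol(V), ncol(V),
                                  dimnames = dimnames(D))
    return(D)
  }
  n <- ncol(V)
  D <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  NP <- matrix(nrow(V), n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(V[, i]) & !is.na(V[, j])
    D[i, j] <- D[j, i] <- sqrt(sum((V[ok, i] - V[ok, j])^2))
    NP[i, j] <- NP[j, i] <- sum(ok)
  }
  attr(D, "n_probes") <- NP
  D
}

#' Balanced minimum-evolution length of a tree
#'
#' Pauplin's formula: L = sum over leaf pairs of d_ij * 2^(1 - p_ij),
#' where p_ij is the topological path length (number of edges) between
#' leaves i and j. For a tree whose branch lengths realize an additive
#' matrix this equals the total branch length.
#'
#' @param tree `phylo` object (unrooted, binary).
#' @param d distance matrix with the tree's tip labels.
#' @return the balanced tree-length objective.
#' @export
bme_length <- function(tree, d) {
  tu <- tree
  tu$edge.length <- rep(1, nrow(tu$edge))
  P <- stats::cophenetic(tu)             # topological path lengths
  labs <- tree$tip.label
  P <- P[labs, labs]
  dd <- as.matrix(d)[labs, labs]
  sum(dd[upper.tri(dd)] * 2^(1 - P[upper.tri(P)]))
}

#' Build a methylation phylogeny from a distance matrix
#'
#' Neighbor joining produces the topology; with `method = "bme"` the tree
#' is refined by nearest-neighbor-interchange moves under the balanced
#' minimum-evolution criterion (FastME's balanced variant). Negative
#' branch lengths are clamped to 0.
#'
#' @param d symmetric distance matrix (zero diagonal, unique labels).
#' @param method "bme" (default) or "nj".
#' @return `phylo` object (ape); serialize with [ape::write.tree()].
#' @export
build_tree <- function(d, method = c("bme", "nj")) {
  method <- match.arg(method)
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-9)
    stop_arg("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop_arg("distance matrix diagonal must be zero")
  if (anyDuplicated(rownames(D))) stop_arg("duplicate sample labels")
  tree <- if (method == "nj") ape::nj(stats::as.dist(D))
    else ape::fastme.bal(stats::as.dist(D), nni = TRUE, spr = FALSE,
                         tbr = FALSE)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
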