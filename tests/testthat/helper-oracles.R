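# Fixtures built in code and independent brute-force oracles used to
# freeze expected values. Oracles are straight-line re-derivations that
# never call the implementation paths they check.

# A hand-laid annotation: two genes (one per strand) on chr1, one CpG
# island overlapping the promoter of gA only, probes at known positions.
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 50000L),
    body_start = c(10000L, 30000L), body_end = c(30000L, 50000L),
    stringsAsFactors = FALSE)
  promoters <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(8500L, 49500L), end = c(10500L, 51500L),
    stringsAsFactors = FALSE)
  cpg_islands <- data.frame(island_id = "cgi1", chrom = "chr1",
                            start = 9800L, end = 10200L,
                            stringsAsFactors = FALSE)
  cgi_promoters <- data.frame(gene_id = "gA", chrom = "chr1",
                              start = 9800L, end = 10200L,
                              stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = paste0("p", 1:10), chrom = "chr1",
    pos = c(9000L, 9900L, 10100L,          # gA promoter (2 in island)
            15000L, 20000L, 25000L,        # gA body
            49600L, 50200L, 51000L,        # gB promoter
            40000L),                       # gB body (only 1 probe)
    stringsAsFactors = FALSE)
  structure(list(genes = genes, promoters = promoters,
                 cpg_islands = cpg_islands, cgi_promoters = cgi_promoters,
                 probes = probes), class = "annotation_set")
}

# independent nine-state classifier: plain if/else on one triple
oracle_nine_state <- function(cna_state, beta, normal_mean, delta = 0.20) {
  cna <- if (cna_state < 0) "del" else if (cna_state > 0) "amp" else "none"
  meth <- if (beta > normal_mean + delta) "hyper"
    else if (beta < normal_mean - delta) "hypo" else "none"
  if (cna == "del" && meth == "hyper") "del+hyper"
  else if (cna == "del" && meth == "none") "del_only"
  else if (cna == "del" && meth == "hypo") "del+hypo"
  else if (cna == "amp" && meth == "hyper") "amp+hyper"
  else if (cna == "amp" && meth == "none") "amp_only"
  else if (cna == "amp" && meth == "hypo") "amp+hypo"
  else if (meth == "hyper") "hyper_only"
  else if (meth == "hypo") "hypo_only"
  else "unaltered"
}

# brute-force optimal changepoint segmentation by enumerating all
# placements (for short series)
oracle_segment_cost <- function(x, penalty) {
  n <- length(x)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # changepoint after bin i
    bounds <- c(0, cps, n)
    cost <- penalty * (length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      seg <- x[(bounds[k] + 1):bounds[k + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    best <- min(best, cost)
  }
  best
}

# exhaustive best-subset NNLS refit (subsets of size <= max_size)
oracle_best_subset_sse <- function(spectrum, refs, max_size = 4) {
  b <- spectrum / sum(spectrum)
  sigs <- seq_len(nrow(refs))
  best <- sum(b^2)
  for (size in seq_len(max_size)) {
    for (sub in utils::combn(sigs, size, simplify = FALSE)) {
      A <- refs[sub, , drop = FALSE]
      w <- pracma::lsqnonneg(t(A), b)$x
      if (sum(w) > 1) w <- w / sum(w)
      best <- min(best, sum((b - as.numeric(w %*% A))^2))
    }
  }
  best
}

# additive distance matrix of a 4-taxon tree ((a:1,b:2):5,(c:3,d:4))
additive_4taxon <- function() {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 1, b = 2, c = 3, d = 4); int <- 5
  d["a", "b"] <- bl["a"] + bl["b"]
  d["c", "d"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d"))
    d[x, y] <- bl[x] + int + bl[y]
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# additive matrix from a random 5-taxon tree via ape's path lengths
additive_5taxon <- function(seed = 42) {
  set.seed(seed)
  tr <- ape::rtree(5, rooted = FALSE, br = function(n) runif(n, 0.5, 2))
  list(tree = tr, d = stats::cophenetic(tr))
}
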