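# Copy-number module: probe-level log2 ratios versus pooled normals,
# fixed-size probe binning, exact least-squares changepoint segmentation,
# gene-level discretization and permutation-based recurrence scoring.

#' Probe-level log2 ratio of one tumor versus pooled normals
#'
#' log2(tumor intensity / mean normal intensity) per probe, then
#' median-centered to 0 so that global array-intensity scale differences
#' between samples cancel.
#'
#' @param intensity `intensity_matrix`.
#' @param tumor_sample tumor column id.
#' @param normal_samples >= 2 normal column ids.
#' @param annotation `annotation_set` supplying probe coordinates.
#' @return data.frame(probe_id, chrom, pos, log2) sorted by chrom, pos.
#' @export
log2_ratio <- function(intensity, tumor_sample, normal_samples, annotation) {
  V <- intensity$values
  if (length(normal_samples) < 2) stop_arg("need >= 2 normal samples")
  if (!all(c(tumor_sample, normal_samples) %in% colnames(V)))
    stop_arg("unknown sample id")
  if (any(V[, c(tumor_sample, normal_samples)] <= 0))
    stop_arg("intensities must be strictly positive")
  ref <- rowMeans(V[, normal_samples, drop = FALSE])
  lr <- log2(V[, tumor_sample] / ref)
  lr <- lr - stats::median(lr)
  p <- annotation$probes
  p <- p[match(rownames(V), p$probe_id), ]
  out <- data.frame(probe_id = p$probe_id, chrom = p$chrom, pos = p$pos,
                    log2 = lr, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), ]
}

#' Group probes into genomic bins of at least a fixed size
#'
#' Greedy left-to-right accumulation per chromosome: a bin closes once it
#' holds `min_probes_per_bin` probes; a trailing undersized bin is merged
#' into its predecessor, so no emitted bin is ever smaller than the
#' minimum. Bin value = mean probe log2; the bin interval spans its member
#' probes. Chromosomes with fewer probes than the minimum are skipped with
#' a warning.
#'
#' @param track output of [log2_ratio()].
#' @param min_probes_per_bin minimum probes per bin (default 5).
#' @return data.frame(chrom, start, end, n_probes, log2).
#' @export
bin_probes <- function(track, min_probes_per_bin = 5) {
  out <- list()
  for (cc in unique(track$chrom)) {
    tr <- track[track$chrom == cc, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    n <- nrow(tr)
    if (n < min_probes_per_bin) {
      warning("chromosome ", cc, " has fewer than ", min_probes_per_bin,
              " probes; skipped")
      next
    }
    n_bins <- n %/% min_probes_per_bin
    sizes <- rep(min_probes_per_bin, n_bins)
    sizes[n_bins] <- sizes[n_bins] + n %% min_probes_per_bin  # merge tail
    idx <- rep(seq_len(n_bins), sizes)
    out[[cc]] <- data.frame(
      chrom = cc,
      start = tapply(tr$pos, idx, min),
      end = tapply(tr$pos, idx, max) + 1L,
      n_probes = as.integer(table(idx)),
      log2 = as.numeric(tapply(tr$log2, idx, mean)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop_arg("no chromosome had enough probes to bin")
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Exact least-squares changepoint segmentation of one numeric series:
# minimize sum of squared residuals + penalty * (number of segments),
# by O(n^2) dynamic programming over last-changepoint positions.
segment_dp <- function(x, penalty) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  segcost <- function(i, j) {            # cost of segment x[i..j], 1-based
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  F <- c(0, rep(Inf, n))                 # F[j+1] = best cost of x[1..j]
  last <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      v <- F[i] + segcost(i, j) + penalty
      if (v < F[j + 1]) { F[j + 1] <- v; last[j] <- i }
    }
  }
  ends <- integer(0); j <- n
  while (j > 0) { ends <- c(j, ends); j <- last[j] - 1L }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(start_bin = starts, end_bin = ends,
             mean = vapply(seq_along(starts), function(k)
               mean(x[starts[k]:ends[k]]), numeric(1)))
}

# default smoothness penalty: BIC-like, with the noise scale estimated
# robustly from successive bin differences
default_penalty <- function(x) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (sigma == 0) sigma <- 1e-6
  2 * sigma^2 * log(length(x))
}

#' Segment a binned log2 track into copy-number segments
#'
#' Exact least-squares changepoint segmentation per chromosome: the
#' segmentation minimizing (sum of squared deviations from segment means)
#' + penalty x (number of segments), solved by dynamic programming —
#' guaranteed optimal, verified against brute-force enumeration in the
#' test suite.
#'
#' @param binned output of [bin_probes()].
#' @param penalty per-segment penalty; NULL for a BIC-like default
#'   (2 * sigma^2 * log n, sigma from the median absolute successive
#'   difference).
#' @param sample sample id stamped on the output.
#' @return `segment_set`: data.frame(sample, chrom, start, end, start_bin,
#'   end_bin, n_bins, mean_log2); segments tile the binned positions of
#'   each chromosome.
#' @export
segment_track <- function(binned, penalty = NULL, sample = "S1") {
  if (any(!is.finite(binned$log2))) stop_arg("non-finite bin values")
  out <- list()
  for (cc in unique(binned$chrom)) {
    b <- binned[binned$chrom == cc, , drop = FALSE]
    pen <- if (is.null(penalty)) default_penalty(b$log2) else penalty
    dp <- segment_dp(b$log2, pen)
    out[[cc]] <- data.frame(
      sample = sample, chrom = cc,
      start = b$start[dp$start_bin], end = b$end[dp$end_bin],
      start_bin = dp$start_bin, end_bin = dp$end_bin,
      n_bins = dp$end_bin - dp$start_bin + 1L,
      mean_log2 = dp$mean, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("segment_set", "data.frame"))
}

discretize_log2 <- function(L2, th, missing = NULL) {
  ST <- matrix(0L, nrow(L2), ncol(L2), dimnames = dimnames(L2))
  ST[L2 > th["t_amp"]] <- 1L
  ST[L2 > th["t_amp2"]] <- 2L
  ST[L2 < th["t_del"]] <- -1L
  ST[L2 < th["t_del2"]] <- -2L
  if (is.null(missing))
    missing <- matrix(FALSE, nrow(L2), ncol(L2), dimnames = dimnames(L2))
  ST[missing] <- 0L
  structure(list(log2 = L2, state = ST, missing = missing,
                 thresholds = th), class = "gene_cna")
}

#' Build a gene-level CNA object from a log2 matrix
#'
#' Discretizes a genes x samples log2-ratio matrix with the standard
#' thresholds (strict outward comparisons), for callers that already hold
#' gene-level values (e.g. external copy-number calls) and want to run
#' [recurrence()] or [classify_states()].
#'
#' @param log2 genes x samples numeric matrix with dimnames.
#' @param thresholds as in [gene_calls()].
#' @return `gene_cna` object.
#' @export
gene_cna_from_log2 <- function(log2,
                               thresholds = c(t_amp = 0.2, t_del = -0.2,
                                              t_amp2 = 1.0, t_del2 = -1.0)) {
  stopifnot(is.matrix(log2), !is.null(rownames(log2)),
            !is.null(colnames(log2)))
  discretize_log2(log2, thresholds)
}

#' Discretize segments into gene-level copy-number states
#'
#' Gene log2 = length-weighted mean of the segments overlapping the gene
#' body; states use strict outward threshold comparisons: +2 if
#' log2 > t_amp2, +1 if > t_amp, -2 if < t_del2, -1 if < t_del, else 0.
#' Genes overlapping no segment get state 0 and a missing-data flag.
#'
#' @param segments `segment_set` for one or more samples.
#' @param annotation `annotation_set`.
#' @param thresholds named vector with t_amp, t_del, t_amp2, t_del2;
#'   defaults +/-0.2 (single copy) and +/-1.0 (high level).
#' @return `gene_cna`: list with matrices `log2`, `state` (genes x
#'   samples, integer in -2..2) and `missing` (logical).
#' @export
gene_calls <- function(segments, annotation,
                       thresholds = c(t_amp = 0.2, t_del = -0.2,
                                      t_amp2 = 1.0, t_del2 = -1.0)) {
  th <- thresholds
  if (!(th["t_del2"] < th["t_del"] && th["t_del"] < 0 &&
        0 < th["t_amp"] && th["t_amp"] < th["t_amp2"]))
    stop_arg("thresholds must satisfy t_del2 < t_del < 0 < t_amp < t_amp2")
  g <- annotation$genes
  samples <- unique(segments$sample)
  L2 <- matrix(NA_real_, nrow(g), length(samples),
               dimnames = list(g$gene_id, samples))
  MISS <- matrix(FALSE, nrow(g), length(samples),
                 dimnames = list(g$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      sc <- seg[seg$chrom == g$chrom[i], , drop = FALSE]
      ov <- interval_overlap(sc$start, sc$end, g$body_start[i], g$body_end[i])
      if (sum(ov) == 0) { MISS[i, s] <- TRUE; L2[i, s] <- 0; next }
      L2[i, s] <- sum(sc$mean_log2 * ov) / sum(ov)
    }
  }
  discretize_log2(L2, th, MISS)
}

#' Score copy-number recurrence across samples with a permutation G-score
#'
#' Per direction, a gene's G-score sums the signed alteration amplitudes
#' across samples: G_amp = sum over samples of max(0, log2), G_del = sum
#' of max(0, -log2) — so only samples deviating in the scored direction
#' contribute, and the score combines alteration frequency with amplitude.
#' The null distribution is built by independently permuting each sample's
#' gene-level log2 values across the genome (which preserves every
#' sample's amplitude distribution) and pooling the permuted gene scores;
#' p = smoothed fraction of pooled null scores >= observed, BH-adjusted
#' across genes within each direction.
#'
#' @param gene_cna `gene_cna` (>= 5 samples).
#' @param n_perm number of permutations (>= 100; >= 1000 recommended).
#' @param seed integer seed.
#' @return data.frame: gene_id, direction ("amp"/"del"), frequency
#'   (fraction of samples with a discrete call in that direction),
#'   avg_amplitude, g_score, p_value, q_value.
#' @export
recurrence <- function(gene_cna, n_perm = 2000, seed = 1) {
  L2 <- gene_cna$log2
  ST <- gene_cna$state
  if (ncol(L2) < 5) stop_arg("need >= 5 samples for recurrence scoring")
  if (n_perm < 100) stop_arg("n_perm < 100: null too coarse")
  set.seed(substream_seed(seed, "recurrence"))
  g_dir <- function(l2) list(amp = rowSums(pmax(l2, 0)),
                             del = rowSums(pmax(-l2, 0)))
  obs <- g_dir(L2)
  n_genes <- nrow(L2)
  null_amp <- matrix(0, n_genes, n_perm)
  null_del <- matrix(0, n_genes, n_perm)
  for (b in seq_len(n_perm)) {
    perm <- apply(L2, 2, function(col) col[sample.int(n_genes)])
    pg <- g_dir(perm)
    null_amp[, b] <- pg$amp
    null_del[, b] <- pg$del
  }
  p_pool <- function(obs_g, null_mat) {
    null_sorted <- sort(as.numeric(null_mat))
    N <- length(null_sorted)
    n_ge <- N - findInterval(obs_g - 1e-12, null_sorted)
    (1 + n_ge) / (1 + N)
  }
  res <- lapply(c("amp", "del"), function(d) {
    st_hit <- if (d == "amp") ST > 0 else ST < 0
    p <- p_pool(obs[[d]], if (d == "amp") null_amp else null_del)
    freq <- rowMeans(st_hit)
    data.frame(gene_id = rownames(L2), direction = d,
               frequency = freq,
               avg_amplitude = ifelse(rowSums(st_hit) > 0,
                                      obs[[d]] / rowSums(st_hit), 0),
               g_score = obs[[d]],
               p_value = p,
               q_value = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
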