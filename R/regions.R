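# Region-level differential methylation: probe-to-region aggregation,
# combined-rank calling, cross-cohort validation and paired testing.

#' Aggregate probe betas to regulatory regions
#'
#' Region value = unweighted mean of member probe betas (missing values
#' ignored). Regions with fewer than `min_probes` mapped probes are
#' excluded, as are regions where fewer than `min_probes` probes are
#' observed (non-missing) in more than 20% of samples.
#'
#' @param beta `beta_matrix`.
#' @param annotation `annotation_set`.
#' @param region_type one of "promoter", "gene_body", "cpg_island",
#'   "cgi_promoter".
#' @param min_probes minimum member probes per region (default 3).
#' @return object of class `region_beta`: list with `values` (regions x
#'   samples), `n_probes`, `region_type`, `regions` (coordinate table) and
#'   `groups`.
#' @export
aggregate_regions <- function(beta, annotation, region_type = "promoter",
                              min_probes = 3) {
  regs <- region_intervals(annotation, region_type)
  p <- annotation$probes
  p <- p[p$probe_id %in% rownames(beta$values), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(regs), ncol(beta$values),
                 dimnames = list(regs$region_id, colnames(beta$values)))
  np <- integer(nrow(regs))
  low_obs <- logical(nrow(regs))
  for (i in seq_len(nrow(regs))) {
    member <- p$probe_id[p$chrom == regs$chrom[i] &
                           pos_in_interval(p$pos, regs$start[i], regs$end[i])]
    np[i] <- length(member)
    if (np[i] == 0) next
    sub <- beta$values[member, , drop = FALSE]
    vals[i, ] <- colMeans(sub, na.rm = TRUE)
    n_obs <- colSums(!is.na(sub))
    low_obs[i] <- mean(n_obs < min_probes) > 0.2
  }
  drop <- np < min_probes | low_obs
  if (any(np == 0))
    warning(sum(np == 0), " region(s) with zero probes excluded")
  structure(list(values = vals[!drop, , drop = FALSE],
                 n_probes = stats::setNames(np[!drop], regs$region_id[!drop]),
                 region_type = region_type,
                 regions = regs[!drop, , drop = FALSE],
                 groups = beta$groups),
            class = "region_beta")
}

# vectorised two-sample Welch t-test over rows of a matrix
welch_rows <- function(A, B) {
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  nA <- ncol(A); nB <- ncol(B)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[is.nan(t)] <- 1                      # zero variance, zero difference
  p[is.infinite(t)] <- 0                 # zero variance, real difference
  list(t = t, p = p)
}

#' Call differentially methylated regions with the combined-rank criterion
#'
#' Three metrics are computed per region — the difference in group mean
#' methylation, the quotient of group means, and a two-group p-value — and
#' each is ranked best-first (largest absolute difference, most extreme
#' quotient, smallest p). The combined rank is the maximum of the three;
#' regions whose combined rank is at most the cutoff are flagged
#' significant. Cutoff "auto" equals the number of regions with
#' BH-adjusted p < 0.05 and |difference| >= 0.1.
#'
#' @param region_beta `region_beta`.
#' @param groupA,groupB character vectors of sample ids (each >= 2);
#'   conventionally groupA = tumors, groupB = normals, so a positive
#'   difference means hypermethylation in A.
#' @param rank_cutoff integer cutoff or "auto".
#' @param method "welch" (default) or "limma" (moderated t via eBayes).
#' @return data.frame (one row per region): mean_A, mean_B, mean_diff,
#'   mean_quot, p_value, q_value, rank_diff, rank_quot, rank_p,
#'   combined_rank, significant, direction.
#' @export
differential_regions <- function(region_beta, groupA, groupB,
                                 rank_cutoff = "auto", method = "welch") {
  V <- region_beta$values
  if (!all(c(groupA, groupB) %in% colnames(V)))
    stop_arg("unknown sample ids in groups")
  if (length(groupA) < 2 || length(groupB) < 2)
    stop_arg("each group needs at least 2 samples")
  A <- V[, groupA, drop = FALSE]
  B <- V[, groupB, drop = FALSE]
  mean_A <- rowMeans(A, na.rm = TRUE)
  mean_B <- rowMeans(B, na.rm = TRUE)
  mean_diff <- mean_A - mean_B
  mean_quot <- ifelse(mean_B == 0,
                      (mean_A + 0.01) / (mean_B + 0.01),
                      mean_A / mean_B)
  if (method == "limma") {
    design <- cbind(Intercept = 1,
                    A = c(rep(1, length(groupA)), rep(0, length(groupB))))
    fit <- limma::eBayes(limma::lmFit(cbind(A, B), design))
    p <- fit$p.value[, "A"]
  } else {
    p <- welch_rows(A, B)$p
  }
  quot_extreme <- pmax(mean_quot, 1 / mean_quot)
  rank_diff <- rank(-abs(mean_diff), ties.method = "max")
  rank_quot <- rank(-quot_extreme, ties.method = "max")
  rank_p <- rank(p, ties.method = "max")
  combined <- pmax(rank_diff, rank_quot, rank_p)
  q <- stats::p.adjust(p, method = "BH")
  cutoff <- if (identical(rank_cutoff, "auto"))
    sum(q < 0.05 & abs(mean_diff) >= 0.1) else as.integer(rank_cutoff)
  data.frame(region_id = rownames(V),
             mean_A = mean_A, mean_B = mean_B,
             mean_diff = mean_diff, mean_quot = mean_quot,
             p_value = p, q_value = q,
             rank_diff = rank_diff, rank_quot = rank_quot, rank_p = rank_p,
             combined_rank = combined,
             significant = combined <= cutoff,
             direction = ifelse(mean_diff > 0, "hyper",
                                ifelse(mean_diff < 0, "hypo", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-cohort validation of differential regions
#'
#' A discovery-significant region is validated iff it is significant in
#' the validation table with the same direction.
#'
#' @param discovery,validation outputs of [differential_regions()] over
#'   the same region universe.
#' @return list(validated = region ids, validation_rate = validated /
#'   discovery-significant; NA when discovery has no significant region).
#' @export
validate_regions <- function(discovery, validation) {
  if (length(intersect(discovery$region_id, validation$region_id)) == 0)
    stop_arg("discovery and validation share no regions")
  if (!setequal(discovery$region_id, validation$region_id))
    stop_arg("discovery and validation must cover the same region universe")
  v <- validation[match(discovery$region_id, validation$region_id), ]
  hit <- discovery$significant
  ok <- hit & v$significant & discovery$direction == v$direction
  list(validated = discovery$region_id[ok],
       validation_rate = if (sum(hit) == 0) NA_real_ else sum(ok) / sum(hit))
}

#' Paired primary-versus-metastasis differential methylation
#'
#' Standard paired t-test per region on metastasis minus primary values,
#' with BH adjustment. Regions whose paired differences have zero variance
#' get NA p-values and are flagged `degenerate`.
#'
#' @param region_beta `region_beta`.
#' @param pairs data.frame with columns `primary` and `metastasis`
#'   (sample ids; >= 3 pairs).
#' @return data.frame: region_id, mean_paired_diff, t, p_value, q_value,
#'   degenerate.
#' @export
paired_differential <- function(region_beta, pairs) {
  V <- region_beta$values
  stopifnot(all(c("primary", "metastasis") %in% names(pairs)))
  if (nrow(pairs) < 3) stop_arg("need at least 3 pairs")
  if (!all(c(pairs$primary, pairs$metastasis) %in% colnames(V)))
    stop_arg("unmatched sample id in pairs")
  D <- V[, pairs$metastasis, drop = FALSE] - V[, pairs$primary, drop = FALSE]
  n <- ncol(D)
  m <- rowMeans(D)
  s <- apply(D, 1, stats::sd)
  degenerate <- s < 1e-10                # zero variance up to fp rounding
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  near0 <- abs(m) < 1e-10
  p[degenerate & near0] <- 1             # no change at all: trivially null
  p[degenerate & !near0] <- NA_real_     # constant nonzero shift: sentinel
  data.frame(region_id = rownames(V), mean_paired_diff = m, t = t,
             p_value = p, q_value = stats::p.adjust(p, "BH"),
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}
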