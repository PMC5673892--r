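# Gene-state integration: cross-classification of gene-level copy number
# (deleted / none / amplified) with promoter differential methylation
# (hyper / none / hypo) into nine categories, recurrence ranking, and
# annotation against published cancer-gene lists.

NINE_STATES <- c("del+hyper", "del_only", "hyper_only", "del+hypo",
                 "unaltered", "amp+hyper", "hypo_only", "amp_only",
                 "amp+hypo")

nine_state_label <- function(cna, meth) {
  # cna in {-1, 0, 1} (sign of the discrete call), meth in
  # {"hyper", "none", "hypo"}
  ifelse(cna < 0,
         ifelse(meth == "hyper", "del+hyper",
                ifelse(meth == "hypo", "del+hypo", "del_only")),
  ifelse(cna > 0,
         ifelse(meth == "hyper", "amp+hyper",
                ifelse(meth == "hypo", "amp+hypo", "amp_only")),
         ifelse(meth == "hyper", "hyper_only",
                ifelse(meth == "hypo", "hypo_only", "unaltered"))))
}

#' Classify genes x samples into the nine integration states
#'
#' A tumor is called hyper-/hypomethylated at a gene when its promoter
#' beta lies above/below the normal-tissue mean by more than `meth_delta`
#' (absolute beta difference, the default reading of a "20%" methylation
#' cutoff) or by more than `meth_delta` x normal mean (mode "relative").
#' The copy-number axis is the sign of the discrete gene state (any
#' magnitude). The two calls combine into the nine-way state.
#'
#' @param gene_cna `gene_cna` from [gene_calls()].
#' @param promoter_beta `region_beta` of promoter regions (tumor columns
#'   are classified).
#' @param normal_means named per-gene mean promoter beta of the normal
#'   group; NULL to compute from `promoter_beta`'s "normal" samples.
#' @param meth_delta methylation cutoff (default 0.20).
#' @param meth_mode "absolute" (default) or "relative".
#' @return `nine_state`: list with `state` (genes x samples character
#'   matrix over the nine categories), `cna_sign`, `meth_call` and
#'   `flagged` (genes missing from one input, other axis treated as
#'   "none").
#' @export
classify_states <- function(gene_cna, promoter_beta, normal_means = NULL,
                            meth_delta = 0.20, meth_mode = "absolute") {
  if (is.null(normal_means)) {
    nrm <- names(promoter_beta$groups)[promoter_beta$groups == "normal"]
    if (length(nrm) == 0) stop_arg("no normal samples to compute normal_means")
    normal_means <- rowMeans(promoter_beta$values[, nrm, drop = FALSE],
                             na.rm = TRUE)
  }
  if (any(normal_means < 0 | normal_means > 1, na.rm = TRUE))
    stop_arg("normal_means must be in [0, 1]")
  samples <- intersect(colnames(gene_cna$state),
                       colnames(promoter_beta$values))
  if (length(samples) == 0) samples <- colnames(gene_cna$state)
  genes <- union(rownames(gene_cna$state), rownames(promoter_beta$values))
  if (length(intersect(rownames(gene_cna$state),
                       rownames(promoter_beta$values))) == 0)
    stop_arg("gene universes of the two inputs do not overlap")
  cna_sign <- matrix(0L, length(genes), length(samples),
                     dimnames = list(genes, samples))
  meth_call <- matrix("none", length(genes), length(samples),
                      dimnames = list(genes, samples))
  flagged <- matrix(FALSE, length(genes), length(samples),
                    dimnames = list(genes, samples))
  in_cna <- genes %in% rownames(gene_cna$state)
  cna_sign[in_cna, ] <- sign(gene_cna$state[genes[in_cna],
                                            samples, drop = FALSE])
  flagged[!in_cna, ] <- TRUE
  in_meth <- genes %in% rownames(promoter_beta$values) &
    genes %in% names(normal_means)
  if (any(in_meth)) {
    b <- promoter_beta$values[genes[in_meth], samples, drop = FALSE]
    nm <- normal_means[genes[in_meth]]
    lo <- if (meth_mode == "absolute") nm - meth_delta else nm * (1 - meth_delta)
    hi <- if (meth_mode == "absolute") nm + meth_delta else nm * (1 + meth_delta)
    mc <- matrix("none", nrow(b), ncol(b), dimnames = dimnames(b))
    mc[b > hi] <- "hyper"
    mc[b < lo] <- "hypo"
    meth_call[genes[in_meth], ] <- mc
  }
  flagged[!in_meth, ] <- TRUE
  state <- matrix(nine_state_label(cna_sign, meth_call),
                  length(genes), length(samples),
                  dimnames = list(genes, samples))
  structure(list(state = state, cna_sign = cna_sign, meth_call = meth_call,
                 flagged = flagged, meth_delta = meth_delta,
                 meth_mode = meth_mode),
            class = "nine_state")
}

#' Rank genes by recurrence of function-loss or function-gain aberrations
#'
#' Loss events are states containing a deletion and/or promoter
#' hypermethylation; gain events contain an amplification and/or
#' hypomethylation. Mixed states (e.g. "del+hypo") therefore count toward
#' both directions. Genes are ordered by descending number of affected
#' samples, ties broken lexicographically by gene id.
#'
#' @param states `nine_state`.
#' @param direction "loss" or "gain".
#' @return data.frame(gene_id, n_affected, frequency) in rank order.
#' @export
rank_genes <- function(states, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  S <- states$state
  hit_states <- if (direction == "loss")
    NINE_STATES[grepl("del|hyper", NINE_STATES)]
  else NINE_STATES[grepl("amp|hypo", NINE_STATES)]
  hits <- matrix(S %in% hit_states, nrow(S), ncol(S))
  n <- rowSums(hits)
  ord <- order(-n, rownames(S))
  data.frame(gene_id = rownames(S)[ord], n_affected = n[ord],
             frequency = n[ord] / ncol(S), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Annotate genes against published cancer-gene lists
#'
#' Each list file holds one gene symbol per line (or a TSV whose first
#' column is the symbol); matching is exact but case-insensitive.
#'
#' @param genes character vector of gene symbols.
#' @param list_files named character vector of file paths; names become
#'   the membership labels.
#' @return list with `membership` (data.frame gene x list logical) and
#'   `summary` (data.frame list, n_matched).
#' @export
annotate_lists <- function(genes, list_files) {
  if (is.null(names(list_files)) || any(names(list_files) == ""))
    names(list_files) <- basename(unname(list_files))
  M <- matrix(FALSE, length(genes), length(list_files),
              dimnames = list(genes, names(list_files)))
  for (nm in names(list_files)) {
    f <- list_files[[nm]]
    if (!file.exists(f)) stop_arg("list file not found: %s", f)
    lines <- readLines(f, warn = FALSE)
    if (length(lines) == 0) {
      warning("empty list file: ", f)
      next
    }
    symbols <- toupper(trimws(vapply(strsplit(lines, "\t"), `[`, "", 1)))
    symbols <- symbols[symbols != ""]
    M[, nm] <- toupper(genes) %in% symbols
  }
  list(membership = as.data.frame(M),
       summary = data.frame(list = colnames(M), n_matched = colSums(M),
                            row.names = NULL))
}
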