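# Reference-based cell-type deconvolution by constrained projection onto
# sorted reference methylomes, plus a LUMP-style purity estimate.

#' Select cell-type discriminating probes from a reference panel
#'
#' For each cell type, the `k_per_type` probes with the largest margin
#' above all other types (type beta minus the maximum other-type beta)
#' and the `k_per_type` with the largest margin below (type beta minus
#' the minimum other-type beta, most negative first) are taken; the union
#' is returned deduplicated.
#'
#' @param panel `reference_panel`.
#' @param k_per_type probes per cell type and direction (>= 1; capped with
#'   a warning when the panel is smaller).
#' @return character vector of probe ids.
#' @export
select_sites <- function(panel, k_per_type = 50) {
  if (k_per_type < 1) stop_arg("k_per_type must be >= 1")
  B <- panel$betas
  n_types <- nrow(B)
  k <- min(k_per_type, ncol(B))
  if (k < k_per_type)
    warning("k_per_type capped at ", k, " (panel has ", ncol(B), " probes)")
  sel <- character(0)
  any_signal <- FALSE
  for (i in seq_len(n_types)) {
    others <- B[-i, , drop = FALSE]
    up <- B[i, ] - apply(others, 2, max)
    dn <- B[i, ] - apply(others, 2, min)
    if (any(up != 0) || any(dn != 0)) any_signal <- TRUE
    sel <- c(sel,
             colnames(B)[order(up, decreasing = TRUE)[seq_len(k)]],
             colnames(B)[order(dn)[seq_len(k)]])
  }
  if (!any_signal) warning("all discriminating scores are zero; panel rows identical?")
  unique(sel)
}

#' Estimate cell-type composition by constrained projection
#'
#' Solves a non-negative least-squares fit of each sample's beta values on
#' the reference profiles restricted to the selected sites, then
#' renormalizes the weights to sum to 1 (the regression-calibration-style
#' constrained projection used for methylome deconvolution).
#'
#' @param sample_betas named numeric vector (one sample) or probes x
#'   samples matrix covering `sites`.
#' @param panel `reference_panel`.
#' @param sites probe ids to fit on (e.g. from [select_sites()]).
#' @return data.frame: one row per sample, one column per cell type
#'   (proportions summing to 1) plus `residual` (NNLS residual norm).
#' @export
estimate_composition <- function(sample_betas, panel, sites) {
  if (length(sites) == 0) stop_arg("empty site set")
  B <- panel$betas
  if (!all(sites %in% colnames(B))) stop_arg("sites missing from panel")
  dup <- which(duplicated(round(B[, sites, drop = FALSE], 12)))
  if (length(dup)) {
    ref <- apply(round(B[, sites, drop = FALSE], 12), 1, paste, collapse = ",")
    groups <- split(rownames(B), ref)
    bad <- groups[vapply(groups, length, 1L) > 1][[1]]
    stop_arg("collinear cell types in panel: %s", paste(bad, collapse = ", "))
  }
  if (is.null(dim(sample_betas)))
    sample_betas <- matrix(sample_betas, ncol = 1,
                           dimnames = list(names(sample_betas), "sample1"))
  if (!all(sites %in% rownames(sample_betas)))
    stop_arg("sample does not cover all selected sites")
  A <- t(B[, sites, drop = FALSE])       # sites x types design
  res <- lapply(colnames(sample_betas), function(s) {
    y <- sample_betas[sites, s]
    fit <- pracma::lsqnonneg(A, y)
    w <- fit$x
    resid <- sqrt(sum((y - A %*% w)^2))
    if (sum(w) == 0) w[] <- 1 / length(w) else w <- w / sum(w)
    c(stats::setNames(w, rownames(B)), residual = resid)
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- colnames(sample_betas)
  out
}

#' LUMP-style tumor purity from leukocyte-unmethylated probes
#'
#' Purity = min(1, mean beta over the leukocyte-unmethylated panel /
#' 0.85): probes unmethylated in leukocytes read low in immune-
#' contaminated samples, so low panel methylation implies low purity.
#'
#' @param sample_betas named numeric beta vector for one sample.
#' @param panel_probes probe ids of the leukocyte-unmethylated panel.
#' @param scale saturation constant (default 0.85).
#' @return purity in [0, 1].
#' @export
lump_purity <- function(sample_betas, panel_probes, scale = 0.85) {
  present <- intersect(panel_probes, names(sample_betas))
  if (length(present) == 0) stop_arg("no panel probes present in sample")
  if (length(present) < 10)
    warning("only ", length(present), " panel probes present; estimate unstable")
  min(1, mean(sample_betas[present], na.rm = TRUE) / scale)
}
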