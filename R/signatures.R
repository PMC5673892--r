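# Mutational signature module: 96-channel trinucleotide spectra and
# refitting against a fixed reference signature matrix.

#' The 96 trinucleotide substitution channels
#'
#' Channels follow the pyrimidine-centric convention: six substitution
#' classes (C>A, C>G, C>T, T>A, T>C, T>G), each combined with the 16
#' flanking-base contexts in alphabetical order, labelled e.g. `"A[C>A]A"`.
#' Mutations whose reference base is a purine are reverse-complemented into
#' this frame before counting.
#'
#' @return character vector of 96 channel labels, in canonical order.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (p5 in bases) for (p3 in bases) {
      out <- c(out, paste0(p5, "[", s, "]", p3))
    }
  }
  out
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), character(1)))
}

# Map (ref, alt, trinucleotide context) to a channel label, applying the
# pyrimidine normalization. Returns NA for inconsistent records.
mutation_channel <- function(ref, alt, context) {
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- nchar(context) == 3 & substr(context, 2, 2) == ref & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  pur <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt; ctx <- context
  if (any(pur)) {
    r[pur] <- chartr("AG", "TC", ref[pur])
    a[pur] <- chartr("ACGT", "TGCA", alt[pur])
    ctx[pur] <- revcomp(context[pur])
  }
  out[ok] <- paste0(substr(ctx[ok], 1, 1), "[", r[ok], ">", a[ok], "]",
                    substr(ctx[ok], 3, 3))
  out[!out %in% sbs_channels()] <- NA_character_
  out
}

#' Build a 96-channel mutation spectrum for one sample
#'
#' Counts the sample's single-nucleotide substitutions into the 96
#' pyrimidine-centric trinucleotide channels. Purine-reference records are
#' reverse-complemented; records whose context middle base disagrees with
#' the reference base (or that are not single-base substitutions) are
#' rejected with a warning.
#'
#' @param catalog data.frame with columns `sample`, `ref`, `alt`,
#'   `context` (3-mer, middle base = ref); extra columns ignored.
#' @param sample sample identifier present in `catalog$sample`.
#' @return named integer vector of length 96 (channel counts); the sum
#'   equals the number of accepted mutations.
#' @export
build_spectrum <- function(catalog, sample) {
  stopifnot(is.data.frame(catalog),
            all(c("sample", "ref", "alt", "context") %in% names(catalog)))
  if (!sample %in% catalog$sample)
    stop_arg("sample '%s' not present in catalog", sample)
  rec <- catalog[catalog$sample == sample, , drop = FALSE]
  ch <- mutation_channel(rec$ref, rec$alt, rec$context)
  if (anyNA(ch))
    warning(sum(is.na(ch)), " record(s) rejected (inconsistent context/ref)")
  chan <- sbs_channels()
  counts <- table(factor(ch[!is.na(ch)], levels = chan))
  out <- as.integer(counts)
  names(out) <- chan
  out
}

# NNLS of b (length-96 frequency vector) on the rows of A (sigs x 96),
# with the total exposure clipped to sum <= 1 by rescaling.
nnls_capped <- function(A, b) {
  fit <- pracma::lsqnonneg(t(A), b)
  w <- fit$x
  s <- sum(w)
  if (s > 1) w <- w / s
  names(w) <- rownames(A)
  w
}

refit_sse <- function(A, b, w) sum((b - as.numeric(w %*% A))^2)

#' Refit a spectrum against reference signatures
#'
#' Expresses a sample spectrum as a non-negative mixture of fixed reference
#' signatures by iterative forward selection: at each step the single
#' signature whose inclusion (weights re-optimized by non-negative least
#' squares on normalized frequencies, total constrained to at most 1) most
#' reduces the squared reconstruction error is added; selection stops when
#' the relative error improvement falls below `tol`. Weights below
#' `weight_cutoff` are then zeroed and the remaining signatures refit once.
#'
#' @param spectrum numeric vector of 96 channel counts (or frequencies).
#' @param refs signature matrix, signatures x 96, rows summing to 1.
#' @param weight_cutoff minimum retained weight (default 0.06).
#' @param tol relative SSE improvement below which selection stops.
#' @param min_mutations warn (not fail) below this spectrum total.
#' @return object of class `signature_exposure`: list with `weights`
#'   (named, over all reference signatures; zeros for unused), `retained`,
#'   `residual` (1 - sum of weights), `sse`, `cosine` (reconstruction vs
#'   observed frequencies) and `n_mutations`.
#' @export
refit_signatures <- function(spectrum, refs, weight_cutoff = 0.06,
                             tol = 1e-3, min_mutations = 50) {
  if (ncol(refs) != 96L)
    stop_arg("reference matrix must have 96 channels, got %d", ncol(refs))
  if (length(spectrum) != 96L)
    stop_arg("spectrum must have 96 channels, got %d", length(spectrum))
  total <- sum(spectrum)
  if (total <= 0) stop_arg("empty spectrum: cannot normalize zero counts")
  if (total < min_mutations)
    warning("spectrum has only ", total, " mutations; refit may be unstable")
  b <- spectrum / total
  sigs <- rownames(refs)
  if (is.null(sigs)) sigs <- paste0("sig", seq_len(nrow(refs)))
  rownames(refs) <- sigs

  selected <- character(0)
  w_cur <- NULL
  sse_cur <- sum(b^2)                    # empty model reconstructs zero
  repeat {
    candidates <- setdiff(sigs, selected)
    if (length(candidates) == 0) break
    best <- NULL; best_sse <- Inf; best_w <- NULL
    for (cand in candidates) {
      trial <- c(selected, cand)
      w <- nnls_capped(refs[trial, , drop = FALSE], b)
      sse <- refit_sse(refs[trial, , drop = FALSE], b, w)
      if (sse < best_sse) { best <- cand; best_sse <- sse; best_w <- w }
    }
    if ((sse_cur - best_sse) / sse_cur < tol) break
    selected <- c(selected, best)
    w_cur <- best_w
    sse_cur <- best_sse
  }

  weights <- stats::setNames(numeric(length(sigs)), sigs)
  if (length(selected)) {
    keep <- names(w_cur)[w_cur >= weight_cutoff]
    if (length(keep)) {
      w_fin <- nnls_capped(refs[keep, , drop = FALSE], b)
      w_fin[w_fin < weight_cutoff] <- 0
      weights[names(w_fin)] <- w_fin
    }
  }
  retained <- names(weights)[weights > 0]
  recon <- as.numeric(weights %*% refs)
  cosine <- if (sum(recon) == 0) 0 else
    sum(recon * b) / sqrt(sum(recon^2) * sum(b^2))
  structure(list(weights = weights, retained = retained,
                 residual = 1 - sum(weights),
                 sse = sum((b - recon)^2), cosine = cosine,
                 n_mutations = total),
            class = "signature_exposure")
}

#' Summarize signature exposures across samples
#'
#' A sample "displays" a signature iff its retained weight is positive
#' after the cutoff.
#'
#' @param exposures list of `signature_exposure` objects (optionally named
#'   by sample).
#' @return data.frame with columns `signature`, `n_samples`, `mean_weight`.
#' @export
exposure_summary <- function(exposures) {
  if (length(exposures) == 0) stop_arg("need at least one exposure")
  W <- do.call(rbind, lapply(exposures, function(e) e$weights))
  data.frame(signature = colnames(W),
             n_samples = colSums(W > 0),
             mean_weight = colMeans(W),
             row.names = NULL)
}
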