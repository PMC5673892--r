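# Synthetic-data module: generates every pipeline input with known ground
# truth so each downstream stage is testable without external downloads.
# No real genome sequence is simulated; coordinates are synthetic and
# trinucleotide contexts are carried as channel labels on mutations.

#' Construct a beta-value matrix container
#'
#' @param values probes x samples numeric matrix, values in [0, 1]
#'   (NA allowed); rownames = probe ids, colnames = sample ids.
#' @param groups character vector (one per sample) of group labels,
#'   typically "tumor", "normal" or "metastasis".
#' @return object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, groups = rep("tumor", ncol(values))) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)), length(groups) == ncol(values))
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop_arg("beta values must lie in [0, 1]")
  structure(list(values = values, groups = stats::setNames(groups, colnames(values))),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples (",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Generate a synthetic genome annotation
#'
#' Lays out `n_genes` genes across `n_chrom` chromosomes with alternating
#' strands, 20 kb gene bodies, promoters spanning 1.5 kb upstream and
#' 0.5 kb downstream of the TSS (strand-aware), one CpG island per gene
#' centered on the TSS for half the genes, and probes guaranteeing at
#' least 3 promoter and 3 body probes per gene; remaining probes are
#' scattered intergenically. All intervals are 0-based half-open.
#'
#' @param n_chrom,n_genes,n_probes positive integers;
#'   `n_probes >= 6 * n_genes` so the per-gene probe guarantee can hold.
#' @param seed integer seed; identical seeds give identical annotations.
#' @return object of class `annotation_set` with data.frames `genes`
#'   (gene_id, chrom, strand, tss, body_start, body_end), `promoters`,
#'   `cpg_islands`, `cgi_promoters` and `probes` (probe_id, chrom, pos).
#' @export
make_annotation <- function(n_chrom = 2, n_genes = 50, n_probes = 6 * n_genes,
                            seed = 1) {
  if (n_chrom < 1 || n_genes < 1 || n_probes < 1)
    stop_arg("counts must be positive")
  if (n_probes < 6 * n_genes)
    stop_arg("need n_probes >= 6 * n_genes (3 promoter + 3 body probes per gene)")
  set.seed(substream_seed(seed, "annotation"))
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  chrom <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chrom) + 1L)
  strand <- rep(c("+", "-"), length.out = n_genes)
  # genes spaced 100 kb apart along each chromosome
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  tss <- 50000L + (idx_on_chrom - 1L) * 100000L
  body_start <- ifelse(strand == "+", tss, tss - 20000L)
  body_end <- ifelse(strand == "+", tss + 20000L, tss)
  prom_start <- ifelse(strand == "+", tss - 1500L, tss - 500L)
  prom_end <- ifelse(strand == "+", tss + 500L, tss + 1500L)
  genes <- data.frame(gene_id, chrom, strand, tss,
                      body_start, body_end, stringsAsFactors = FALSE)
  promoters <- data.frame(gene_id, chrom, start = prom_start, end = prom_end,
                          stringsAsFactors = FALSE)
  has_island <- seq_len(n_genes) %% 2L == 1L
  cpg_islands <- data.frame(island_id = sprintf("cgi_%04d", which(has_island)),
                            chrom = chrom[has_island],
                            start = tss[has_island] - 400L,
                            end = tss[has_island] + 400L,
                            stringsAsFactors = FALSE)
  ov_start <- pmax(prom_start, tss - 400L)
  ov_end <- pmin(prom_end, tss + 400L)
  keep <- has_island & ov_start < ov_end
  cgi_promoters <- data.frame(gene_id = gene_id[keep], chrom = chrom[keep],
                              start = ov_start[keep], end = ov_end[keep],
                              stringsAsFactors = FALSE)
  # three probes inside the promoter/island overlap region and three in the
  # body of every gene; leftovers placed uniformly between genes
  ppos <- cbind(tss - 300L, tss, tss + 300L)
  bmid <- (body_start + body_end) %/% 2L
  bpos <- cbind(bmid - 2000L, bmid, bmid + 2000L)
  fixed <- data.frame(chrom = rep(chrom, 6L),
                      pos = c(ppos, bpos), stringsAsFactors = FALSE)
  n_extra <- n_probes - nrow(fixed)
  if (n_extra > 0) {
    ch <- sample(paste0("chr", seq_len(n_chrom)), n_extra, replace = TRUE)
    chrom_len <- stats::setNames(
      vapply(paste0("chr", seq_len(n_chrom)),
             function(cc) max(c(100000L, tss[chrom == cc] + 50000L)),
             integer(1)),
      paste0("chr", seq_len(n_chrom)))
    extra <- data.frame(chrom = ch,
                        pos = floor(stats::runif(n_extra) * chrom_len[ch]),
                        stringsAsFactors = FALSE)
    fixed <- rbind(fixed, extra)
  }
  ord <- order(fixed$chrom, fixed$pos)
  probes <- data.frame(probe_id = sprintf("cg%07d", seq_len(nrow(fixed))),
                       chrom = fixed$chrom[ord], pos = as.integer(fixed$pos[ord]),
                       stringsAsFactors = FALSE)
  structure(list(genes = genes, promoters = promoters,
                 cpg_islands = cpg_islands, cgi_promoters = cgi_promoters,
                 probes = probes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,", nrow(x$probes), "probes,",
      nrow(x$cpg_islands), "CpG islands\n")
  invisible(x)
}

# region intervals of a given type as a data.frame(region_id, chrom, start, end)
region_intervals <- function(annotation, region_type) {
  switch(region_type,
    promoter = data.frame(region_id = annotation$promoters$gene_id,
                          annotation$promoters[c("chrom", "start", "end")]),
    gene_body = data.frame(region_id = annotation$genes$gene_id,
                           chrom = annotation$genes$chrom,
                           start = annotation$genes$body_start,
                           end = annotation$genes$body_end),
    cpg_island = data.frame(region_id = annotation$cpg_islands$island_id,
                            annotation$cpg_islands[c("chrom", "start", "end")]),
    cgi_promoter = data.frame(region_id = annotation$cgi_promoters$gene_id,
                              annotation$cgi_promoters[c("chrom", "start", "end")]),
    stop_arg("unknown region_type '%s'", region_type))
}

# probe ids falling in one interval
probes_in_interval <- function(annotation, chrom, start, end) {
  p <- annotation$probes
  p$probe_id[p$chrom == chrom & pos_in_interval(p$pos, start, end)]
}

#' Simulate tumor and normal beta matrices with implanted DMRs
#'
#' Baselines are drawn per probe (uniform 0.2-0.6), shared across samples.
#' For each entry of `dmr_spec` the member probes of the named promoter
#' region are shifted by `delta` (up for "hyper", down for "hypo") in a
#' random subset of tumors of size `ceiling(fraction * n_tumor)`; Gaussian
#' noise truncated to [0, 1] is then added everywhere.
#'
#' @param annotation `annotation_set`.
#' @param n_tumor,n_normal sample counts.
#' @param dmr_spec data.frame with columns `region_id` (a gene id; its
#'   promoter is the implanted region), `direction` ("hyper"/"hypo"),
#'   `delta` (0 < delta <= 1) and `fraction` (0 < fraction <= 1); NULL for
#'   pure-null data.
#' @param noise_sd standard deviation of the truncated Gaussian noise.
#' @param seed integer seed.
#' @param region_type which region the ids of `dmr_spec` denote.
#' @return list(beta = `beta_matrix`, truth = list with `dmr` data.frame
#'   (region_id, direction, delta, affected tumor ids) and `baseline`).
#' @export
simulate_betas <- function(annotation, n_tumor, n_normal, dmr_spec = NULL,
                           noise_sd = 0.05, seed = 1,
                           region_type = "promoter") {
  set.seed(substream_seed(seed, "betas"))
  probes <- annotation$probes
  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  groups <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  baseline <- stats::runif(nrow(probes), 0.2, 0.6)
  vals <- matrix(rep(baseline, length(samples)), ncol = length(samples),
                 dimnames = list(probes$probe_id, samples))
  truth_rows <- list()
  if (!is.null(dmr_spec) && nrow(dmr_spec) > 0) {
    stopifnot(all(c("region_id", "direction", "delta", "fraction") %in%
                    names(dmr_spec)))
    if (any(dmr_spec$delta <= 0 | dmr_spec$delta > 1))
      stop_arg("delta must be in (0, 1]")
    if (any(dmr_spec$fraction <= 0 | dmr_spec$fraction > 1))
      stop_arg("fraction must be in (0, 1]")
    regs <- region_intervals(annotation, region_type)
    for (i in seq_len(nrow(dmr_spec))) {
      rid <- dmr_spec$region_id[i]
      j <- match(rid, regs$region_id)
      if (is.na(j)) stop_arg("region_id '%s' absent from annotation", rid)
      member <- probes_in_interval(annotation, regs$chrom[j],
                                   regs$start[j], regs$end[j])
      n_aff <- ceiling(dmr_spec$fraction[i] * n_tumor)
      aff <- sort(sample(seq_len(n_tumor), n_aff))
      shift <- if (dmr_spec$direction[i] == "hyper") dmr_spec$delta[i] else
        -dmr_spec$delta[i]
      vals[member, aff] <- vals[member, aff] + shift
      truth_rows[[i]] <- data.frame(region_id = rid,
                                    direction = dmr_spec$direction[i],
                                    delta = dmr_spec$delta[i],
                                    affected = paste(samples[aff], collapse = ","),
                                    stringsAsFactors = FALSE)
    }
  }
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
  vals <- clip01(vals)
  list(beta = beta_matrix(vals, groups),
       truth = list(dmr = if (length(truth_rows)) do.call(rbind, truth_rows)
                    else NULL,
                    baseline = stats::setNames(baseline, probes$probe_id)))
}

#' Construct a total-intensity matrix container
#'
#' @param values probes x samples matrix of strictly positive, finite
#'   total intensities (methylated + unmethylated signal).
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(!is.finite(values)) || any(values <= 0))
    stop_arg("intensities must be positive and finite")
  structure(list(values = values), class = "intensity_matrix")
}

#' Simulate array total intensities with implanted copy-number segments
#'
#' Per-probe baselines are lognormal around a global constant (median
#' 5000) and shared across samples. Probes of a tumor falling inside one
#' of its implanted segments are scaled by `2^log2_ratio`; multiplicative
#' lognormal noise (`exp(N(0, noise_sd))`) is applied to every cell.
#' Normal samples carry no implanted segments.
#'
#' @param annotation `annotation_set`.
#' @param n_tumor,n_normal sample counts.
#' @param cna_spec data.frame with columns `sample` (tumor index or id),
#'   `chrom`, `start`, `end`, `log2_ratio` (in [-3, 3]); NULL for null data.
#' @param noise_sd sd of the log-scale noise.
#' @param seed integer seed.
#' @return list(intensity = `intensity_matrix`, truth = cna_spec as given,
#'   with sample ids resolved).
#' @export
simulate_intensities <- function(annotation, n_tumor, n_normal,
                                 cna_spec = NULL, noise_sd = 0.1, seed = 1) {
  set.seed(substream_seed(seed, "intensities"))
  probes <- annotation$probes
  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  baseline <- 5000 * exp(stats::rnorm(nrow(probes), 0, 0.2))
  vals <- matrix(rep(baseline, length(samples)), ncol = length(samples),
                 dimnames = list(probes$probe_id, samples))
  if (!is.null(cna_spec) && nrow(cna_spec) > 0) {
    stopifnot(all(c("sample", "chrom", "start", "end", "log2_ratio") %in%
                    names(cna_spec)))
    if (any(abs(cna_spec$log2_ratio) > 3))
      stop_arg("log2_ratio must lie in [-3, 3]")
    if (is.numeric(cna_spec$sample))
      cna_spec$sample <- sprintf("T%03d", cna_spec$sample)
    if (!all(cna_spec$sample %in% samples[seq_len(n_tumor)]))
      stop_arg("cna_spec samples must be tumors")
    for (s in unique(cna_spec$sample)) {
      seg <- cna_spec[cna_spec$sample == s, , drop = FALSE]
      for (cc in unique(seg$chrom)) {
        sc <- seg[seg$chrom == cc, , drop = FALSE]
        sc <- sc[order(sc$start), , drop = FALSE]
        if (nrow(sc) > 1 && any(sc$start[-1] < sc$end[-nrow(sc)]))
          stop_arg("overlapping implanted segments for sample %s on %s", s, cc)
      }
    }
    for (i in seq_len(nrow(cna_spec))) {
      hit <- probes$chrom == cna_spec$chrom[i] &
        pos_in_interval(probes$pos, cna_spec$start[i], cna_spec$end[i])
      vals[hit, cna_spec$sample[i]] <-
        vals[hit, cna_spec$sample[i]] * 2^cna_spec$log2_ratio[i]
    }
  }
  if (noise_sd > 0)
    vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, noise_sd),
                              nrow(vals)))
  list(intensity = intensity_matrix(vals),
       truth = cna_spec,
       groups = stats::setNames(c(rep("tumor", n_tumor),
                                  rep("normal", n_normal)), samples))
}

#' Generate a panel of well-separated reference signatures
#'
#' Each signature concentrates most of its probability mass on its own
#' disjoint block of channels (plus a small flat floor), mimicking the
#' strongly peaked substitution signatures (e.g. the spontaneous-
#' deamination signature, dominated by N[C>T]G channels) for which
#' refitting is identifiable. Defaults are deliberately concentrated:
#' diffuse, flat signatures are not resolvable from a 96-channel spectrum
#' at typical exome mutation counts and are out of the generator's scope.
#'
#' @param n_sigs number of signatures (<= 96 / block size).
#' @param seed integer seed.
#' @param peak_channels channels per signature's high-mass block.
#' @param floor flat probability floor shared by all channels.
#' @return matrix n_sigs x 96, rows summing to 1, named Sig1..SigN.
#' @export
random_signatures <- function(n_sigs = 6, seed = 1, peak_channels = 4,
                              floor = 0.02) {
  set.seed(substream_seed(seed, "signatures"))
  chan <- sbs_channels()
  M <- matrix(floor / 96, n_sigs, 96, dimnames = list(
    paste0("Sig", seq_len(n_sigs)), chan))
  blocks <- split(sample(seq_len(96)),
                  rep(seq_len(n_sigs), length.out = 96))
  for (i in seq_len(n_sigs)) {
    pk <- blocks[[i]][seq_len(min(peak_channels, length(blocks[[i]])))]
    w <- stats::runif(length(pk))
    M[i, pk] <- M[i, pk] + (1 - floor) * w / sum(w)
  }
  M / rowSums(M)
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Mutations are drawn i.i.d. from the 96-channel mixture distribution
#' `weights %*% signature_matrix`; each record carries a synthetic
#' coordinate and the ref/alt/context implied by its channel label.
#'
#' @param signature_matrix signatures x 96 matrix, rows summing to 1.
#' @param weights non-negative mixture weights summing to 1 (one per
#'   signature).
#' @param n_mutations number of mutations (> 0).
#' @param seed integer seed.
#' @param sample sample id recorded on every row.
#' @return data.frame(sample, chrom, pos, ref, alt, context, channel).
#' @export
simulate_catalog <- function(signature_matrix, weights, n_mutations,
                             seed = 1, sample = "S1") {
  if (n_mutations <= 0) stop_arg("n_mutations must be positive")
  if (length(weights) != nrow(signature_matrix))
    stop_arg("weights length must match signature count")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_arg("weights must be non-negative and sum to 1")
  if (any(abs(rowSums(signature_matrix) - 1) > 1e-6))
    stop_arg("signature rows must sum to 1")
  set.seed(substream_seed(seed, "catalog"))
  p <- as.numeric(weights %*% signature_matrix)
  chan <- sbs_channels()
  idx <- sample.int(96, n_mutations, replace = TRUE, prob = p)
  lab <- chan[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  context <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  data.frame(sample = sample, chrom = "chr1",
             pos = seq_len(n_mutations) * 100L,
             ref = ref, alt = alt, context = context, channel = lab,
             stringsAsFactors = FALSE)
}

#' Construct a reference cell-type methylome panel
#'
#' @param betas cell types x probes matrix of beta values in [0, 1];
#'   rownames = cell types, colnames = probe ids.
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(betas) {
  stopifnot(is.matrix(betas), nrow(betas) >= 2, !is.null(rownames(betas)),
            !is.null(colnames(betas)))
  if (any(betas < 0 | betas > 1)) stop_arg("panel betas must be in [0, 1]")
  structure(list(betas = betas), class = "reference_panel")
}

#' Simulate a reference panel with planted marker probes
#'
#' Background probes share a common beta across cell types; each cell type
#' additionally receives `n_markers` probes where it alone is highly
#' methylated (0.9) against a low background (0.1) — mimicking the
#' discriminating CpGs reference-based deconvolution relies on.
#'
#' @param n_types,n_probes,n_markers panel dimensions.
#' @param seed integer seed.
#' @return list(panel = `reference_panel`, markers = list of probe ids per
#'   cell type).
#' @export
make_reference_panel <- function(n_types = 4, n_probes = 500, n_markers = 50,
                                 seed = 1) {
  if (n_markers * n_types > n_probes)
    stop_arg("too many markers for n_probes")
  set.seed(substream_seed(seed, "panel"))
  types <- paste0("cell", seq_len(n_types))
  probe_ids <- sprintf("cg%07d", seq_len(n_probes))
  base <- stats::runif(n_probes, 0.3, 0.7)
  B <- matrix(rep(base, each = n_types), n_types, n_probes,
              dimnames = list(types, probe_ids))
  markers <- list()
  slots <- split(seq_len(n_markers * n_types), rep(seq_len(n_types),
                                                   each = n_markers))
  for (i in seq_len(n_types)) {
    idx <- slots[[i]]
    B[, idx] <- 0.1
    B[i, idx] <- 0.9
    markers[[types[i]]] <- probe_ids[idx]
  }
  list(panel = reference_panel(B), markers = markers)
}

#' Simulate bulk methylomes as mixtures of reference cell types
#'
#' The mixture beta at each probe is the proportion-weighted average of
#' the reference profiles, plus Gaussian noise truncated to [0, 1].
#'
#' @param panel `reference_panel`.
#' @param proportions non-negative vector summing to 1 (length = number of
#'   cell types), or a samples x types matrix for several samples.
#' @param noise_sd noise standard deviation.
#' @param seed integer seed.
#' @return `beta_matrix` (probes x samples).
#' @export
simulate_mixture <- function(panel, proportions, noise_sd = 0, seed = 1) {
  B <- panel$betas
  if (is.null(dim(proportions))) {
    if (length(proportions) != nrow(B))
      stop_arg("proportions length %d != %d cell types",
               length(proportions), nrow(B))
    proportions <- matrix(proportions, nrow = 1,
                          dimnames = list("mix1", rownames(B)))
  }
  if (ncol(proportions) != nrow(B))
    stop_arg("proportions length %d != %d cell types",
             ncol(proportions), nrow(B))
  if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-8))
    stop_arg("proportions must be non-negative and sum to 1")
  set.seed(substream_seed(seed, "mixture"))
  vals <- t(proportions %*% B)           # probes x samples
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
  vals <- clip01(vals)
  if (is.null(rownames(proportions)))
    rownames(proportions) <- paste0("mix", seq_len(nrow(proportions)))
  colnames(vals) <- rownames(proportions)
  rownames(vals) <- colnames(B)
  beta_matrix(vals, groups = rep("tumor", ncol(vals)))
}
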