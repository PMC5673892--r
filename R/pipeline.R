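# End-to-end orchestration: one config object drives the synthetic-data
# generators and every analysis stage in the order
# regions -> cna -> signatures -> deconv -> integrate -> phylo, with all
# stage outputs persisted before the next stage starts and a JSON summary
# at the end. All randomness flows from the single root seed via named
# substreams, so identical seeds give byte-identical run directories.

# coerce a YAML list-of-rows (or a data.frame) into a data.frame
rows_to_df <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Default end-to-end synthetic scenario
#'
#' Sixty genes on two chromosomes; a deletion window on chr1 and an
#' amplification window on chr2 implanted in every tumor; promoter DMRs
#' placed so that, combined with the copy-number calls, all nine
#' integration states occur; signature mixtures, reference-panel mixtures
#' and a leukocyte-unmethylated probe panel round out the inputs.
#'
#' @param seed root seed for the whole run.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(n_chrom = 2, n_genes = 60, n_probes = 760,
                 n_tumor = 10, n_normal = 8,
                 beta_noise_sd = 0.05, intensity_noise_sd = 0.1),
    # driver genes: chr1 genes sit at odd indices, chr2 at even ones
    dmr = data.frame(
      region_id = sprintf("gene_%04d", c(1, 5, 2, 4, 9, 11, 13)),
      direction = c("hyper", "hypo", "hyper", "hypo", "hyper", "hypo",
                    "hyper"),
      delta = 0.35, fraction = 1.0, stringsAsFactors = FALSE),
    cna_windows = data.frame(
      chrom = c("chr1", "chr2"), start = 0L, end = 420000L,
      log2_ratio = c(-1.0, 1.0), stringsAsFactors = FALSE),
    regions = list(region_type = "promoter", min_probes = 3,
                   rank_cutoff = "auto", method = "welch"),
    cna = list(min_bin = 5, penalty = NULL,
               thresholds = c(t_amp = 0.2, t_del = -0.2,
                              t_amp2 = 1.0, t_del2 = -1.0),
               n_perm = 1000),
    signatures = list(n_sigs = 6, n_active = 3, n_mutations = 1000,
                      weight_cutoff = 0.06),
    deconv = list(n_types = 4, n_probes = 500, n_markers = 50,
                  noise_sd = 0.02, k_per_type = 50),
    integrate = list(meth_delta = 0.20, meth_mode = "absolute"),
    phylo = list(method = "bme")
  )
}

REQUIRED_CONFIG <- c("seed", "synth", "regions", "cna", "signatures",
                     "deconv", "integrate", "phylo")

#' Validate a pipeline configuration
#'
#' @param config nested list (see [default_config()]) or a YAML file path.
#' @return the validated config list; errors name the missing field.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing <- setdiff(REQUIRED_CONFIG, names(config))
  if (length(missing))
    stop_arg("config missing required field(s): %s",
             paste(missing, collapse = ", "))
  for (f in c("n_sigs", "n_mutations"))
    if (is.null(config$signatures[[f]]))
      stop_arg("config missing required field: signatures.%s", f)
  config
}

#' Run every pipeline stage on a synthetic scenario
#'
#' Generates annotation, beta, intensity, mutation and mixture inputs
#' from the config, then executes differential-methylation calling,
#' copy-number segmentation + recurrence, signature refitting,
#' deconvolution + purity, nine-state integration and tree building,
#' writing each stage's TSV outputs into `out_dir` before the next stage
#' starts, plus `summary.json` with parameters, seed and headline counts.
#'
#' @param config config list or YAML path (see [default_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with all in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  sy <- cfg$synth
  out <- function(f) file.path(out_dir, f)

  ## ---- inputs ----
  ann <- make_annotation(sy$n_chrom, sy$n_genes, sy$n_probes, seed = seed)
  write_tsv(ann$genes, out("genes.tsv"))
  write_tsv(ann$probes, out("probes.tsv"))
  write_bed(ann$promoters, out("promoters.bed"), name_col = "gene_id")

  dmr_spec <- rows_to_df(cfg$dmr)
  sim_b <- simulate_betas(ann, sy$n_tumor, sy$n_normal, dmr_spec,
                          noise_sd = sy$beta_noise_sd, seed = seed)
  write_beta_tsv(sim_b$beta, out("beta.tsv"))

  win <- rows_to_df(cfg$cna_windows)
  cna_spec <- NULL
  if (!is.null(win)) {
    cna_spec <- do.call(rbind, lapply(seq_len(sy$n_tumor), function(i)
      cbind(sample = sprintf("T%03d", i), win)))
  }
  sim_i <- simulate_intensities(ann, sy$n_tumor, sy$n_normal, cna_spec,
                                noise_sd = sy$intensity_noise_sd, seed = seed)
  tumors <- names(sim_i$groups)[sim_i$groups == "tumor"]
  normals <- names(sim_i$groups)[sim_i$groups == "normal"]
  jsonlite::write_json(list(dmr = sim_b$truth$dmr, cna = cna_spec),
                       out("truth.json"), auto_unbox = TRUE, digits = NA)

  ## ---- regions: differential methylation ----
  rg <- cfg$regions
  region_beta <- aggregate_regions(sim_b$beta, ann, rg$region_type,
                                   rg$min_probes)
  diff_tab <- differential_regions(region_beta, tumors, normals,
                                   rank_cutoff = rg$rank_cutoff,
                                   method = rg$method)
  write_tsv(diff_tab, out("region_diff.tsv"))

  ## ---- cna: segmentation, gene calls, recurrence ----
  cn <- cfg$cna
  seg_list <- lapply(tumors, function(s) {
    tr <- log2_ratio(sim_i$intensity, s, normals, ann)
    segment_track(bin_probes(tr, cn$min_bin), penalty = cn$penalty,
                  sample = s)
  })
  segments <- do.call(rbind, seg_list)
  write_tsv(segments, out("segments.seg"))
  th <- unlist(cn$thresholds)
  gene_cna <- gene_calls(segments, ann, thresholds = th)
  write_tsv(gene_cna$state, out("gene_states.tsv"), rownames_col = "gene_id")
  gscore <- recurrence(gene_cna, n_perm = cn$n_perm,
                       seed = substream_seed(seed, "gscore"))
  write_tsv(gscore, out("gscore.tsv"))

  ## ---- signatures: catalogs, spectra, refit ----
  sg <- cfg$signatures
  refs <- random_signatures(sg$n_sigs, seed = substream_seed(seed, "refs"))
  set.seed(substream_seed(seed, "sig_weights"))
  catalogs <- list(); truth_w <- list()
  for (s in tumors) {
    active <- sample(seq_len(sg$n_sigs), sg$n_active)
    w <- numeric(sg$n_sigs)
    raw <- stats::runif(sg$n_active, 0.5, 1)
    w[active] <- raw / sum(raw)
    truth_w[[s]] <- w
    catalogs[[s]] <- simulate_catalog(refs, w, sg$n_mutations,
                                      seed = substream_seed(seed, s),
                                      sample = s)
  }
  catalog <- do.call(rbind, catalogs)
  write_tsv(catalog, out("mutations.tsv"))
  exposures <- lapply(tumors, function(s)
    refit_signatures(build_spectrum(catalog, s), refs,
                     weight_cutoff = sg$weight_cutoff))
  names(exposures) <- tumors
  expo_tab <- data.frame(sample = tumors,
                         do.call(rbind, lapply(exposures, `[[`, "weights")),
                         row.names = NULL, check.names = FALSE)
  write_tsv(expo_tab, out("exposures.tsv"))
  write_tsv(exposure_summary(exposures), out("exposure_summary.tsv"))

  ## ---- deconv: composition + purity ----
  dv <- cfg$deconv
  pan <- make_reference_panel(dv$n_types, dv$n_probes, dv$n_markers,
                              seed = substream_seed(seed, "panel"))
  set.seed(substream_seed(seed, "props"))
  P <- matrix(stats::runif(sy$n_tumor * dv$n_types), sy$n_tumor,
              dimnames = list(tumors, rownames(pan$panel$betas)))
  P <- P / rowSums(P)
  mix <- simulate_mixture(pan$panel, P, noise_sd = dv$noise_sd,
                          seed = substream_seed(seed, "mix"))
  sites <- select_sites(pan$panel, dv$k_per_type)
  comp <- estimate_composition(mix$values, pan$panel, sites)
  write_tsv(comp, out("composition.tsv"), rownames_col = "sample")
  lump_panel <- pan$markers[[2]]
  purity <- vapply(colnames(mix$values), function(s)
    lump_purity(mix$values[, s], lump_panel), numeric(1))
  write_tsv(data.frame(sample = names(purity), purity = purity),
            out("purity.tsv"))

  ## ---- integrate: nine-state matrix ----
  ig <- cfg$integrate
  states <- classify_states(gene_cna, region_beta,
                            meth_delta = ig$meth_delta,
                            meth_mode = ig$meth_mode)
  write_tsv(states$state[, tumors, drop = FALSE], out("nine_state.tsv"),
            rownames_col = "gene_id")
  write_tsv(rank_genes(states, "loss"), out("ranked_loss.tsv"))
  write_tsv(rank_genes(states, "gain"), out("ranked_gain.tsv"))

  ## ---- phylo: distances + tree ----
  D <- beta_distances(sim_b$beta)
  write_tsv(round(D, 10), out("distances.tsv"), rownames_col = "sample")
  tree <- build_tree(D, method = cfg$phylo$method)
  ape::write.tree(tree, out("tree.nwk"))

  state_counts <- table(factor(states$state[, tumors], levels = NINE_STATES))
  summary <- list(
    package_version = as.character(utils::packageVersion("meth450pipe")),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), "seed")],
    n_significant_regions = sum(diff_tab$significant),
    n_segments = nrow(segments),
    top_deleted_gene = gscore$gene_id[gscore$direction == "del"][
      which.min(gscore$q_value[gscore$direction == "del"])],
    mean_signatures_per_sample = mean(vapply(exposures, function(e)
      length(e$retained), numeric(1))),
    mean_purity = mean(purity),
    nine_state_counts = as.list(state_counts),
    n_states_observed = sum(state_counts > 0),
    n_tree_tips = length(tree$tip.label))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(annotation = ann, beta = sim_b, intensity = sim_i,
                 region_beta = region_beta, diff = diff_tab,
                 segments = segments, gene_cna = gene_cna, gscore = gscore,
                 signatures = list(refs = refs, truth = truth_w,
                                   exposures = exposures),
                 deconv = list(panel = pan, truth = P, composition = comp,
                               purity = purity),
                 states = states, tree = tree, summary = summary,
                 out_dir = out_dir))
}
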