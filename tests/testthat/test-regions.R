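mk_beta <- function(values, groups) {
  beta_matrix(values, groups)
}

test_that("region aggregation averages member probes and applies filters", {
  ann <- tiny_annotation()
  V <- matrix(0.5, 10, 4, dimnames = list(paste0("p", 1:10),
                                          c("T1", "T2", "N1", "N2")))
  V[c("p1", "p2", "p3"), "T1"] <- c(0.2, 0.4, 0.6)
  b <- mk_beta(V, c("tumor", "tumor", "normal", "normal"))
  rb <- aggregate_regions(b, ann, "promoter", min_probes = 3)
  expect_equal(unname(rb$values["gA", "T1"]), 0.4)   # mean(0.2, 0.4, 0.6)
  expect_true(all(c("gA", "gB") %in% rownames(rb$values)))
  # gB's body has only one probe -> excluded at min_probes = 3
  rb_body <- suppressWarnings(aggregate_regions(b, ann, "gene_body", 3))
  expect_true("gA" %in% rownames(rb_body$values))
  expect_false("gB" %in% rownames(rb_body$values))
  # cgi promoters: probe p1 (inside promoter, outside island) excluded
  rb_cgi <- aggregate_regions(b, ann, "cgi_promoter", min_probes = 2)
  expect_equal(unname(rb_cgi$values["gA", "T1"]), mean(c(0.4, 0.6)))
  expect_equal(unname(rb_cgi$n_probes["gA"]), 2)
})

test_that("identical groups yield zero differences and no significant call", {
  ann <- make_annotation(1, 10, 100, seed = 6)
  sim <- simulate_betas(ann, 6, 6, NULL, noise_sd = 0.05, seed = 6)
  rb <- aggregate_regions(sim$beta, ann, "promoter")
  tum <- names(rb$groups)[rb$groups == "tumor"]
  d <- differential_regions(rb, tum[1:3], tum[1:3])
  expect_true(all(d$mean_diff == 0))
  expect_false(any(d$significant))
  expect_error(differential_regions(rb, tum[1], tum[2:4]), "2 samples")
})

test_that("an implanted DMR attains combined rank 1 among null regions", {
  ann <- make_annotation(2, 100, 700, seed = 7)
  spec <- data.frame(region_id = "gene_0042", direction = "hyper",
                     delta = 0.3, fraction = 1)
  sim <- simulate_betas(ann, 10, 10, spec, noise_sd = 0.05, seed = 7)
  rb <- aggregate_regions(sim$beta, ann, "promoter")
  tum <- names(rb$groups)[rb$groups == "tumor"]
  nrm <- names(rb$groups)[rb$groups == "normal"]
  d <- differential_regions(rb, tum, nrm)
  expect_equal(d$region_id[d$combined_rank == min(d$combined_rank)],
               "gene_0042")
  expect_equal(d$combined_rank[d$region_id == "gene_0042"], 1)
  expect_equal(d$direction[d$region_id == "gene_0042"], "hyper")
  # swapping the group labels flips direction, |diff| and p unchanged
  d2 <- differential_regions(rb, nrm, tum)
  expect_equal(d2$mean_diff, -d$mean_diff)
  expect_equal(d2$p_value, d$p_value, tolerance = 1e-12)
  expect_equal(abs(d2$mean_diff), abs(d$mean_diff))
  # limma engine agrees on the top region
  dl <- differential_regions(rb, tum, nrm, method = "limma")
  expect_equal(dl$combined_rank[dl$region_id == "gene_0042"], 1)
})

test_that("validation requires same direction and same region universe", {
  ann <- make_annotation(2, 100, 700, seed = 8)
  spec <- data.frame(region_id = sprintf("gene_%04d", 1:10),
                     direction = "hyper", delta = 0.3, fraction = 1)
  sim <- simulate_betas(ann, 10, 10, spec, noise_sd = 0.05, seed = 8)
  rb <- aggregate_regions(sim$beta, ann, "promoter")
  tum <- names(rb$groups)[rb$groups == "tumor"]
  nrm <- names(rb$groups)[rb$groups == "normal"]
  d <- differential_regions(rb, tum, nrm)
  # self-validation: every hit confirms itself
  expect_equal(validate_regions(d, d)$validation_rate, 1.0)
  # direction mismatch: flip the validation table's directions
  dflip <- d
  dflip$direction <- ifelse(d$direction == "hyper", "hypo", "hyper")
  expect_equal(validate_regions(d, dflip)$validation_rate, 0)
  # half-overlapping significant sets of size 10 -> rate 0.5
  dhalf <- d
  sig_ids <- d$region_id[d$significant]
  expect_equal(length(sig_ids), 10)
  drop5 <- sig_ids[1:5]
  dhalf$significant[dhalf$region_id %in% drop5] <- FALSE
  other <- d$region_id[!d$significant][1:5]
  dhalf$significant[dhalf$region_id %in% other] <- TRUE
  expect_equal(validate_regions(d, dhalf)$validation_rate, 0.5)
  dother <- d[1:10, ]
  dother$region_id <- paste0("x", dother$region_id)
  expect_error(validate_regions(d, dother), "no regions")
})

test_that("paired testing flags a shifted region and degenerate inputs", {
  ann <- make_annotation(1, 20, 160, seed = 9)
  sim <- simulate_betas(ann, 10, 2, NULL, noise_sd = 0.01, seed = 9)
  rb <- aggregate_regions(sim$beta, ann, "promoter")
  prim <- sprintf("T%03d", 1:5)
  met <- sprintf("T%03d", 6:10)
  # metastases byte-equal to primaries: all p = 1
  rb_eq <- rb
  rb_eq$values[, met] <- rb_eq$values[, prim]
  pt <- paired_differential(rb_eq, data.frame(primary = prim,
                                              metastasis = met))
  expect_true(all(pt$p_value == 1))
  # constant +0.2 shift at one region gives it the smallest p
  rb_sh <- rb
  rb_sh$values["gene_0007", met] <- rb_sh$values["gene_0007", met] + 0.2
  pt2 <- paired_differential(rb_sh, data.frame(primary = prim,
                                               metastasis = met))
  expect_equal(pt2$region_id[which.min(pt2$p_value)], "gene_0007")
  # zero-variance nonzero differences: sentinel NA and degenerate flag
  rb_dg <- rb
  rb_dg$values[, met] <- rb_dg$values[, prim] + 0.1
  pt3 <- paired_differential(rb_dg, data.frame(primary = prim,
                                               metastasis = met))
  expect_true(all(is.na(pt3$p_value)))
  expect_true(all(pt3$degenerate))
  expect_error(paired_differential(rb, data.frame(primary = prim[1:2],
                                                  metastasis = met[1:2])),
               "3 pairs")
  expect_error(paired_differential(rb, data.frame(primary = c(prim[1:2], "zz"),
                                                  metastasis = met[1:3])),
               "unmatched")
})
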