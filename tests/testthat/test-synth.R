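test_that("promoter intervals follow the strand-aware 1500/500 rule", {
  ann <- make_annotation(n_chrom = 2, n_genes = 20, n_probes = 140, seed = 3)
  g <- ann$genes
  p <- ann$promoters[match(g$gene_id, ann$promoters$gene_id), ]
  plus <- g$strand == "+"
  expect_equal(p$start[plus], g$tss[plus] - 1500L)
  expect_equal(p$end[plus], g$tss[plus] + 500L)
  expect_equal(p$start[!plus], g$tss[!plus] - 500L)
  expect_equal(p$end[!plus], g$tss[!plus] + 1500L)
  expect_true(all(p$start < p$end))
})

test_that("every gene carries at least 3 promoter and 3 body probes", {
  ann <- make_annotation(n_chrom = 3, n_genes = 30, n_probes = 200, seed = 5)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    pr <- ann$promoters[ann$promoters$gene_id == g$gene_id, ]
    in_prom <- sum(ann$probes$chrom == g$chrom &
                     ann$probes$pos >= pr$start & ann$probes$pos < pr$end)
    in_body <- sum(ann$probes$chrom == g$chrom &
                     ann$probes$pos >= g$body_start &
                     ann$probes$pos < g$body_end)
    expect_gte(in_prom, 3)
    expect_gte(in_body, 3)
  }
  expect_error(make_annotation(2, 10, 20), "6 \\* n_genes")
  expect_error(make_annotation(0, 10, 60), "positive")
})

test_that("generators are deterministic in the seed and vary across seeds", {
  expect_identical(make_annotation(2, 12, 80, seed = 9),
                   make_annotation(2, 12, 80, seed = 9))
  ann <- make_annotation(2, 12, 80, seed = 9)
  b1 <- simulate_betas(ann, 4, 4, noise_sd = 0.05, seed = 11)
  b2 <- simulate_betas(ann, 4, 4, noise_sd = 0.05, seed = 11)
  b3 <- simulate_betas(ann, 4, 4, noise_sd = 0.05, seed = 12)
  expect_identical(b1, b2)
  expect_false(identical(b1$beta$values, b3$beta$values))
  sig <- random_signatures(3, seed = 1)
  c1 <- simulate_catalog(sig, c(1, 0, 0), 50, seed = 4)
  expect_identical(c1, simulate_catalog(sig, c(1, 0, 0), 50, seed = 4))
  expect_false(identical(c1, simulate_catalog(sig, c(1, 0, 0), 50, seed = 5)))
})

test_that("beta simulation implants the requested effect and stays in [0,1]", {
  ann <- make_annotation(1, 10, 100, seed = 2)
  # null case: group means differ only by noise
  null <- simulate_betas(ann, 10, 10, NULL, noise_sd = 0.05, seed = 1)
  g <- null$beta$groups
  dd <- mean(null$beta$values[, g == "tumor"]) -
    mean(null$beta$values[, g == "normal"])
  # shared baselines cancel; the mean difference is noise over
  # 100 probes x 10 samples per group: 3 * 0.05 * sqrt(2/1000)
  expect_lt(abs(dd), 3 * 0.05 * sqrt(2 / 1000))
  # implanted hyper DMR: recovered within 3 standard errors of 0.3
  spec <- data.frame(region_id = "gene_0003", direction = "hyper",
                     delta = 0.3, fraction = 1)
  sim <- simulate_betas(ann, 8, 8, spec, noise_sd = 0.05, seed = 21)
  pr <- ann$promoters[ann$promoters$gene_id == "gene_0003", ]
  member <- ann$probes$probe_id[ann$probes$pos >= pr$start &
                                  ann$probes$pos < pr$end &
                                  ann$probes$chrom == pr$chrom]
  V <- sim$beta$values[member, ]
  k <- length(member)
  se <- 0.05 * sqrt(1 / (k * 8) + 1 / (k * 8))
  obs <- mean(V[, sim$beta$groups == "tumor"]) -
    mean(V[, sim$beta$groups == "normal"])
  expect_lt(abs(obs - 0.3), 3 * se)
  expect_equal(sim$truth$dmr$region_id, "gene_0003")
  expect_true(all(sim$beta$values >= 0 & sim$beta$values <= 1))
  # zero noise, no DMRs: tumor columns equal the normal baseline exactly
  z <- simulate_betas(ann, 3, 3, NULL, noise_sd = 0, seed = 1)
  expect_identical(z$beta$values[, 1], z$beta$values[, 4])
  expect_error(
    simulate_betas(ann, 3, 3, data.frame(region_id = "nope",
                                         direction = "hyper", delta = 0.3,
                                         fraction = 1), 0.05, 1),
    "absent")
})

test_that("intensity simulation implants exact multiplicative segments", {
  ann <- make_annotation(1, 10, 100, seed = 2)
  spec <- data.frame(sample = 1, chrom = "chr1", start = 0L, end = 300000L,
                     log2_ratio = -1)
  sim <- simulate_intensities(ann, 2, 2, spec, noise_sd = 0, seed = 3)
  V <- sim$intensity$values
  inside <- ann$probes$pos < 300000
  expect_equal(V[inside, "T001"] / V[inside, "N001"],
               rep(0.5, sum(inside)), ignore_attr = TRUE)
  expect_equal(V[!inside, "T001"], V[!inside, "N001"])
  expect_true(all(V > 0))
  # +0.58 (~3 copies) recovered from the probe means under noise
  spec2 <- data.frame(sample = 1, chrom = "chr1", start = 0L,
                      end = 600000L, log2_ratio = 0.58)
  sim2 <- simulate_intensities(ann, 2, 2, spec2, noise_sd = 0.1, seed = 5)
  inside2 <- ann$probes$pos < 600000
  expect_gte(sum(inside2), 50)
  lr <- log2(sim2$intensity$values[inside2, "T001"] /
               rowMeans(sim2$intensity$values[inside2, c("N001", "N002")]))
  expect_lt(abs(mean(lr) - 0.58), 0.05)
  # overlapping segments rejected
  bad <- data.frame(sample = c(1, 1), chrom = "chr1",
                    start = c(0L, 1000L), end = c(2000L, 3000L),
                    log2_ratio = 1)
  expect_error(simulate_intensities(ann, 2, 2, bad, 0, 1), "overlapping")
})

test_that("catalog sampling matches the mixture distribution", {
  refs <- random_signatures(4, seed = 8)
  cat1 <- simulate_catalog(refs, c(0, 1, 0, 0), 10000, seed = 13)
  emp <- table(factor(cat1$channel, levels = sbs_channels())) / nrow(cat1)
  tv <- 0.5 * sum(abs(as.numeric(emp) - refs[2, ]))
  expect_lt(tv, 0.05)
  expect_equal(nrow(simulate_catalog(refs, c(1, 0, 0, 0), 1, seed = 1)), 1)
  expect_error(simulate_catalog(refs, c(1, 0, 0, 0), 0, seed = 1), "positive")
  expect_error(simulate_catalog(refs, c(0.5, 0.5, 0.5, 0), 10, 1), "sum to 1")
})

test_that("mixtures are exact weighted averages of the reference panel", {
  pan <- make_reference_panel(3, 60, 10, seed = 4)$panel
  one <- simulate_mixture(pan, c(0, 1, 0), noise_sd = 0)
  expect_equal(one$values[, 1], pan$betas[2, ], ignore_attr = TRUE)
  half <- simulate_mixture(pan, c(0.5, 0.5, 0), noise_sd = 0)
  expect_equal(half$values[, 1], (pan$betas[1, ] + pan$betas[2, ]) / 2,
               ignore_attr = TRUE)
  expect_error(simulate_mixture(pan, c(0.5, 0.5), 0), "cell types")
})
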