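test_that("log2 ratio is zero for a tumor equal to the normal mean", {
  ann <- make_annotation(1, 10, 80, seed = 3)
  sim <- simulate_intensities(ann, 1, 3, NULL, noise_sd = 0, seed = 3)
  tr <- log2_ratio(sim$intensity, "T001", c("N001", "N002", "N003"), ann)
  expect_equal(tr$log2, rep(0, nrow(tr)))
  # doubling every intensity: all-1 track, 0 after median centering
  V2 <- sim$intensity$values
  V2[, "T001"] <- 2 * V2[, "T001"]
  tr2 <- log2_ratio(intensity_matrix(V2), "T001",
                    c("N001", "N002", "N003"), ann)
  expect_equal(tr2$log2, rep(0, nrow(tr2)))
  expect_error(log2_ratio(sim$intensity, "T001", "N001", ann), ">= 2 normal")
})

test_that("median centering maps a half-genome loss to a symmetric bimodal track", {
  ann <- make_annotation(1, 10, 100, seed = 4)
  mid <- stats::median(ann$probes$pos)
  # exactly half the probes at ratio 0.5: median log2 = -0.5, so the
  # centered track is bimodal at {+0.5, -0.5}
  spec <- data.frame(sample = 1, chrom = "chr1", start = 0L,
                     end = as.integer(mid) + 1L, log2_ratio = -1)
  sim <- simulate_intensities(ann, 1, 2, spec, noise_sd = 0, seed = 4)
  tr <- log2_ratio(sim$intensity, "T001", c("N001", "N002"), ann)
  expect_equal(sort(unique(round(tr$log2, 9))), c(-0.5, 0.5))
})

test_that("probe binning is greedy with tail merge and never undersized", {
  track <- data.frame(probe_id = paste0("p", 1:10), chrom = "chr1",
                      pos = seq(0L, 900L, by = 100L), log2 = 0.7)
  b <- bin_probes(track, 5)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_probes, c(5L, 5L))
  expect_equal(b$log2, c(0.7, 0.7))                  # mean of constants
  b12 <- bin_probes(rbind(track,
                          data.frame(probe_id = c("p11", "p12"),
                                     chrom = "chr1", pos = c(1000L, 1100L),
                                     log2 = 0.7)), 5)
  expect_equal(b12$n_probes, c(5L, 7L))              # trailing bin merged
  expect_true(all(b12$n_probes >= 5))
  small <- track[1:3, ]
  expect_error(suppressWarnings(bin_probes(small, 5)), "no chromosome")
  expect_warning(bin_probes(rbind(track,
                                  data.frame(probe_id = "q1", chrom = "chr2",
                                             pos = 1L, log2 = 0)), 5),
                 "chr2")
})

test_that("segmentation DP is exact and locates an implanted step", {
  # equals brute-force enumeration on short series
  set.seed(31)
  for (rep in 1:5) {
    x <- c(rnorm(6, 0), rnorm(6, 1.5))[sample(1:12)]
    pen <- runif(1, 0.1, 2)
    b <- data.frame(chrom = "chr1", start = seq_along(x) * 10L,
                    end = seq_along(x) * 10L + 1L, n_probes = 5L, log2 = x)
    segs <- segment_track(b, penalty = pen)
    got <- sum(vapply(seq_len(nrow(segs)), function(i) {
      v <- x[segs$start_bin[i]:segs$end_bin[i]]
      sum((v - mean(v))^2)
    }, numeric(1))) + pen * nrow(segs)
    expect_equal(got, oracle_segment_cost(x, pen), tolerance = 1e-9)
  }
  # constant track: one segment; infinite penalty: one segment
  cb <- data.frame(chrom = "chr1", start = 1:20 * 10L, end = 1:20 * 10L + 1L,
                   n_probes = 5L, log2 = 0.3)
  expect_equal(nrow(segment_track(cb)), 1)
  set.seed(32)
  nb <- cb; nb$log2 <- rnorm(20, 0, 0.3)
  expect_equal(nrow(segment_track(nb, penalty = 1e9)), 1)
  # step of height 1 at bin 50 of 100, noise 0.05, default penalty
  set.seed(33)
  sb <- data.frame(chrom = "chr1", start = 1:100 * 10L,
                   end = 1:100 * 10L + 1L, n_probes = 5L,
                   log2 = c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05)))
  ss <- segment_track(sb)
  expect_equal(nrow(ss), 2)
  expect_lte(abs(ss$end_bin[1] - 50), 1)
  expect_error(segment_track(transform(sb, log2 = c(NA, log2[-1]))),
               "non-finite")
})

test_that("gene calls apply length weighting and strict outward thresholds", {
  ann <- tiny_annotation()
  segs <- structure(data.frame(
    sample = "S1", chrom = "chr1",
    start = c(0L, 20000L), end = c(20000L, 60000L),
    start_bin = c(1L, 3L), end_bin = c(2L, 5L),
    n_bins = c(2L, 3L), mean_log2 = c(0.6, 0.0),
    stringsAsFactors = FALSE), class = c("segment_set", "data.frame"))
  gc <- gene_calls(segs, ann)
  # gA body [10000, 30000): equal 10 kb overlap with both segments
  expect_equal(unname(gc$log2["gA", "S1"]), 0.3)
  expect_equal(unname(gc$state["gA", "S1"]), 1L)
  expect_equal(unname(gc$state["gB", "S1"]), 0L)
  # threshold grid via the direct constructor
  L2 <- matrix(c(0, -1.2, -0.5, 0.5, 1.4, -1.0), 6, 1,
               dimnames = list(paste0("g", 1:6), "S"))
  st <- gene_cna_from_log2(L2)$state[, 1]
  expect_equal(unname(st), c(0L, -2L, -1L, 1L, 2L, -1L))  # -1.0 not < -1.0
  expect_error(gene_calls(segs, ann, thresholds = c(t_amp = -1, t_del = -0.2,
                                                    t_amp2 = 1, t_del2 = -2)),
               "thresholds")
  # gene overlapping no segment: state 0, flagged missing
  segs2 <- segs[1, ]
  segs2$end <- 15000L
  gc2 <- gene_calls(structure(segs2, class = c("segment_set", "data.frame")),
                    ann)
  expect_equal(unname(gc2$state["gB", "S1"]), 0L)
  expect_true(gc2$missing["gB", "S1"])
})

test_that("recurrence scores separate an 8/10 deletion from background", {
  set.seed(41)
  n_genes <- 200
  L2 <- matrix(rnorm(n_genes * 10, 0, 0.08), n_genes, 10,
               dimnames = list(sprintf("g%03d", 1:n_genes),
                               sprintf("S%02d", 1:10)))
  L2["g050", 1:8] <- -1
  gc <- gene_cna_from_log2(L2)
  rec <- recurrence(gc, n_perm = 2000, seed = 5)
  del <- rec[rec$direction == "del", ]
  expect_lt(del$q_value[del$gene_id == "g050"], 0.05)
  expect_gt(del$q_value[del$gene_id == "g120"], 0.2)
  expect_equal(del$frequency[del$gene_id == "g050"], 0.8)
  # linearity: doubling amplitudes doubles every G-score
  rec2 <- recurrence(gene_cna_from_log2(2 * L2), n_perm = 200, seed = 5)
  expect_equal(rec2$g_score, 2 * rec$g_score[match(
    paste(rec2$gene_id, rec2$direction),
    paste(rec$gene_id, rec$direction))], tolerance = 1e-12)
  # all-zero matrix: G = 0 and p = 1 everywhere
  Z <- matrix(0, 20, 5, dimnames = list(paste0("g", 1:20), paste0("S", 1:5)))
  rz <- recurrence(gene_cna_from_log2(Z), n_perm = 200, seed = 1)
  expect_true(all(rz$g_score == 0))
  expect_true(all(rz$p_value == 1))
  expect_error(recurrence(gc, n_perm = 50), "n_perm")
})
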