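tiling_reads <- function() {
  data.frame(contig = "r", start = seq(0, 900, by = 100), width = 100L)
}

test_that("mean depth is exact for tiling, empty and oracle-checked inputs", {
  reg <- data.frame(name = "r", contig = "r", start = 0, end = 1000)
  expect_equal(region_depth(tiling_reads(), reg)$mean_depth, 1.0)

  empty <- data.frame(contig = character(), start = integer(),
                      width = integer())
  expect_equal(region_depth(empty, reg)$mean_depth, 0)

  set.seed(51)
  reads <- data.frame(
    contig = sample(c("r", "other"), 300, replace = TRUE),
    start = sample.int(1200, 300, replace = TRUE) - 1L,
    width = sample(30:80, 300, replace = TRUE))
  got <- region_depth(reads, data.frame(name = "r", contig = "r",
                                        start = 100, end = 700))
  expect_equal(got$mean_depth, oracle_mean_depth(reads, "r", 100, 700),
               tolerance = 1e-12)

  # depth-table input agrees with the read-record path
  pos <- 0:1199
  depth_tab <- data.frame(
    contig = "r", pos = pos,
    depth = vapply(pos, function(p) {
      rd <- reads[reads$contig == "r", ]
      sum(rd$start <= p & rd$start + rd$width > p)
    }, numeric(1)))
  got2 <- region_depth(depth_tab, data.frame(name = "r", contig = "r",
                                             start = 100, end = 700))
  expect_equal(got2$mean_depth, got$mean_depth, tolerance = 1e-12)
})

test_that("split regions average over the union of their intervals", {
  reads <- tiling_reads()
  reg <- data.frame(name = c("s", "s"), contig = "r",
                    start = c(0, 800), end = c(100, 1000))
  got <- region_depth(reads, reg)
  expect_equal(got$n_bases, 300L)
  expect_equal(got$mean_depth, 1.0)
})

test_that("secondary/supplementary/unmapped records are not counted", {
  reads <- tiling_reads()
  reads$flag <- 0L
  reads$flag[1:3] <- c(256L, 2048L, 4L)
  reg <- data.frame(name = "r", contig = "r", start = 0, end = 1000)
  expect_equal(region_depth(reads, reg)$mean_depth, 0.7)
  expect_error(region_depth(reads, data.frame(name = "z", contig = "r",
                                              start = 5, end = 5)),
               "zero-length")
})

test_that("WGBS copy number is 2x the 18S/exome depth ratio", {
  expect_equal(estimate_cn_wgbs(
    depth_summary("s", 7, 7, 1874, 1000))$value, 2)
  expect_equal(estimate_cn_wgbs(
    depth_summary("s", 0, 7, 1874, 1000))$value, 0)
  df <- data.frame(sample_id = "s", mean_depth_18S = 10,
                   mean_depth_exome = 0)
  expect_error(estimate_cn_wgbs(df), "exome depth")

  # scale invariance: multiplying all depths leaves CN unchanged
  set.seed(52)
  d18 <- runif(20, 100, 4000); dex <- runif(20, 5, 30)
  base <- estimate_cn_wgbs(data.frame(sample_id = as.character(1:20),
                                      mean_depth_18S = d18,
                                      mean_depth_exome = dex))$value
  scaled <- estimate_cn_wgbs(data.frame(sample_id = as.character(1:20),
                                        mean_depth_18S = 3.7 * d18,
                                        mean_depth_exome = 3.7 * dex))$value
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("RRBS relative copy number is the rDNA read fraction", {
  cnt <- data.frame(sample_id = c("a", "b"),
                    rdna_aligned_reads = c(0, 500),
                    total_alignments = c(1e6, 1e6))
  est <- estimate_cn_rrbs(cnt)
  expect_equal(est$value, c(0, 5e-4))
  expect_identical(est$method, rep("rrbs_relative", 2))
  # doubling total effort leaves the ratio unchanged exactly
  cnt2 <- cnt; cnt2$rdna_aligned_reads <- cnt$rdna_aligned_reads * 2
  cnt2$total_alignments <- cnt$total_alignments * 2
  expect_equal(estimate_cn_rrbs(cnt2)$value, est$value)
  expect_error(estimate_cn_rrbs(
    data.frame(sample_id = "a", rdna_aligned_reads = 1,
               total_alignments = 0)), "total alignments")
})

test_that("both estimators are rank-monotone in true copy number (noise-free)", {
  cn <- c(150, 220, 305, 410, 590)
  ds <- data.frame(sample_id = as.character(1:5),
                   mean_depth_18S = cn / 2 * 14, mean_depth_exome = 14)
  expect_identical(order(estimate_cn_wgbs(ds)$value), order(cn))
  cnt <- data.frame(sample_id = as.character(1:5),
                    rdna_aligned_reads = round(cn * 10),
                    total_alignments = 1e6)
  expect_identical(order(estimate_cn_rrbs(cnt)$value), order(cn))
})

test_that("ddPCR copy number scales FAM/VIC by reference ploidy and applies the Lambda cut", {
  wells <- data.frame(sample_id = c("a", "b", "c", "d"),
                      target_concentration = c(50, 100, 100, 80),
                      reference_concentration = c(50, 1, 100, 80),
                      lambda_cp_per_rxn = c(0.5, 0.5, 1.6, 1.59))
  res <- estimate_cn_ddpcr(wells)
  expect_identical(res$excluded$sample_id, "c")   # lambda = 1.6 excluded
  expect_identical(res$estimates$sample_id, c("a", "b", "d"))
  expect_equal(res$estimates$value, c(2, 200, 2))
  expect_error(estimate_cn_ddpcr(
    data.frame(sample_id = "x", target_concentration = 1,
               reference_concentration = 0, lambda_cp_per_rxn = 0.2)),
    "reference concentration")
})

test_that("cross-validation correlates estimates on shared samples only", {
  a <- data.frame(sample_id = as.character(1:6),
                  method = "wgbs_absolute", value = 1:6)
  b <- data.frame(sample_id = as.character(1:6), method = "rrbs_relative",
                  value = (1:6) / 100)
  cv <- cross_validate(a, b)
  expect_equal(cv$spearman_r, 1)
  b_rev <- b; b_rev$value <- rev(b$value)
  expect_equal(cross_validate(a, b_rev)$spearman_r, -1)
  # intersection only
  b_part <- b[1:4, ]
  expect_equal(cross_validate(a, b_part)$n, 4L)
  expect_error(cross_validate(a, b[1:2, ]), "at least 3")
})

test_that("down-sampling partitions exhaustively and is seed-deterministic", {
  sr <- simulate_reads(true_cn = 300, exome_bases = 30000L, seed = 53)
  ds <- downsampling_stability(sr$reads, sr$regions, seed = 54)
  part <- attr(ds, "partition")
  expect_identical(length(part), nrow(sr$reads))       # exhaustive
  sizes <- table(part)
  expect_identical(length(sizes), 10L)                 # disjoint cover
  expect_lte(max(sizes) - min(sizes), 1)               # equal split
  expect_identical(sum(sizes), nrow(sr$reads))

  ds2 <- downsampling_stability(sr$reads, sr$regions, seed = 54)
  expect_identical(ds$cn, ds2$cn)
  expect_identical(attr(ds2, "partition"), part)

  # fraction 1.0 reproduces the full-data estimate exactly
  ds3 <- downsampling_stability(sr$reads, sr$regions, fractions = 1.0,
                                seed = 54)
  expect_equal(ds3$cn, attr(ds3, "full_cn"))
  expect_equal(ds3$rel_dev, 0)

  expect_warning(
    downsampling_stability(sr$reads, sr$regions, fractions = 0.45,
                           seed = 54),
    "rounded")
})
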