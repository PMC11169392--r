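test_that("bismark coverage parsing converts coordinates and trusts counts", {
  f <- tempfile()
  writeLines(c("rDNA\t101\t101\t75.0\t3\t1",
               "rDNA\t51\t51\t0.0\t0\t40"), f)
  rec <- read_cpg_calls(f)
  expect_identical(rec$pos, c(50L, 100L))      # sorted, 0-based
  expect_identical(rec$methylated, c(0L, 3L))
  expect_identical(rec$unmethylated, c(40L, 1L))

  writeLines(character(0), f)
  expect_identical(nrow(read_cpg_calls(f)), 0L)

  writeLines("rDNA\t10\t10\t50", f)
  expect_error(read_cpg_calls(f), "malformed")

  writeLines("rDNA\t10\t10\t10.0\t9\t1", f)  # 90% methylated, says 10%
  expect_warning(read_cpg_calls(f), "inconsistent")
})

test_that("coverage files round-trip losslessly", {
  set.seed(61)
  tab <- random_cpg_table(150)
  f <- tempfile()
  write_cpg_calls(tab, f)
  back <- read_cpg_calls(f)
  rownames(back) <- rownames(tab) <- NULL
  expect_equal(back, tab)
})

test_that("region methylation applies the 50-read filter and both weightings", {
  rec <- data.frame(contig = "rDNA", pos = c(10L, 20L, 30L),
                    methylated = c(60L, 60L, 60L),
                    unmethylated = c(0L, 0L, 0L))
  s <- region_methylation(rec, data.frame(start = 0, end = 100))
  expect_equal(s$mean_methylation, 1)
  expect_identical(s$n_cpgs_used, 3L)

  rec2 <- data.frame(contig = "rDNA", pos = c(10L, 20L),
                     methylated = c(60L, 0L),
                     unmethylated = c(0L, 40L))
  s2 <- region_methylation(rec2, data.frame(start = 0, end = 100))
  expect_equal(s2$mean_methylation, 1)     # 40x CpG filtered out
  expect_identical(s2$n_cpgs_filtered, 1L)

  # no survivor: explicit empty signal, not zero
  s3 <- region_methylation(rec2, data.frame(start = 0, end = 100),
                           min_coverage = 1000L)
  expect_true(s3$empty)
  expect_true(is.na(s3$mean_methylation))
})

test_that("regional means equal the sigma-ratio oracle under both weightings", {
  set.seed(62)
  for (rep in 1:5) {
    rec <- random_cpg_table(200)
    for (w in c("coverage", "cpg")) {
      got <- region_methylation(rec, data.frame(start = 300, end = 1500),
                                min_coverage = 50L, weighting = w)
      want <- oracle_region_meth(rec, 300, 1500, 50, w)
      expect_equal(got$mean_methylation, want$mean, tolerance = 1e-12)
      expect_identical(got$n_cpgs_used, length(want$used))
    }
  }
})

test_that("coverage-weighted mean is conserved under region splitting", {
  set.seed(63)
  rec <- random_cpg_table(120)
  whole <- region_methylation(rec, data.frame(start = 0, end = 2000),
                              min_coverage = 30L)
  halves <- region_methylation(
    rec, data.frame(start = c(0, 700), end = c(700, 2000)),
    min_coverage = 30L)
  expect_equal(halves$mean_methylation, whole$mean_methylation,
               tolerance = 1e-12)
  expect_identical(halves$n_cpgs_used, whole$n_cpgs_used)
  # raising min_coverage never recovers CpGs
  stricter <- region_methylation(rec, data.frame(start = 0, end = 2000),
                                 min_coverage = 60L)
  expect_lte(stricter$n_cpgs_used, whole$n_cpgs_used)
  # conservation: weighted mean = total methylated / total reads
  expect_equal(whole$mean_methylation,
               sum(rec$methylated[rec$methylated + rec$unmethylated >= 30]) /
                 whole$total_coverage, tolerance = 1e-12)
})

test_that("rDNA promoter-and-unit window works across the loop junction", {
  # all CpGs at 80%: mean is 0.80 regardless of geometry
  ann <- rdna_annotation(4000, tss = 2000, transcript_end = 3500)
  lr <- build_looped_unit(random_dna(4000), derive_breakpoint(ann, 1000L),
                          ann)
  pos <- seq(0L, 2400L, by = 40L)  # looped window is [0, 2500)
  rec <- data.frame(contig = "rDNA_looped", pos = pos,
                    methylated = 80L, unmethylated = 20L)
  s <- rdna_methylation(rec, lr)
  expect_equal(s$mean_methylation, 0.8)
  expect_identical(s$n_cpgs_filtered, 0L)

  # window crossing the junction: two looped intervals, same answer as
  # recomputing in native coordinates
  ann2 <- rdna_annotation(4000, tss = 300, transcript_end = 1800)
  bp2 <- derive_breakpoint(ann2, 1000L)  # 3300; window wraps native 3300..1800
  lr2 <- build_looped_unit(random_dna(4000), bp2, ann2)
  set.seed(64)
  native_pos <- c(3300:3999, 0:1799)
  cpg_native <- sort(sample(native_pos, 80))
  cov <- rpois(80, 120); meth <- rbinom(80, cov, 0.3)
  rec2 <- data.frame(
    contig = "rDNA_looped",
    pos = native_to_looped(cpg_native, lr2),
    methylated = meth, unmethylated = cov - meth)
  s2 <- rdna_methylation(rec2, lr2, promoter_upstream = 1000L)
  keep <- cov >= 50
  expect_equal(s2$mean_methylation, sum(meth[keep]) / sum(cov[keep]),
               tolerance = 1e-12)
  expect_identical(s2$n_cpgs_used, sum(keep))
})

test_that("annotated subregions are selectable by name", {
  ann <- rdna_annotation(
    4000, tss = 2000, transcript_end = 3500,
    regions = data.frame(name = c("UCE", "core_promoter"),
                         start = c(1850, 1950), end = c(1930, 2010)))
  lr <- build_looped_unit(random_dna(4000), derive_breakpoint(ann, 1000L),
                          ann)
  rec <- data.frame(contig = "rDNA_looped",
                    pos = native_to_looped(c(1860L, 1960L), lr),
                    methylated = c(100L, 0L),
                    unmethylated = c(0L, 100L))
  expect_equal(rdna_methylation(rec, lr, region = "UCE")$mean_methylation,
               1)
  expect_equal(
    rdna_methylation(rec, lr, region = "core_promoter")$mean_methylation,
    0)
  expect_error(rdna_methylation(rec, lr, region = "nope"), "no annotated")
})

test_that("feature-class methylation and coverage use position containment", {
  rec <- data.frame(contig = "chr1", pos = c(10L, 20L, 500L),
                    methylated = c(5L, 10L, 7L),
                    unmethylated = c(5L, 10L, 0L))
  feats <- data.frame(class = c("exon", "intron"), contig = "chr1",
                      start = c(0, 900), end = c(100, 1000))
  res <- feature_methylation(rec, feats)
  exon <- res[res$class == "exon", ]
  expect_equal(exon$mean_coverage, 15)      # CpGs at 10 and 20 reads
  expect_identical(exon$n_cpgs, 2L)
  expect_equal(exon$mean_methylation, 15 / 30)
  intron <- res[res$class == "intron", ]
  expect_identical(intron$n_cpgs, 0L)       # CpG at 500 is outside all
  expect_true(is.na(intron$mean_methylation))

  # random fixture vs exhaustive containment oracle
  set.seed(65)
  rec2 <- random_cpg_table(150, contig = "chr1", max_pos = 5000L)
  feats2 <- data.frame(
    class = sample(c("exon", "promoter"), 12, replace = TRUE),
    contig = "chr1",
    start = st <- sample.int(4500, 12),
    end = st + sample(100:400, 12, replace = TRUE))
  res2 <- feature_methylation(rec2, feats2)
  for (cl in unique(feats2$class)) {
    fr <- feats2[feats2$class == cl, ]
    inside <- vapply(seq_len(nrow(rec2)), function(i)
      any(rec2$pos[i] >= fr$start & rec2$pos[i] < fr$end), logical(1))
    cov <- rec2$methylated[inside] + rec2$unmethylated[inside]
    row <- res2[res2$class == cl, ]
    expect_identical(row$n_cpgs, sum(inside))
    expect_equal(row$mean_coverage, mean(cov), tolerance = 1e-12)
    expect_equal(row$mean_methylation,
                 sum(rec2$methylated[inside]) / sum(cov),
                 tolerance = 1e-12)
  }
})

test_that("promoter windows are +-1 kb around the TSS", {
  pr <- promoters_from_tss(data.frame(contig = "chr1",
                                      pos = c(500L, 5000L)))
  expect_equal(pr$start, c(0, 4000))
  expect_equal(pr$end, c(1500, 6000))
})

test_that("methylation-adjusted copy number discounts silenced copies", {
  expect_equal(methylation_adjusted_cn(400, 0)$active_cn, 400)
  expect_equal(methylation_adjusted_cn(400, 1)$active_cn, 0)
  expect_error(methylation_adjusted_cn(400, NA_real_), "missing")
  expect_error(methylation_adjusted_cn(400, 1.2), "outside")
  # monotone: decreasing in methylation, increasing in copy number
  m <- seq(0, 1, by = 0.1)
  act <- methylation_adjusted_cn(rep(300, length(m)), m)$active_cn
  expect_true(all(diff(act) < 0))
  cn <- seq(100, 600, by = 50)
  act2 <- methylation_adjusted_cn(cn, rep(0.3, length(cn)))$active_cn
  expect_true(all(diff(act2) > 0))
})

test_that("active copy number tracks transcription better than raw copy number", {
  # nascent transcription proportional to CN*(1-m): adjusting for
  # methylation must improve the correlation
  set.seed(66)
  cfg <- sim_config(seed = 67, n_samples = 40, exome_bases = 2000L,
                    n_cpgs = 80L, emit = c("depth", "cpg"))
  sim <- simulate_cohort(cfg)
  est_cn <- cohort_wgbs_estimates(sim)$value
  est_m <- cohort_methylation_estimates(sim)$mean_methylation
  transcription <- sim$truth$true_active_cn *
    exp(rnorm(40, 0, 0.05))
  act <- methylation_adjusted_cn(
    data.frame(sample_id = sim$truth$sample_id, value = est_cn),
    est_m)$active_cn
  r_act <- spearman_correlation(act, transcription)$r
  r_raw <- spearman_correlation(est_cn, transcription)$r
  expect_gt(r_act, r_raw)
})
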