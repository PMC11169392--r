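#' Down-sampling stability of the copy-number estimate
#'
#' Checks whether the depth-ratio copy-number estimate is robust to
#' sequencing effort: the library's read records are split into
#' `n_subsamples` equal partitions (seeded shuffle, then round-robin
#' assignment, so partition sizes differ by at most one and the partition
#' is exhaustive and disjoint), and for each requested fraction `f` the
#' estimate is recomputed on the merge of `round(f * n_subsamples)`
#' randomly chosen partitions. Identical seeds give identical partitions,
#' selections and estimates.
#'
#' @param reads Read-record `data.frame` (`contig`, `start`, `width`), as
#'   produced by [simulate_reads()] or [read_alignments()].
#' @param regions Region table (see [region_depth()]) naming the rDNA and
#'   exome regions used by the estimator.
#' @param n_subsamples Number of equal partitions (default 10).
#' @param fractions Coverage fractions to evaluate (default 0.9 down to
#'   0.1). Fractions that are not multiples of `1/n_subsamples` are
#'   rounded to the nearest subsample count with a warning.
#' @param seed Integer seed controlling the shuffle and the subsample
#'   selections.
#' @param sample_id,rdna_region,exome_region Passed to
#'   [depth_from_alignments()].
#' @return `data.frame` with one row per fraction: `fraction`,
#'   `n_subsamples_used`, `n_reads`, `cn`, `rel_dev` (relative deviation
#'   from the full-data estimate). The full-data estimate and the
#'   partition assignment are attached as attributes `full_cn` and
#'   `partition`.
#' @export
downsampling_stability <- function(reads, regions, n_subsamples = 10L,
                                   fractions = seq(0.9, 0.1, by = -0.1),
                                   seed = NULL, sample_id = "sample",
                                   rdna_region = "18S",
                                   exome_region = "exome") {
  n <- nrow(reads)
  if (n < n_subsamples) stop("fewer reads than subsamples")
  est <- function(rd) {
    estimate_cn_wgbs(depth_from_alignments(
      rd, regions, sample_id = sample_id,
      rdna_region = rdna_region, exome_region = exome_region))$value
  }
  full_cn <- est(reads)

  with_seed(seed, {
    perm <- sample.int(n)
    group <- integer(n)
    group[perm] <- rep_len(seq_len(n_subsamples), n)

    rows <- lapply(fractions, function(f) {
      m_exact <- f * n_subsamples
      m <- as.integer(round(m_exact))
      if (abs(m_exact - m) > 1e-8) {
        warning("fraction ", f, " is not a multiple of 1/", n_subsamples,
                "; rounded to ", m, " subsamples")
      }
      if (m < 1L) stop("fraction ", f, " selects no subsamples")
      chosen <- if (m >= n_subsamples) seq_len(n_subsamples)
                else sample.int(n_subsamples, m)
      sub <- reads[group %in% chosen, , drop = FALSE]
      cn <- est(sub)
      data.frame(fraction = f, n_subsamples_used = m, n_reads = nrow(sub),
                 cn = cn, rel_dev = (cn - full_cn) / full_cn)
    })
    out <- do.call(rbind, rows)
    attr(out, "full_cn") <- full_cn
    attr(out, "partition") <- group
    out
  })
}
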