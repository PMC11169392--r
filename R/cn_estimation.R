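#' Absolute rDNA copy number from WGBS depth ratios
#'
#' The rDNA unit is tandemly repeated, so read depth over it scales with
#' the number of copies; the single-copy exome anchors the per-haploid
#' depth. Copy number on the diploid scale is
#' \deqn{CN = 2 \times \frac{\bar d_{18S}}{\bar d_{exome}}}
#' with \eqn{\bar d} the per-base mean unique-read depth.
#'
#' @param depth A `depth_summary` (see [depth_from_alignments()]) or a
#'   `data.frame` with columns `sample_id`, `mean_depth_18S`,
#'   `mean_depth_exome` for many samples at once.
#' @return Copy-number table: `data.frame` with `sample_id`, `method`
#'   (`"wgbs_absolute"`), `value` (copies per diploid genome) and
#'   `inputs_digest`.
#' @examples
#' ds <- depth_summary("s1", 1400, 7, 1874, 50000)
#' estimate_cn_wgbs(ds)$value  # 400
#' @export
estimate_cn_wgbs <- function(depth) {
  if (inherits(depth, "depth_summary")) {
    depth <- data.frame(sample_id = depth$sample_id,
                        mean_depth_18S = depth$mean_depth_18S,
                        mean_depth_exome = depth$mean_depth_exome,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "mean_depth_18S", "mean_depth_exome") %in%
                  names(depth)))
  if (any(!is.finite(depth$mean_depth_exome)) ||
      any(depth$mean_depth_exome <= 0)) {
    stop("zero or non-finite exome depth: copy number undefined")
  }
  if (any(depth$mean_depth_18S < 0)) stop("negative 18S depth")
  value <- 2 * depth$mean_depth_18S / depth$mean_depth_exome
  digest <- vapply(seq_len(nrow(depth)), function(i)
    inputs_digest(mean_depth_18S = depth$mean_depth_18S[i],
                  mean_depth_exome = depth$mean_depth_exome[i]),
    character(1))
  cn_table(depth$sample_id, "wgbs_absolute", value, digest)
}

#' Relative rDNA copy number from RRBS read fractions
#'
#' RRBS libraries cover the exome too patchily for a depth-ratio
#' denominator, so copy number is instead expressed as the fraction of
#' all alignments that land on the rDNA contig: the number of reads
#' aligned to the rDNA divided by the total number of alignments reported
#' for the library. The result is a unitless relative (not absolute) copy
#' number, comparable only across individuals; mix it with absolute
#' estimates only through ranks (see [cross_validate()]).
#'
#' @param counts `data.frame` with columns `sample_id`,
#'   `rdna_aligned_reads`, `total_alignments`.
#' @return Copy-number table with `method = "rrbs_relative"`.
#' @examples
#' estimate_cn_rrbs(data.frame(sample_id = "s1",
#'                             rdna_aligned_reads = 500,
#'                             total_alignments = 1e6))$value  # 5e-04
#' @export
estimate_cn_rrbs <- function(counts) {
  stopifnot(all(c("sample_id", "rdna_aligned_reads", "total_alignments")
                %in% names(counts)))
  if (any(counts$total_alignments <= 0)) stop("zero total alignments")
  if (any(counts$rdna_aligned_reads < 0) ||
      any(counts$rdna_aligned_reads > counts$total_alignments)) {
    stop("rdna_aligned_reads must lie in [0, total_alignments]")
  }
  value <- counts$rdna_aligned_reads / counts$total_alignments
  digest <- vapply(seq_len(nrow(counts)), function(i)
    inputs_digest(rdna_aligned_reads = counts$rdna_aligned_reads[i],
                  total_alignments = counts$total_alignments[i]),
    character(1))
  cn_table(counts$sample_id, "rrbs_relative", value, digest)
}

#' rDNA copy number from droplet digital PCR
#'
#' Copy number is the target (FAM-channel 18S) concentration over the
#' single-copy reference (VIC-channel) concentration, scaled by the
#' reference ploidy (2 for a diploid autosomal reference). Wells whose
#' Lambda (mean template copies per partition, Cp/Rxn) is at or above the
#' threshold violate the Poisson quantification assumption and are
#' excluded with a recorded reason.
#'
#' @param wells `data.frame` with columns `sample_id`,
#'   `target_concentration`, `reference_concentration`,
#'   `lambda_cp_per_rxn`; optional `reference_ploidy` (default 2).
#' @param lambda_threshold Exclusion threshold on Lambda (default 1.6;
#'   wells with Lambda >= threshold are excluded).
#' @return List with `estimates` (copy-number table, `method = "ddpcr"`)
#'   and `excluded` (`data.frame` of excluded wells with reasons).
#' @export
estimate_cn_ddpcr <- function(wells, lambda_threshold = 1.6) {
  req <- c("sample_id", "target_concentration", "reference_concentration",
           "lambda_cp_per_rxn")
  stopifnot(all(req %in% names(wells)))
  if (!"reference_ploidy" %in% names(wells)) wells$reference_ploidy <- 2
  if (any(wells$reference_concentration <= 0)) {
    stop("zero reference concentration: copy number undefined")
  }
  if (any(wells$target_concentration < 0) ||
      any(wells$lambda_cp_per_rxn < 0)) {
    stop("negative concentration or Lambda")
  }
  drop <- wells$lambda_cp_per_rxn >= lambda_threshold
  excluded <- data.frame(
    sample_id = wells$sample_id[drop],
    reason = rep("lambda_at_or_above_threshold", sum(drop)),
    lambda_cp_per_rxn = wells$lambda_cp_per_rxn[drop],
    stringsAsFactors = FALSE)
  kept <- wells[!drop, , drop = FALSE]
  value <- kept$reference_ploidy * kept$target_concentration /
    kept$reference_concentration
  digest <- vapply(seq_len(nrow(kept)), function(i)
    inputs_digest(target = kept$target_concentration[i],
                  reference = kept$reference_concentration[i],
                  lambda = kept$lambda_cp_per_rxn[i],
                  reference_ploidy = kept$reference_ploidy[i]),
    character(1))
  list(estimates = cn_table(kept$sample_id, "ddpcr", value, digest),
       excluded = excluded)
}

cn_table <- function(sample_id, method, value, digest = NA_character_) {
  stopifnot(all(value >= 0))
  data.frame(sample_id = as.character(sample_id), method = method,
             value = value, inputs_digest = digest,
             stringsAsFactors = FALSE)
}

#' Cross-validate two copy-number estimate sets
#'
#' Correlates two per-sample copy-number tables (e.g. the absolute WGBS
#' estimator against the relative RRBS estimator) on the samples they
#' share. Because the two methods may live on different scales, the
#' primary comparison is rank-based (Spearman); Pearson is reported
#' alongside.
#'
#' @param estimates_a,estimates_b Copy-number tables as returned by the
#'   `estimate_cn_*` functions (columns `sample_id`, `value`).
#' @return List with `n`, `spearman_r`, `spearman_p`, `pearson_r`,
#'   `pearson_p`, `methods`, and the shared `sample_id`s.
#' @export
cross_validate <- function(estimates_a, estimates_b) {
  shared <- intersect(estimates_a$sample_id, estimates_b$sample_id)
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples, got ", length(shared))
  }
  a <- estimates_a$value[match(shared, estimates_a$sample_id)]
  b <- estimates_b$value[match(shared, estimates_b$sample_id)]
  sp <- spearman_correlation(a, b)
  pe <- stats::cor.test(a, b, method = "pearson")
  list(n = length(shared),
       spearman_r = sp$r, spearman_p = sp$p,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       methods = c(a = estimates_a$method[1], b = estimates_b$method[1]),
       sample_id = shared)
}
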