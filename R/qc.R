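#' Sample-exclusion policy for bisulfite libraries
#'
#' Thresholds behind the per-sample QC rules. The source criteria are
#' qualitative ("extremely high or low uniquely mapped reads, poor
#' mapping efficiency, poor bisulfite conversion"), so the numbers are
#' explicit policy here and are echoed into every verdict's provenance.
#'
#' @param read_count_mad_k Samples whose uniquely mapped read count lies
#'   beyond median +- k*MAD are flagged (robust outlier rule, default 3).
#' @param min_mapping_efficiency Minimum acceptable mapping efficiency
#'   (fraction, default 0.6).
#' @param max_non_cpg_methylation Maximum non-CpG methylation; higher
#'   values indicate incomplete bisulfite conversion (default 0.02).
#' @param rrbs_total_meth_sd_k RRBS-only: samples whose total CpG
#'   methylation lies beyond mean +- k*SD are flagged (default 3);
#'   extreme values indicate digestion/size-selection problems shifting
#'   the captured fraction of the genome.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(read_count_mad_k = 3,
                      min_mapping_efficiency = 0.6,
                      max_non_cpg_methylation = 0.02,
                      rrbs_total_meth_sd_k = 3) {
  stopifnot(read_count_mad_k > 0, min_mapping_efficiency > 0,
            max_non_cpg_methylation > 0, rrbs_total_meth_sd_k > 0)
  structure(list(read_count_mad_k = read_count_mad_k,
                 min_mapping_efficiency = min_mapping_efficiency,
                 max_non_cpg_methylation = max_non_cpg_methylation,
                 rrbs_total_meth_sd_k = rrbs_total_meth_sd_k),
            class = "qc_policy")
}

#' Apply sample QC to per-library sequencing metrics
#'
#' Evaluates each sample against the exclusion rules: a cohort-relative
#' uniquely-mapped-read-count outlier rule (median +- k*MAD), a mapping
#' efficiency floor, a bisulfite-conversion rule on non-CpG methylation,
#' and, for RRBS libraries, a cohort-relative total-CpG-methylation
#' outlier rule (mean +- k*SD). A sample is included exactly when no rule
#' fires; every verdict lists all rules that failed. Verdicts are
#' deterministic and independent of input order (cohort statistics are
#' computed on the full input).
#'
#' @param metrics `data.frame` with columns `sample_id`,
#'   `uniquely_mapped_reads`, `mapping_efficiency`,
#'   `non_cpg_methylation`, and for RRBS `total_cpg_methylation`;
#'   optional `assay` column (`"wgbs"`/`"rrbs"`, default `assay`
#'   argument).
#' @param policy A [qc_policy()].
#' @param assay Default assay when `metrics` lacks an `assay` column.
#' @return `data.frame` with `sample_id`, `included`, `reasons`
#'   (comma-separated failed rules, `""` when included). The thresholds
#'   actually applied are attached as attribute `policy`.
#' @export
apply_qc <- function(metrics, policy = qc_policy(), assay = "wgbs") {
  req <- c("sample_id", "uniquely_mapped_reads", "mapping_efficiency",
           "non_cpg_methylation")
  stopifnot(all(req %in% names(metrics)))
  if (nrow(metrics) == 0L) stop("empty cohort")
  num_cols <- intersect(c("uniquely_mapped_reads", "mapping_efficiency",
                          "non_cpg_methylation", "total_cpg_methylation"),
                        names(metrics))
  for (cl in num_cols) {
    if (any(!is.finite(metrics[[cl]]))) stop("non-finite metric in ", cl)
  }
  if (!"assay" %in% names(metrics)) metrics$assay <- assay

  reasons <- vector("list", nrow(metrics))

  med <- stats::median(metrics$uniquely_mapped_reads)
  mad_ <- stats::mad(metrics$uniquely_mapped_reads)
  if (nrow(metrics) >= 3L && mad_ > 0) {
    out_reads <- abs(metrics$uniquely_mapped_reads - med) >
      policy$read_count_mad_k * mad_
    for (i in which(out_reads)) {
      reasons[[i]] <- c(reasons[[i]], "read_count_outlier")
    }
  }

  low_eff <- metrics$mapping_efficiency < policy$min_mapping_efficiency
  for (i in which(low_eff)) {
    reasons[[i]] <- c(reasons[[i]], "mapping_efficiency")
  }

  bad_conv <- metrics$non_cpg_methylation > policy$max_non_cpg_methylation
  for (i in which(bad_conv)) {
    reasons[[i]] <- c(reasons[[i]], "bisulfite_conversion")
  }

  rrbs <- metrics$assay == "rrbs"
  if (any(rrbs) && "total_cpg_methylation" %in% names(metrics) &&
      sum(rrbs) >= 3L) {
    v <- metrics$total_cpg_methylation[rrbs]
    mu <- mean(v); sdv <- stats::sd(v)
    if (sdv > 0) {
      out_meth <- abs(v - mu) > policy$rrbs_total_meth_sd_k * sdv
      for (i in which(rrbs)[out_meth]) {
        reasons[[i]] <- c(reasons[[i]], "total_methylation_outlier")
      }
    }
  }

  out <- data.frame(
    sample_id = metrics$sample_id,
    included = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  attr(out, "policy") <- unclass(policy)
  out
}
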