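#' Read a bismark-style CpG coverage file
#'
#' Parses the six-column coverage format produced by
#' `bismark_methylation_extractor` (chromosome, start, end, percent
#' methylation, count methylated, count unmethylated). Start/end are
#' 1-based in the file and converted to the package's 0-based positions.
#' The percent column is redundant with the counts and is ignored in
#' favour of them; a warning is raised when it disagrees with the counts
#' beyond rounding.
#'
#' @param path Coverage file (TSV, optionally with no header).
#' @return `data.frame` of CpG records: `contig`, `pos` (0-based),
#'   `methylated`, `unmethylated`, sorted by (contig, pos).
#' @export
read_cpg_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), pos = integer(),
                      methylated = integer(), unmethylated = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    stop("malformed coverage line(s): ",
         paste(utils::head(which(nf < 6L), 5L), collapse = ", "))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  bad <- is.na(start1) | is.na(meth) | is.na(unmeth)
  if (any(bad)) {
    stop("malformed coverage line(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  cov <- meth + unmeth
  have_pct <- !is.na(pct) & cov > 0
  if (any(have_pct &
          abs(pct - 100 * meth / pmax(cov, 1L))[have_pct] > 0.51)) {
    warning("percent-methylation column inconsistent with counts; ",
            "counts used")
  }
  out <- data.frame(contig = m[, 1], pos = start1 - 1L,
                    methylated = meth, unmethylated = unmeth,
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Write CpG records in bismark coverage format
#'
#' @param records CpG record `data.frame` (as from [read_cpg_calls()]).
#' @param path Output file.
#' @export
write_cpg_calls <- function(records, path) {
  cov <- records$methylated + records$unmethylated
  pct <- ifelse(cov > 0, 100 * records$methylated / cov, 0)
  out <- data.frame(records$contig, records$pos + 1L, records$pos + 1L,
                    pct, records$methylated, records$unmethylated)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Region-level methylation summary
#'
#' Aggregates per-CpG methylated/unmethylated counts over a region (one
#' or several 0-based half-open intervals). CpGs with read coverage below
#' `min_coverage` are excluded and counted in `n_cpgs_filtered`; the
#' high threshold (default 50) is appropriate for the multicopy rDNA
#' contig, where per-CpG coverage is hundreds-fold — use
#' `min_coverage = 1` for single-copy features. Two weightings are
#' offered: `"coverage"` (the default) computes the read-weighted mean
#' \eqn{\sum M / \sum (M+U)} over retained CpGs; `"cpg"` averages the
#' per-CpG methylation fractions unweighted.
#'
#' @param records CpG record `data.frame` (`contig`, `pos`, `methylated`,
#'   `unmethylated`).
#' @param region `data.frame` with `start`, `end` (0-based half-open),
#'   optionally `contig`; multiple rows form a split region.
#' @param min_coverage Minimum combined-strand read coverage per CpG.
#' @param weighting `"coverage"` or `"cpg"`.
#' @param sample_id,region_name Labels carried into the summary.
#' @return An object of class `methylation_summary`: `sample_id`,
#'   `region_name`, `mean_methylation` (fraction, `NA` when no CpG
#'   survives the filter — see `empty`), `n_cpgs_used`, `n_cpgs_filtered`,
#'   `total_coverage`, `empty`.
#' @export
region_methylation <- function(records, region, min_coverage = 50L,
                               weighting = c("coverage", "cpg"),
                               sample_id = "sample",
                               region_name = "region") {
  weighting <- match.arg(weighting)
  stopifnot(all(c("start", "end") %in% names(region)), nrow(region) >= 1L)
  sel <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(region))) {
    hit <- records$pos >= region$start[i] & records$pos < region$end[i]
    if ("contig" %in% names(region) && !is.na(region$contig[i])) {
      hit <- hit & records$contig == region$contig[i]
    }
    sel <- sel | hit
  }
  inside <- records[sel, , drop = FALSE]
  cov <- inside$methylated + inside$unmethylated
  keep <- cov >= min_coverage
  used <- inside[keep, , drop = FALSE]
  mean_meth <- if (nrow(used) == 0L) NA_real_
  else if (weighting == "coverage") {
    sum(used$methylated) / sum(used$methylated + used$unmethylated)
  } else {
    mean(used$methylated / (used$methylated + used$unmethylated))
  }
  structure(
    list(sample_id = sample_id, region_name = region_name,
         mean_methylation = mean_meth,
         n_cpgs_used = nrow(used),
         n_cpgs_filtered = sum(!keep),
         total_coverage = sum(cov[keep]),
         weighting = weighting, min_coverage = min_coverage,
         empty = nrow(used) == 0L),
    class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat("methylation summary [", x$region_name, "] sample ", x$sample_id,
      ": ", sep = "")
  if (x$empty) cat("no CpGs passed the coverage filter\n")
  else cat(sprintf("mean %.4f over %d CpGs (%d filtered, %s-weighted)\n",
                   x$mean_methylation, x$n_cpgs_used, x$n_cpgs_filtered,
                   x$weighting))
  invisible(x)
}

#' rDNA promoter-and-unit methylation on the looped contig
#'
#' Mean methylation across the rDNA promoter (default 1000 bp upstream of
#' the TSS) together with the entire transcribed region, expressed on the
#' looped contig; the window is split into two intervals when it crosses
#' the loop junction. Named subregions of the annotation (e.g. `"UCE"`,
#' `"core_promoter"`, `"18S"`) can be summarised instead via `region`.
#'
#' @param records CpG records on the looped rDNA contig.
#' @param looped A `looped_reference` built with an annotation that has a
#'   `transcript_end`.
#' @param promoter_upstream Bases upstream of the TSS included (default
#'   1000).
#' @param region `"promoter_and_unit"` (default) or the name of an
#'   annotated subregion.
#' @param min_coverage,weighting,sample_id Passed to
#'   [region_methylation()].
#' @return A `methylation_summary`.
#' @export
rdna_methylation <- function(records, looped, promoter_upstream = 1000L,
                             region = "promoter_and_unit",
                             min_coverage = 50L,
                             weighting = c("coverage", "cpg"),
                             sample_id = "sample") {
  stopifnot(inherits(looped, "looped_reference"))
  weighting <- match.arg(weighting)
  if (region == "promoter_and_unit") {
    if (is.na(looped$transcript_end)) {
      stop("annotation lacks a transcript_end; cannot form the ",
           "promoter-and-unit window")
    }
    ann <- looped$annotation
    native_start <- (ann$tss - promoter_upstream) %% ann$unit_length
    width <- promoter_upstream + (ann$transcript_end - ann$tss)
    native <- data.frame(name = "promoter_and_unit",
                         start = native_start,
                         end = native_start + width)
    # window expressed relative to a start that may itself wrap: remap via
    # rotation after normalising the wrap into two native intervals
    if (native$end > ann$unit_length) {
      native <- data.frame(name = "promoter_and_unit",
                           start = c(native_start, 0L),
                           end = c(ann$unit_length,
                                   native$end - ann$unit_length))
    }
    ivs <- remap_regions(native, looped$breakpoint, looped$unit_length)
  } else {
    ivs <- looped_region(looped, region)
  }
  region_methylation(records, ivs, min_coverage = min_coverage,
                     weighting = weighting, sample_id = sample_id,
                     region_name = region)
}

#' Feature-class methylation and CpG coverage
#'
#' Assigns CpGs to annotated feature classes (exons, introns, promoters,
#' repeat families, ...) by position containment and reports, per class,
#' the methylation summary over all contained CpGs (no coverage filter:
#' outside the rDNA every CpG is analysed) plus the class's mean CpG read
#' coverage (mean of methylated+unmethylated over contained CpGs). A CpG
#' contained in several features of the same class is counted once.
#'
#' @param records CpG record `data.frame`.
#' @param features `data.frame` with columns `class`, `contig`, `start`,
#'   `end` (0-based half-open; `strand` optional and ignored for
#'   destranded CpG calls).
#' @param sample_id Label carried into the summaries.
#' @return `data.frame` with one row per feature class: `class`,
#'   `mean_methylation`, `n_cpgs`, `mean_coverage`. Classes containing no
#'   CpG get `NA` summaries and `n_cpgs = 0`.
#' @export
feature_methylation <- function(records, features, sample_id = "sample") {
  stopifnot(all(c("class", "contig", "start", "end") %in% names(features)))
  cpg_gr <- GenomicRanges::GRanges(
    seqnames = records$contig,
    ranges = IRanges::IRanges(start = records$pos + 1L, width = 1L))
  feat_gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end))
  hits <- GenomicRanges::findOverlaps(cpg_gr, feat_gr)
  classes <- unique(features$class)
  rows <- lapply(classes, function(cl) {
    feat_idx <- which(features$class == cl)
    cpg_idx <- unique(S4Vectors::queryHits(
      hits[S4Vectors::subjectHits(hits) %in% feat_idx]))
    if (!length(cpg_idx)) {
      return(data.frame(class = cl, mean_methylation = NA_real_,
                        n_cpgs = 0L, mean_coverage = NA_real_))
    }
    sub <- records[cpg_idx, , drop = FALSE]
    cov <- sub$methylated + sub$unmethylated
    data.frame(class = cl,
               mean_methylation = sum(sub$methylated) / sum(cov),
               n_cpgs = length(cpg_idx),
               mean_coverage = mean(cov))
  })
  out <- do.call(rbind, rows)
  out$sample_id <- sample_id
  out
}

#' Genome promoters from transcription start sites
#'
#' Promoters are the windows 1 kb upstream and downstream of each TSS
#' (total 2 kb), clipped at zero.
#'
#' @param tss `data.frame` with `contig`, `pos` (0-based TSS), optional
#'   `strand` (promoters are symmetric, so strand only labels output).
#' @param flank Half-width in bases (default 1000).
#' @return Feature `data.frame` with `class = "promoter"`.
#' @export
promoters_from_tss <- function(tss, flank = 1000L) {
  data.frame(class = "promoter", contig = tss$contig,
             start = pmax(0L, tss$pos - flank), end = tss$pos + flank,
             stringsAsFactors = FALSE)
}

#' Methylation-adjusted ("active") copy number
#'
#' Heavily methylated rDNA copies are transcriptionally silenced, so the
#' effective dosage of active units is smaller than the raw copy number.
#' The adjusted value discounts the methylated fraction:
#' `active_cn = cn * (1 - mean_methylation)`. The formula is recorded in
#' the output so downstream consumers can see the adjustment rule used.
#'
#' @param cn Copy-number table (columns `sample_id`, `value`) or a single
#'   numeric value.
#' @param meth A `methylation_summary`, a numeric methylation fraction,
#'   or a vector matching `cn` rows.
#' @return `data.frame` with `sample_id`, `raw_cn`, `mean_methylation`,
#'   `active_cn`, `formula`.
#' @export
methylation_adjusted_cn <- function(cn, meth) {
  if (is.numeric(cn)) cn <- data.frame(sample_id = "sample", value = cn)
  m <- if (inherits(meth, "methylation_summary")) meth$mean_methylation
       else as.numeric(meth)
  if (any(is.na(m))) stop("missing methylation summary")
  if (any(m < 0 | m > 1)) stop("methylation fraction outside [0, 1]")
  data.frame(sample_id = cn$sample_id, raw_cn = cn$value,
             mean_methylation = m,
             active_cn = cn$value * (1 - m),
             formula = "cn * (1 - mean_methylation)",
             stringsAsFactors = FALSE)
}
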