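#' Mean unique-read depth over named regions
#'
#' Computes, for each named region (a set of 0-based half-open intervals,
#' possibly on different contigs and possibly split, as happens to the 18S
#' when a looped rotation cuts through it), the per-base arithmetic mean
#' of unique-read coverage: the sum of per-base depth over the region
#' divided by the region length. Positions with no data count as depth 0.
#'
#' Input is either a per-base depth table (columns `contig`, `pos`
#' 0-based, `depth`; the `samtools depth` convention shifted to 0-based)
#' or a read-record table (columns `contig`, `start` 0-based, `width`,
#' optional `flag` and `mapq`). For read records, multi-mapping alignments
#' are excluded first: records with the secondary (0x100), supplementary
#' (0x800) or unmapped (0x4) SAM flag bits are dropped, and records below
#' `min_mapq` when a `mapq` column is present. For depth tables,
#' uniqueness is assumed to have been enforced upstream.
#'
#' @param x Depth table or read-record `data.frame` (see Details), or a
#'   `GAlignments` object.
#' @param regions `data.frame` with columns `name`, `contig`, `start`,
#'   `end` (0-based half-open); several rows may share a `name`.
#' @param min_mapq Minimum mapping quality for read records (default 0).
#' @return `data.frame` with `name`, `mean_depth`, `n_bases`.
#' @export
region_depth <- function(x, regions, min_mapq = 0L) {
  stopifnot(all(c("name", "contig", "start", "end") %in% names(regions)))
  if (nrow(regions) == 0L) stop("no regions supplied")
  if (any(regions$start >= regions$end)) stop("zero-length region")

  if (inherits(x, "GAlignments")) x <- alignments_to_reads(x)

  is_depth_table <- all(c("pos", "depth") %in% names(x))
  if (!is_depth_table && !all(c("start", "width") %in% names(x))) {
    stop("x must be a depth table (contig,pos,depth) or a read table ",
         "(contig,start,width)")
  }
  if (!is_depth_table) x <- filter_unique_reads(x, min_mapq)

  out <- lapply(split(regions, regions$name), function(rg) {
    total_len <- sum(rg$end - rg$start)
    covered <- 0
    for (i in seq_len(nrow(rg))) {
      ctg <- rg$contig[i]
      if (is_depth_table) {
        sel <- x$contig == ctg & x$pos >= rg$start[i] & x$pos < rg$end[i]
        covered <- covered + sum(x$depth[sel])
      } else {
        rd <- x[x$contig == ctg, , drop = FALSE]
        if (nrow(rd)) {
          ov_start <- pmax(rd$start, rg$start[i])
          ov_end <- pmin(rd$start + rd$width, rg$end[i])
          covered <- covered + sum(pmax(0, ov_end - ov_start))
        }
      }
    }
    data.frame(name = rg$name[1], mean_depth = covered / total_len,
               n_bases = as.integer(total_len))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# SAM-flag based uniqueness rule for generic alignment input.
filter_unique_reads <- function(reads, min_mapq = 0L) {
  if ("flag" %in% names(reads)) {
    bad <- bitwAnd(as.integer(reads$flag), 0x4L + 0x100L + 0x800L) != 0L
    reads <- reads[!bad, , drop = FALSE]
  }
  if (min_mapq > 0L && "mapq" %in% names(reads)) {
    reads <- reads[!is.na(reads$mapq) & reads$mapq >= min_mapq, ,
                   drop = FALSE]
  }
  reads
}

alignments_to_reads <- function(ga) {
  data.frame(contig = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             width = GenomicAlignments::width(ga),
             stringsAsFactors = FALSE)
}

#' Per-sample depth summary over the 18S and exome regions
#'
#' Bundles the two depth terms of the WGBS copy-number formula for one
#' sample: mean unique-read depth over the 18S interval of the (looped)
#' rDNA contig and over the retained single-copy exome.
#'
#' @param x Input accepted by [region_depth()].
#' @param regions Region table naming (at least) the rDNA and exome
#'   regions.
#' @param sample_id Sample identifier.
#' @param rdna_region,exome_region Names of the two regions in `regions`.
#' @param min_mapq Passed to [region_depth()].
#' @return An object of class `depth_summary`.
#' @export
depth_from_alignments <- function(x, regions, sample_id = "sample",
                                  rdna_region = "18S",
                                  exome_region = "exome",
                                  min_mapq = 0L) {
  d <- region_depth(x, regions, min_mapq = min_mapq)
  for (nm in c(rdna_region, exome_region)) {
    if (!nm %in% d$name) stop("region '", nm, "' absent from input regions")
  }
  r <- d[d$name == rdna_region, ]
  e <- d[d$name == exome_region, ]
  depth_summary(sample_id, r$mean_depth, e$mean_depth,
                r$n_bases, e$n_bases)
}

#' @rdname depth_from_alignments
#' @param mean_depth_18S,mean_depth_exome,n_bases_18S,n_bases_exome Raw
#'   components for constructing a summary directly.
#' @export
depth_summary <- function(sample_id, mean_depth_18S, mean_depth_exome,
                          n_bases_18S, n_bases_exome) {
  stopifnot(mean_depth_18S >= 0, mean_depth_exome >= 0,
            n_bases_18S > 0, n_bases_exome > 0)
  structure(list(sample_id = sample_id,
                 mean_depth_18S = mean_depth_18S,
                 mean_depth_exome = mean_depth_exome,
                 n_bases_18S = as.integer(n_bases_18S),
                 n_bases_exome = as.integer(n_bases_exome)),
            class = "depth_summary")
}

#' Read alignments from SAM/BAM into a read-record table
#'
#' Convenience reader for SAM/BAM restricted to the rDNA/exome contigs.
#' Requires the Rsamtools and GenomicAlignments packages; plain-text SAM
#' is converted on the fly.
#'
#' @param path SAM or BAM file.
#' @return Read-record `data.frame` (`contig`, `start` 0-based, `width`,
#'   `flag`, `mapq`) usable with [region_depth()].
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("Rsamtools and GenomicAlignments are required to read SAM/BAM")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = c("flag", "mapq")))
  data.frame(contig = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             width = GenomicAlignments::width(ga),
             flag = S4Vectors::mcols(ga)$flag,
             mapq = S4Vectors::mcols(ga)$mapq,
             stringsAsFactors = FALSE)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns: contig, position, depth. `samtools depth`
#' emits 1-based positions; set `one_based = TRUE` for such files and the
#' positions are shifted to the package's 0-based convention.
#'
#' @param path TSV file.
#' @param one_based Whether positions in the file are 1-based.
#' @return `data.frame` with `contig`, `pos` (0-based), `depth`.
#' @export
read_depth_table <- function(path, one_based = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "pos", "depth"),
                         stringsAsFactors = FALSE)
  if (one_based) d$pos <- d$pos - 1L
  d
}
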