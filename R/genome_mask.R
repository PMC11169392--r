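#' Read a pseudocopy mask from BED
#'
#' BED intervals are 0-based half-open, matching the package's internal
#' convention; no conversion is applied.
#'
#' @param path BED file (first three columns used).
#' @return `data.frame` with `contig`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
  out <- data.frame(contig = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  out
}

#' Hard-mask pseudocopies and append the looped rDNA contig
#'
#' Replaces every base inside the mask intervals with `N` (contig lengths
#' are unchanged) and appends the looped rDNA unit as one additional
#' contig. Masking rDNA pseudocopies scattered through the assembly
#' prevents reads of true rDNA origin from being siphoned off to (or
#' multi-mapping with) partial copies elsewhere, which would depress the
#' rDNA depth signal used for copy-number estimation.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector)
#'   of assembly contigs.
#' @param mask `data.frame` with `contig`, `start`, `end` (0-based
#'   half-open), e.g. from [read_mask_bed()]. May have zero rows.
#' @param looped A `looped_reference` from [build_looped_unit()], or a
#'   plain sequence (character / `DNAString`) to append verbatim.
#' @param extra_contig_name Name of the appended contig.
#' @return A `DNAStringSet` with `length(genome) + 1` contigs.
#' @export
mask_and_append <- function(genome, mask, looped,
                            extra_contig_name = "rDNA_looped") {
  genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome contigs must be named")
  }
  if (extra_contig_name %in% names(genome)) {
    stop("contig name collision: '", extra_contig_name,
         "' already present in the genome")
  }
  genome <- mask_contigs(genome, mask)
  app_seq <- if (inherits(looped, "looped_reference")) looped$sequence
             else as.character(looped)
  extra <- Biostrings::DNAStringSet(app_seq)
  names(extra) <- extra_contig_name
  c(genome, extra)
}

# Replace mask intervals with N runs; lengths preserved.
mask_contigs <- function(genome, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(genome)
  stopifnot(all(c("contig", "start", "end") %in% names(mask)))
  unknown <- setdiff(unique(mask$contig), names(genome))
  if (length(unknown)) {
    stop("mask interval on unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  for (ctg in unique(mask$contig)) {
    rows <- mask[mask$contig == ctg, , drop = FALSE]
    len <- Biostrings::width(genome[ctg])
    if (any(rows$start < 0) || any(rows$end > len)) {
      stop("mask interval out of bounds on contig ", ctg)
    }
    # merge overlaps so replaceAt sees disjoint ranges
    ir <- IRanges::reduce(IRanges::IRanges(start = rows$start + 1L,
                                           end = rows$end))
    repl <- Biostrings::DNAStringSet(strrep("N", IRanges::width(ir)))
    genome[[ctg]] <- Biostrings::replaceAt(genome[[ctg]], ir, repl)
  }
  genome
}

#' Build the rat reference: masked assembly plus the 18S contig
#'
#' The rat rDNA consensus covers only 18S through 28S, so no looped full
#' unit can be built; instead the 18S subsequence alone (unit positions
#' 1-1874, 1-based inclusive, i.e. `[0, 1874)` internally) is appended to
#' the pseudocopy-masked assembly as an additional contig.
#'
#' @param genome Assembly contigs (`DNAStringSet` or named character).
#' @param mask Pseudocopy mask as for [mask_and_append()].
#' @param unit_18s The 18S sequence to append (character or `DNAString`).
#' @param expected_length Sanity check on the 18S length (default 1874;
#'   set `NULL` to skip, e.g. for toy fixtures).
#' @param extra_contig_name Name of the appended contig.
#' @return A `DNAStringSet` with one additional contig.
#' @export
build_rat_reference <- function(genome, mask, unit_18s,
                                expected_length = 1874L,
                                extra_contig_name = "rDNA_18S") {
  s <- as.character(unit_18s)
  if (!is.null(expected_length) && nchar(s) != expected_length) {
    stop("18S sequence length ", nchar(s), " != expected ", expected_length)
  }
  mask_and_append(genome, mask, s, extra_contig_name = extra_contig_name)
}

#' Extract a subsequence by 1-based inclusive positions
#'
#' Convenience converter for coordinates quoted 1-based inclusive
#' (e.g. "positions 1 to 1874") into the package's 0-based half-open
#' world: `subseq_1based(x, 1, 1874)` equals internal interval `[0, 1874)`.
#'
#' @param x Sequence (character or `DNAString`).
#' @param first,last 1-based inclusive positions.
#' @return Character subsequence.
#' @export
subseq_1based <- function(x, first, last) {
  s <- as.character(x)
  stopifnot(first >= 1, last >= first, last <= nchar(s))
  substring(s, first, last)
}
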