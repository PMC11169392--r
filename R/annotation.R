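#' rDNA unit annotation
#'
#' Describes one 47S rDNA repeat unit in its native coordinate system:
#' total unit length, the transcription start site (TSS), the end of the
#' transcribed (47S pre-rRNA) region, and any named subregions such as the
#' 18S/5.8S/28S rRNAs, the promoter, the upstream control element (UCE) and
#' the core promoter. All coordinates are 0-based half-open.
#'
#' @param unit_length Length of the rDNA unit in bases.
#' @param tss 0-based offset of the transcription start site in the native
#'   unit.
#' @param transcript_end 0-based half-open end of the transcribed region
#'   (the 47S pre-rRNA 3' end) in native coordinates.
#' @param regions Optional `data.frame` with columns `name`, `start`, `end`
#'   giving named subregions as 0-based half-open intervals in native
#'   coordinates.
#' @return An object of class `rdna_annotation`.
#' @examples
#' ann <- rdna_annotation(44000, tss = 10000, transcript_end = 23300,
#'                        regions = data.frame(name = "18S",
#'                                             start = 13000, end = 14874))
#' @export
rdna_annotation <- function(unit_length, tss, transcript_end = NULL,
                            regions = NULL) {
  stopifnot(is.numeric(unit_length), length(unit_length) == 1L,
            unit_length > 0)
  stopifnot(is.numeric(tss), tss >= 0, tss < unit_length)
  if (!is.null(transcript_end)) {
    stopifnot(transcript_end > tss, transcript_end <= unit_length)
  }
  if (is.null(regions)) {
    regions <- data.frame(name = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (nrow(regions)) {
    bad <- regions$start < 0 | regions$end > unit_length |
      regions$start >= regions$end
    if (any(bad)) {
      stop("invalid annotation region(s): ",
           paste(regions$name[bad], collapse = ", "))
    }
  }
  structure(
    list(unit_length = as.integer(unit_length), tss = as.integer(tss),
         transcript_end = if (is.null(transcript_end)) NA_integer_
                          else as.integer(transcript_end),
         regions = regions),
    class = "rdna_annotation")
}

#' @export
print.rdna_annotation <- function(x, ...) {
  cat("rDNA unit annotation:", x$unit_length, "bp; TSS at", x$tss)
  if (!is.na(x$transcript_end))
    cat("; transcribed region ends at", x$transcript_end)
  cat("\n")
  if (nrow(x$regions)) {
    cat("regions:\n")
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

#' Derive the loop breakpoint from the TSS
#'
#' The loop point of the rotated ("looped") rDNA unit is placed a fixed
#' distance upstream of the TSS, inside the intergenic spacer, so that
#' reads spanning the natural unit start/end junction align contiguously.
#' The default offset of 2120 bases corresponds to the midpoint of the
#' IGS repetitive element closest to the 3' end of the human unit.
#'
#' @param annotation An [rdna_annotation()].
#' @param upstream_offset Distance in bases upstream of the TSS at which to
#'   place the breakpoint (default 2120).
#' @return 0-based breakpoint offset in native unit coordinates.
#' @examples
#' ann <- rdna_annotation(44000, tss = 10000)
#' derive_breakpoint(ann)           # 7880
#' derive_breakpoint(rdna_annotation(44000, tss = 1000))  # wraps to 42880
#' @export
derive_breakpoint <- function(annotation, upstream_offset = 2120L) {
  stopifnot(inherits(annotation, "rdna_annotation"))
  if (upstream_offset >= annotation$unit_length) {
    stop("upstream_offset must be smaller than the unit length")
  }
  as.integer((annotation$tss - upstream_offset) %% annotation$unit_length)
}
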