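#' Build the looped (rotated) rDNA unit
#'
#' Rotates the native rDNA unit at a breakpoint inside the intergenic
#' spacer: bases downstream of the breakpoint up to the end of the unit are
#' prepended to the bases upstream of it. Reads spanning the natural unit
#' end/start junction then align contiguously on the looped contig, which
#' avoids coverage loss around the TSS from split alignments.
#'
#' The returned object carries a coordinate map (the rotation is a
#' bijection: looped position of native position `p` is
#' `(p - breakpoint) mod unit_length`) and, when an annotation is
#' supplied, the annotation re-expressed in looped coordinates. A region
#' that straddles the rotation junction is reported as two looped
#' intervals (column `part` distinguishes them).
#'
#' @param unit_sequence Native unit sequence: a single character string or
#'   a [Biostrings::DNAString].
#' @param breakpoint 0-based offset of the loop point in the native unit.
#' @param annotation Optional [rdna_annotation()] to remap.
#' @return An object of class `looped_reference` with elements `sequence`
#'   (character), `unit_length`, `breakpoint`, `tss_looped`,
#'   `transcript_end` (native), and `annotation_looped` (a `data.frame`
#'   of remapped named regions, possibly split).
#' @examples
#' lr <- build_looped_unit("ACGTACGT", 3)
#' lr$sequence  # "TACGTACG"
#' @export
build_looped_unit <- function(unit_sequence, breakpoint, annotation = NULL) {
  seq_chr <- as.character(unit_sequence)
  n <- nchar(seq_chr)
  if (n == 0L) stop("unit sequence is empty")
  if (!is.numeric(breakpoint) || breakpoint < 0 || breakpoint >= n) {
    stop("breakpoint out of range [0, ", n, ")")
  }
  breakpoint <- as.integer(breakpoint)
  looped <- if (breakpoint == 0L) seq_chr else
    paste0(substring(seq_chr, breakpoint + 1L, n),
           substring(seq_chr, 1L, breakpoint))

  ann_looped <- NULL
  tss_looped <- NA_integer_
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "rdna_annotation"))
    if (annotation$unit_length != n) {
      stop("annotation unit_length (", annotation$unit_length,
           ") does not match sequence length (", n, ")")
    }
    tss_looped <- native_to_looped(annotation$tss, breakpoint, n)
    ann_looped <- remap_regions(annotation$regions, breakpoint, n)
  }

  structure(
    list(sequence = looped, unit_length = n, breakpoint = breakpoint,
         tss_looped = tss_looped,
         transcript_end = if (is.null(annotation)) NA_integer_
                          else annotation$transcript_end,
         annotation = annotation,
         annotation_looped = ann_looped),
    class = "looped_reference")
}

#' Map native unit positions to looped positions
#'
#' @param pos 0-based native position(s).
#' @param breakpoint,unit_length Rotation parameters, or pass a
#'   `looped_reference` as `breakpoint`.
#' @return 0-based looped position(s).
#' @export
native_to_looped <- function(pos, breakpoint, unit_length = NULL) {
  if (inherits(breakpoint, "looped_reference")) {
    unit_length <- breakpoint$unit_length
    breakpoint <- breakpoint$breakpoint
  }
  stopifnot(all(pos >= 0), all(pos < unit_length))
  as.integer((pos - breakpoint) %% unit_length)
}

#' Map looped positions back to native unit positions
#'
#' @inheritParams native_to_looped
#' @export
looped_to_native <- function(pos, breakpoint, unit_length = NULL) {
  if (inherits(breakpoint, "looped_reference")) {
    unit_length <- breakpoint$unit_length
    breakpoint <- breakpoint$breakpoint
  }
  stopifnot(all(pos >= 0), all(pos < unit_length))
  as.integer((pos + breakpoint) %% unit_length)
}

# Remap native 0-based half-open regions through the rotation; a region
# crossing the junction becomes two rows sharing `name`, part 1 and 2.
remap_regions <- function(regions, breakpoint, unit_length) {
  if (!nrow(regions)) {
    return(data.frame(name = character(), start = integer(),
                      end = integer(), part = integer()))
  }
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ls <- (regions$start[i] - breakpoint) %% unit_length
    width <- regions$end[i] - regions$start[i]
    le <- ls + width
    if (le <= unit_length) {
      out[[i]] <- data.frame(name = regions$name[i], start = as.integer(ls),
                             end = as.integer(le), part = 1L)
    } else {
      out[[i]] <- data.frame(
        name = regions$name[i],
        start = c(as.integer(ls), 0L),
        end = c(as.integer(unit_length), as.integer(le - unit_length)),
        part = c(1L, 2L))
    }
  }
  do.call(rbind, out)
}

#' Intervals of a looped region by name
#'
#' @param looped A `looped_reference`.
#' @param name Region name as annotated (e.g. `"18S"`, `"UCE"`).
#' @return `data.frame` with `start`, `end` (0-based half-open, looped
#'   coordinates); two rows if the region is split by the rotation.
#' @export
looped_region <- function(looped, name) {
  stopifnot(inherits(looped, "looped_reference"))
  ann <- looped$annotation_looped
  if (is.null(ann) || !name %in% ann$name) {
    stop("no annotated region named '", name, "'")
  }
  ann[ann$name == name, c("start", "end"), drop = FALSE]
}

#' @export
print.looped_reference <- function(x, ...) {
  cat("looped rDNA reference: ", x$unit_length, " bp, breakpoint at native ",
      x$breakpoint, "\n", sep = "")
  if (!is.na(x$tss_looped)) cat("TSS at looped position", x$tss_looped, "\n")
  if (!is.null(x$annotation_looped) && nrow(x$annotation_looped)) {
    cat("remapped regions:\n")
    print(x$annotation_looped, row.names = FALSE)
  }
  invisible(x)
}

#' Write a looped reference and its coordinate-map sidecar
#'
#' Writes the looped sequence as FASTA (60-column wrap) and a JSON sidecar
#' holding the rotation parameters and the remapped annotation, enough to
#' reconstruct the native<->looped coordinate bijection.
#'
#' @param looped A `looped_reference`.
#' @param fasta_path,json_path Output paths.
#' @param contig_name Name for the FASTA record.
#' @return Invisibly, the two paths.
#' @export
write_looped_reference <- function(looped, fasta_path, json_path,
                                   contig_name = "rDNA_looped") {
  stopifnot(inherits(looped, "looped_reference"))
  dss <- Biostrings::DNAStringSet(looped$sequence)
  names(dss) <- contig_name
  Biostrings::writeXStringSet(dss, fasta_path, width = 60L)
  side <- list(contig = contig_name,
               unit_length = looped$unit_length,
               breakpoint = looped$breakpoint,
               coord_map = "looped = (native - breakpoint) mod unit_length",
               tss_looped = looped$tss_looped,
               annotation_looped = looped$annotation_looped)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(fasta = fasta_path, json = json_path))
}
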