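#' Exome filtering policy
#'
#' Rules for deriving a single-copy exome reference used as the
#' normalisation denominator in depth-based copy-number estimation:
#' exons from excluded contigs (sex chromosomes by default, whose dosage
#' differs between sexes) and exons shorter than `min_length` are removed,
#' and of any pair of retained sequences with high mutual similarity one
#' member is dropped so that no read can multi-map within the reference.
#' Similarity is measured as the Jaccard index of shared k-mer sets.
#'
#' @param min_length Minimum exon length in bases (default 300).
#' @param excluded_contigs Contigs whose exons are removed (default
#'   `c("chrX", "chrY", "X", "Y")`).
#' @param similarity_k k-mer size for the similarity screen (default 31).
#' @param similarity_threshold Maximum shared-k-mer Jaccard allowed
#'   between any retained pair (default 0.5).
#' @return An object of class `exome_filter_policy`.
#' @export
exome_filter_policy <- function(min_length = 300L,
                                excluded_contigs = c("chrX", "chrY",
                                                     "X", "Y"),
                                similarity_k = 31L,
                                similarity_threshold = 0.5) {
  stopifnot(min_length > 0, similarity_k > 0,
            similarity_threshold > 0, similarity_threshold <= 1)
  structure(list(min_length = as.integer(min_length),
                 excluded_contigs = excluded_contigs,
                 similarity_k = as.integer(similarity_k),
                 similarity_threshold = similarity_threshold),
            class = "exome_filter_policy")
}

# Set of distinct k-mers of a sequence (character scalar).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# Jaccard index of two k-mer sets.
kmer_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Filter an exome reference to single-copy sequences
#'
#' Applies an [exome_filter_policy()]: contig exclusion, minimum length,
#' then an iterative pairwise similarity screen. While any retained pair
#' exceeds the Jaccard threshold, the most similar offending pair is
#' resolved by dropping its shorter member (ties broken by dropping the
#' lexicographically later identifier). Every removal is logged with its
#' reason and, for similarity removals, the retained partner.
#'
#' @param exons A [Biostrings::DNAStringSet] with unique names, or a named
#'   character vector of sequences.
#' @param contig Character vector, one source contig per exon (recycled
#'   `NA` if unknown; then contig exclusion never fires).
#' @param policy An [exome_filter_policy()].
#' @return A list with `retained` (`DNAStringSet`) and `removed`
#'   (`data.frame` with `id`, `reason`, `partner`, `jaccard`).
#' @export
filter_exome <- function(exons, contig = NULL,
                         policy = exome_filter_policy()) {
  exons <- Biostrings::DNAStringSet(exons)
  ids <- names(exons)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("exon records must have unique identifiers")
  }
  if (is.null(contig)) contig <- rep(NA_character_, length(exons))
  stopifnot(length(contig) == length(exons))

  log <- data.frame(id = character(), reason = character(),
                    partner = character(), jaccard = numeric(),
                    stringsAsFactors = FALSE)
  drop_contig <- !is.na(contig) & contig %in% policy$excluded_contigs
  if (any(drop_contig)) {
    log <- rbind(log, data.frame(id = ids[drop_contig],
                                 reason = "excluded_contig",
                                 partner = NA_character_,
                                 jaccard = NA_real_))
  }
  too_short <- Biostrings::width(exons) < policy$min_length
  drop_short <- too_short & !drop_contig
  if (any(drop_short)) {
    log <- rbind(log, data.frame(id = ids[drop_short],
                                 reason = "too_short",
                                 partner = NA_character_,
                                 jaccard = NA_real_))
  }
  keep <- !(drop_contig | drop_short)
  retained <- exons[keep]

  if (length(retained) >= 2L) {
    seqs <- as.character(retained)
    ksets <- lapply(seqs, kmer_set, k = policy$similarity_k)
    names(ksets) <- names(retained)
    repeat {
      nms <- names(ksets)
      if (length(nms) < 2L) break
      pairs <- utils::combn(nms, 2L)
      jac <- apply(pairs, 2L, function(p)
        kmer_jaccard(ksets[[p[1]]], ksets[[p[2]]]))
      offending <- which(jac > policy$similarity_threshold)
      if (!length(offending)) break
      worst <- offending[which.max(jac[offending])]
      a <- pairs[1L, worst]; b <- pairs[2L, worst]
      wa <- Biostrings::width(retained[a])
      wb <- Biostrings::width(retained[b])
      victim <- if (wa < wb) a else if (wb < wa) b else max(a, b)
      partner <- if (victim == a) b else a
      log <- rbind(log, data.frame(id = victim, reason = "similarity",
                                   partner = partner,
                                   jaccard = jac[worst]))
      ksets[[victim]] <- NULL
      retained <- retained[names(retained) != victim]
    }
  }
  rownames(log) <- NULL
  list(retained = retained, removed = log)
}
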