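test_that("looped unit rotation matches its definition", {
  expect_equal(build_looped_unit("ACGTACGT", 0)$sequence, "ACGTACGT")
  expect_equal(build_looped_unit("ACGTACGT", 3)$sequence, "TACGTACG")
  expect_error(build_looped_unit("ACGT", 4), "out of range")
  expect_error(build_looped_unit("", 0), "empty")
})

test_that("breakpoint derivation places the TSS 2120 bases into the loop", {
  ann <- rdna_annotation(44000, tss = 10000)
  expect_identical(derive_breakpoint(ann, 2120), 7880L)
  # modular wrap when the TSS is closer than the offset to the unit start
  ann2 <- rdna_annotation(44000, tss = 1000)
  expect_identical(derive_breakpoint(ann2, 2120), 42880L)
  expect_identical(derive_breakpoint(ann, 0L), 10000L)
  expect_error(derive_breakpoint(ann, 44000), "smaller than the unit")

  # with the derived breakpoint, the looped TSS sits exactly at the
  # upstream offset
  seqs <- random_dna(44000)
  lr <- build_looped_unit(seqs, derive_breakpoint(ann, 2120), ann)
  expect_identical(lr$tss_looped, 2120L)
})

test_that("coordinate map is a bijection and rotation round-trips", {
  n <- 997L
  lr <- build_looped_unit(random_dna(n), 356L)
  pos <- 0:(n - 1L)
  lp <- native_to_looped(pos, lr)
  expect_identical(sort(lp), pos)                 # bijection onto [0, n)
  expect_identical(looped_to_native(lp, lr), pos) # round-trip identity
})

test_that("inverse rotation reproduces the native sequence", {
  s <- random_dna(512)
  lr <- build_looped_unit(s, 100L)
  expect_identical(build_looped_unit(lr$sequence, 512L - 100L)$sequence, s)
})

test_that("regions are remapped, splitting at the loop junction", {
  ann <- rdna_annotation(
    1000, tss = 500,
    regions = data.frame(name = c("inside", "upstream"),
                         start = c(600, 10), end = c(700, 90)))
  lr <- build_looped_unit(random_dna(1000), 100L, ann)
  inside <- lr$annotation_looped[lr$annotation_looped$name == "inside", ]
  expect_equal(inside$start, 500)
  expect_equal(inside$end, 600)
  # a region upstream of the breakpoint wraps to the end of the loop
  up <- lr$annotation_looped[lr$annotation_looped$name == "upstream", ]
  expect_equal(up$start, 910)
  expect_equal(up$end, 990)
  # region crossing the junction itself becomes two intervals
  ann2 <- rdna_annotation(
    1000, tss = 500,
    regions = data.frame(name = "cross", start = 80, end = 180))
  lr2 <- build_looped_unit(random_dna(1000), 100L, ann2)
  cross <- lr2$annotation_looped
  expect_equal(nrow(cross), 2L)
  expect_equal(cross$start, c(980, 0))
  expect_equal(cross$end, c(1000, 80))
  expect_equal(sum(cross$end - cross$start), 100)
})

test_that("a read spanning the native unit junction is contiguous on the looped contig", {
  unit <- random_dna(3000)
  ann <- rdna_annotation(3000, tss = 2900)  # TSS near the unit 3' end
  bp <- derive_breakpoint(ann, 500L)        # breakpoint in the spacer
  lr <- build_looped_unit(unit, bp, ann)
  # read spanning end -> start of the native unit
  junction_read <- paste0(substring(unit, 2971, 3000),
                          substring(unit, 1, 30))
  # toy exact-match placement: the 60-mer occurs as a single contiguous
  # interval on the looped contig, and not at all in the native unit
  expect_identical(
    length(gregexpr(junction_read, lr$sequence, fixed = TRUE)[[1]]) == 1L &&
      gregexpr(junction_read, lr$sequence, fixed = TRUE)[[1]][1] != -1L,
    TRUE)
  expect_identical(gregexpr(junction_read, unit, fixed = TRUE)[[1]][1],
                   -1L)
})

test_that("masking hard-masks intervals without changing lengths", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(400),
                                  chr2 = random_dna(200)))
  lr <- build_looped_unit(random_dna(300), 50L)

  # empty mask: genome unchanged except the appended contig
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer())
  out <- mask_and_append(g, empty, lr)
  expect_identical(length(out), 3L)
  expect_identical(as.character(out[["chr1"]]), as.character(g[["chr1"]]))
  expect_identical(as.character(out[["rDNA_looped"]]), lr$sequence)

  # full mask of chr2
  out2 <- mask_and_append(
    g, data.frame(contig = "chr2", start = 0, end = 200), lr)
  expect_identical(as.character(out2[["chr2"]]), strrep("N", 200))
  expect_identical(length(out2[["chr2"]]), 200L)
  expect_identical(as.character(out2[["chr1"]]), as.character(g[["chr1"]]))

  expect_error(mask_and_append(
    g, data.frame(contig = "chr9", start = 0, end = 10), lr), "unknown")
  names(g)[1] <- "rDNA_looped"
  expect_error(mask_and_append(g, empty, lr), "collision")
})

test_that("planted pseudocopy is silenced: rDNA k-mers unique to the appended contig", {
  set.seed(31)
  unit <- random_dna(1200)
  ann <- rdna_annotation(1200, tss = 600,
                         regions = data.frame(name = "18S",
                                              start = 650, end = 950))
  lr <- build_looped_unit(unit, derive_breakpoint(ann, 200L), ann)
  # plant the 18S fragment inside a genome contig (a pseudocopy)
  frag <- substring(unit, 651, 950)
  g <- Biostrings::DNAStringSet(c(
    chr1 = paste0(random_dna(500), frag, random_dna(500)),
    chr2 = random_dna(800)))
  masked <- mask_and_append(
    g, data.frame(contig = "chr1", start = 500, end = 800), lr)

  # brute-force k-mer scan oracle over every contig
  k <- 31L
  kmers_18s <- unique(substring(frag, 1:(nchar(frag) - k + 1L),
                                k:nchar(frag)))
  hits <- vapply(names(masked), function(nm) {
    s <- as.character(masked[[nm]])
    any(vapply(kmers_18s, function(km)
      grepl(km, s, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_identical(unname(hits[c("chr1", "chr2")]), c(FALSE, FALSE))
  expect_true(hits[["rDNA_looped"]])
})

test_that("rat reference appends the bare 18S subsequence", {
  unit <- random_dna(2500)
  s18 <- subseq_1based(unit, 1, 1874)  # 1-based inclusive quoting
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(300)))
  out <- build_rat_reference(g, NULL, s18)
  expect_identical(length(out), 2L)
  expect_identical(length(out[["rDNA_18S"]]), 1874L)
  expect_identical(as.character(out[["rDNA_18S"]]), s18)
  expect_error(build_rat_reference(g, NULL, substring(unit, 1, 100)),
               "expected 1874")
})

test_that("looped reference round-trips through its FASTA/JSON sidecar", {
  ann <- rdna_annotation(600, tss = 300,
                         regions = data.frame(name = "18S", start = 310,
                                              end = 500))
  lr <- build_looped_unit(random_dna(600), 120L, ann)
  fa <- tempfile(fileext = ".fa"); js <- tempfile(fileext = ".json")
  write_looped_reference(lr, fa, js)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[[1]]), lr$sequence)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(side$breakpoint, lr$breakpoint)
  expect_equal(side$annotation_looped$start,
               lr$annotation_looped$start)
})
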