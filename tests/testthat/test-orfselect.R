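test_that("frame translation follows the standard code with X for ambiguity", {
  expect_equal(translateFrame("ATGAAA"), "MK")
  expect_equal(translateFrame("ATGAAATAA"), "MK*")
  expect_equal(translateFrame("ATGNNN"), "MX")
  expect_equal(translateFrame("AATGAAA", 2), "MK")
  # minus strand = translate the reverse complement
  expect_equal(translateFrame("TTTCAT", 1, "-"), "MK")
  expect_equal(translateFrame("AC"), "")
  expect_error(translateFrame("ATGRAA"), "ACGTN")
  expect_error(translateFrame("ATGAAA", 4), "frame")
})

test_that("candidate enumeration recovers hand-checked ORFs", {
  o <- findOrfs("ATGAAATAA", minAa = 1)
  expect_equal(nrow(o[o$strand == "+" & o$met_initiated, ]), 1L)
  mk <- o[o$met_initiated & o$strand == "+", ]
  expect_equal(mk$peptide, "MK")
  expect_equal(c(mk$cds_start, mk$cds_end), c(1L, 9L))
  expect_true(mk$has_stop)

  # Met ORF on the minus strand with forward-strand coordinates
  m <- findOrfs("TTACATGGGCAT", minAa = 1)
  mm <- m[m$met_initiated & m$strand == "-" & m$peptide == "MPM", ]
  expect_equal(nrow(mm), 1L)
  expect_equal(c(mm$cds_start, mm$cds_end), c(1L, 12L))

  # a segment without Met yields only the 5'-partial candidate
  p <- findOrfs("AAAAAAAAA", minAa = 1)
  expect_false(any(p$met_initiated))
  expect_true(all(!p$has_stop))
  expect_error(findOrfs("AT"), "at least 3")
})

test_that("enumeration agrees with the brute-force oracle on random sequences", {
  set.seed(80)
  for (i in 1:400) {
    L <- sample(3:60, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    got <- findOrfs(s, minAa = 1)
    got$orf_key <- sub("^seq1:", "", got$orf_key)
    got <- got[order(got$orf_key, got$met_initiated),
               c("orf_key", "peptide", "met_initiated")]
    rownames(got) <- NULL
    want <- bruteOrfs(s, minAa = 1)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("merging dedupes identical coordinates and unions sources", {
  int <- findOrfs("ATGAAATAA", minAa = 1)
  ext <- int[int$met_initiated & int$strand == "+", , drop = FALSE]
  ext$source <- "external"
  m <- mergeCandidates(int, ext)
  expect_equal(nrow(m), nrow(int))
  merged <- m[m$met_initiated & m$strand == "+", ]
  expect_equal(merged$source, "external,internal")
  expect_error(
    mergeCandidates(int, contigLengths = c(ctg = 5L)), "out of contig bounds")
})

test_that("selection prefers the longest Met unless a hit overrides", {
  cand <- function(key, len, met, start = 1L)
    data.frame(contig_id = "c", orf_key = key, strand = "+", frame = 1L,
               cds_start = start, cds_end = start + 3L * len - 1L,
               peptide = strrep("A", len), length_aa = len,
               met_initiated = met, has_stop = TRUE, source = "internal",
               stringsAsFactors = FALSE)
  cands <- rbind(cand("c:+:1-903", 301L, TRUE),
                 cand("c:+:2-362", 120L, TRUE, 2L),
                 cand("c:+:3-183", 60L, FALSE, 3L))
  # no hits: longest Met wins and passes the length keep rule
  r <- selectRepresentative(cands)
  expect_equal(r$orf_key, "c:+:1-903")
  expect_equal(r$selection_reason, "LONGEST_MET")
  expect_true(r$kept)
  expect_equal(r$keep_reason, "LENGTH_GT_100")

  # a significant hit on the shorter candidate overrides length
  hits <- data.frame(orf_key = "c:+:2-362", sseqid = "sp1",
                     bitscore = 250, evalue = 1e-30)
  r2 <- selectRepresentative(cands, hits)
  expect_equal(r2$orf_key, "c:+:2-362")
  expect_equal(r2$selection_reason, "HIT_SCORE")
  expect_equal(r2$keep_reason, "HIT_E_LT_1e10")
  expect_equal(r2$hit_subject, "sp1")

  # a non-significant hit does not override
  weak <- data.frame(orf_key = "c:+:2-362", sseqid = "sp1",
                     bitscore = 40, evalue = 1e-3)
  expect_equal(selectRepresentative(cands, weak)$orf_key, "c:+:1-903")

  # short winner without a hit is not kept
  shortOnly <- cand("c:+:1-150", 50L, TRUE)
  r3 <- selectRepresentative(shortOnly)
  expect_false(r3$kept)
  expect_equal(r3$keep_reason, "NOT_KEPT")

  # exactly 100 aa fails the strict > rule
  r4 <- selectRepresentative(cand("c:+:1-300", 100L, TRUE))
  expect_false(r4$kept)

  # no Met anywhere: longest candidate overall
  noMet <- rbind(cand("c:+:1-150", 50L, FALSE),
                 cand("c:+:2-241", 80L, FALSE, 2L))
  expect_equal(selectRepresentative(noMet)$orf_key, "c:+:2-241")
})

test_that("planted CDS regions are recovered as the representatives", {
  po <- plantOrfs(60, peptideLengths = c(110, 250), seed = 81)
  tr <- truthRecords(po$manifest)
  cands <- findOrfs(po$contigs, minAa = 30)
  reps <- selectRepresentatives(cands)
  m <- match(tr$contig_id, reps$contig_id)
  expect_false(anyNA(m))
  expect_equal(reps$cds_start[m], tr$cds_start)
  expect_equal(reps$cds_end[m], tr$cds_end)
  expect_equal(reps$strand[m], tr$strand)
  expect_identical(reps$peptide[m], tr$peptide)
  expect_true(all(reps$kept[m]))
})

test_that("peptide FASTA and CDS GFF3 outputs are consistent", {
  po <- plantOrfs(10, peptideLengths = c(110, 200), seed = 82)
  reps <- selectRepresentatives(findOrfs(po$contigs, minAa = 30))
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  gr <- writeOrfOutputs(reps, fa, gff)
  pep <- Biostrings::readAAStringSet(fa)
  expect_equal(length(pep), sum(reps$kept))
  expect_true(all(grepl("\\.p1$", names(pep))))
  back <- rtracklayer::import(gff)
  expect_equal(length(back), length(gr))
  expect_equal(as.character(back$type), rep("CDS", length(back)))
  expect_equal(IRanges::start(back), reps$cds_start[reps$kept])
  expect_equal(IRanges::end(back), reps$cds_end[reps$kept])
  expect_identical(back$ID, names(pep))
  # CDS interval length is a codon multiple
  expect_true(all((IRanges::end(back) - IRanges::start(back) + 1L) %% 3 == 0))
})
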