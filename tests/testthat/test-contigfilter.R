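test_that("the word-seeded scan finds planted adapter fragments exactly", {
  ad <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  ctg <- paste0(strrep("ACGT", 30), ad, strrep("TTGCA", 20))
  sp <- scanAdapters(ctg, ad)
  expect_equal(IRanges::start(sp), 121L)
  expect_equal(IRanges::end(sp), 153L)

  # a clean repeat sequence yields no spans at e <= 0.01
  expect_length(scanAdapters(strrep("ACGT", 100), ad), 0L)

  # planted fragments are recovered across a generated batch
  pa <- plantAdapters(makeContigs(40, c(500, 2000), seed = 60)$contigs,
                      ad, rate = 1, seed = 61)
  tr <- truthRecords(pa$manifest)
  for (i in seq_len(nrow(tr))) {
    sp <- scanAdapters(pa$contigs[[tr$contig_id[i]]], ad)
    hit <- any(IRanges::start(sp) <= tr$start[i] &
                 IRanges::end(sp) >= tr$end[i] - 1L)
    expect_true(hit)
  }
  expect_error(scanAdapters(ctg, ad, wordSize = 1), "at least 2")
})

test_that("clipping keeps the longest complementary segment", {
  s <- strrep("A", 500)
  # span covering 101..120 leaves 100 + 380; the 380-nt tail wins
  cc <- clipContig(s, IRanges::IRanges(101, 120))
  expect_true(cc$kept)
  expect_equal(cc$new_length, 380L)
  expect_equal(cc$segment, c(121L, 500L))
  expect_equal(cc$bases_removed, 120L)
  # all segments under minLen: contig removed
  short <- clipContig(strrep("A", 300), IRanges::IRanges(140, 160),
                      minLen = 200)
  expect_false(short$kept)
  expect_equal(short$new_length, 0L)
  # exactly minLen survives
  edge <- clipContig(strrep("A", 300), IRanges::IRanges(201, 300),
                     minLen = 200)
  expect_true(edge$kept)
  expect_equal(edge$new_length, 200L)
  # leftmost wins on a length tie
  tie <- clipContig(strrep("A", 401), IRanges::IRanges(201, 201), minLen = 1)
  expect_equal(tie$segment, c(1L, 200L))
  expect_equal(clipContig(s, IRanges::IRanges())$new_length, 500L)
  expect_error(clipContig(s, IRanges::IRanges(400, 600)), "bounds")
})

test_that("triage applies the reference gate then the best-nt-hit rule", {
  ref <- rbind(hitRow("c1", "chr1", 500, ev = 1e-20, pid = 95, len = 300),
               # fails each gate in turn
               hitRow("c2", "chr1", 500, ev = 1e-3, pid = 95, len = 300),
               hitRow("c3", "chr1", 500, ev = 1e-20, pid = 95, len = 100),
               hitRow("c4", "chr1", 500, ev = 1e-20, pid = 80, len = 300))
  nt <- rbind(hitRow("c2", "bact1", 400),
              hitRow("c2", "plant1", 300),
              hitRow("c3", "plant1", 400),
              hitRow("c3", "bact1", 300),
              # c5: bitscore tie broken by lower e-value
              hitRow("c5", "bact1", 200, ev = 1e-8),
              hitRow("c5", "plant1", 200, ev = 1e-20))
  tax <- c(bact1 = "Bacteria", plant1 = "Viridiplantae")
  res <- classifyContamination(paste0("c", 1:6), ref, nt, tax)
  lab <- stats::setNames(res$label, res$contig_id)
  expect_equal(unname(lab["c1"]), "PLANT_REFERENCE")
  expect_equal(unname(lab["c2"]), "BACTERIAL_REMOVED")
  expect_equal(unname(lab["c3"]), "NONBACTERIAL_KEPT")
  expect_equal(unname(lab["c4"]), "NO_HIT_KEPT")  # fails ref gate, no nt hit
  expect_equal(unname(lab["c5"]), "NONBACTERIAL_KEPT")
  expect_equal(unname(lab["c6"]), "NO_HIT_KEPT")
  # boundary: e-value exactly at threshold fails the strict < gate
  refEdge <- hitRow("c9", "chr1", 500, ev = 1e-5, pid = 95, len = 300)
  expect_equal(classifyContamination("c9", refEdge, NULL, tax)$label,
               "NO_HIT_KEPT")
  expect_error(classifyContamination("c2", NULL, nt, c(bact1 = "Bacteria")),
               "absent from taxonomy")
})

test_that("the length filter keeps contigs at exactly the cutoff", {
  ctg <- Biostrings::DNAStringSet(stats::setNames(
    c(strrep("A", 399), strrep("A", 400), strrep("A", 401)),
    c("a", "b", "c")))
  lf <- lengthFilter(ctg, 400)
  expect_equal(names(lf$contigs), c("b", "c"))
  expect_equal(lf$removed, "a")
  expect_equal(lf$n_removed, 1L)
})

test_that("runCleanup reconciles counts and reproduces fixture truth", {
  fx <- makeCleanupFixture(nContigs = 120, seed = 70)
  cl <- runCleanup(fx$contigs, adapters = fx$adapters, refHits = fx$refHits,
                   ntHits = fx$ntHits, taxonomy = fx$taxonomy)
  st <- stageCounts(cl$report)
  expect_equal(st$n_out, st$n_in - st$n_removed)
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
  expect_equal(st$n_out[nrow(st)], length(cl$contigs))

  tr <- truthRecords(fx$manifest)
  surv <- stats::setNames(tr$expected_fate, tr$contig_id)
  expect_identical(sort(names(cl$contigs)),
                   sort(tr$contig_id[tr$expected_fate == "KEPT"]))
  rm <- removalReasons(cl$report)
  got <- stats::setNames(rm$reason, rm$contig_id)
  lost <- tr[tr$expected_fate != "KEPT", ]
  expect_identical(unname(got[lost$contig_id]), lost$expected_fate)
  # surviving lengths match the arithmetic expectation
  kept <- tr[tr$expected_fate == "KEPT", ]
  expect_equal(
    unname(Biostrings::width(cl$contigs)[match(kept$contig_id,
                                               names(cl$contigs))]),
    kept$expected_length)
  expect_error(runCleanup(Biostrings::DNAStringSet(
    stats::setNames(c("ACGT", "ACGT"), c("x", "x")))), "unique")
})
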