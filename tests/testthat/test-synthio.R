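test_that("contig generation is seed-deterministic and honours its contract", {
  a <- makeContigs(100, c(300, 3000), gc = 0.4, seed = 42)
  b <- makeContigs(100, c(300, 3000), gc = 0.4, seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(a$contigs, f1)
  Biostrings::writeXStringSet(b$contigs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(Biostrings::width(a$contigs) >= 300 &
                    Biostrings::width(a$contigs) <= 3000))

  one <- makeContigs(1, c(500, 500), seed = 1)
  expect_length(one$contigs, 1L)
  expect_equal(Biostrings::width(one$contigs), 500L)

  big <- makeContigs(1000, c(500, 500), gc = 0.4, seed = 3)
  bases <- table(strsplit(paste(as.character(big$contigs), collapse = ""),
                          "")[[1]])
  gcObs <- sum(bases[c("G", "C")]) / sum(bases)
  expect_lt(abs(gcObs - 0.4), 0.02)

  expect_error(makeContigs(0, c(100, 200)), "n must be")
  expect_error(makeContigs(5, c(200, 100)), "length range")
})

test_that("adapter planting records every span and round-trips through the scanner", {
  ad <- as.character(illuminaAdapters()[[1]])
  ctg <- makeContigs(50, c(400, 2000), seed = 10)$contigs

  none <- plantAdapters(ctg, ad, rate = 0, seed = 2)
  expect_identical(as.character(none$contigs), as.character(ctg))
  expect_equal(nrow(truthRecords(none$manifest)), 0L)

  all10 <- plantAdapters(ctg[1:10], ad, rate = 1, seed = 2)
  expect_equal(nrow(truthRecords(all10$manifest)), 10L)

  pa <- plantAdapters(ctg, ad, rate = 0.5, seed = 4)
  tr <- truthRecords(pa$manifest)
  expect_equal(nrow(tr), 25L)
  # planted fragment is really there and >= 75% of the adapter
  for (i in seq_len(nrow(tr))) {
    w <- tr$end[i] - tr$start[i] + 1L
    expect_gte(w, ceiling(0.75 * nchar(ad)))
    frag <- substr(as.character(pa$contigs[[tr$contig_id[i]]]),
                   tr$start[i], tr$end[i])
    expect_identical(frag, substr(ad, 1, w))
  }
  expect_error(plantAdapters(ctg, substr(ad, 1, 8), rate = 1),
               "at least 10")
  expect_error(plantAdapters(makeContigs(3, c(20, 20), seed = 1)$contigs,
                             ad, rate = 1), "longer than")
})

test_that("contamination planting yields exact class counts and consistent evidence", {
  ctg <- makeContigs(100, c(400, 1500), seed = 20)$contigs
  pc <- plantContaminants(ctg, bacterialFraction = 0.2,
                          noHitFraction = 0.1,
                          nonbacterialFraction = 0.05, seed = 21)
  tr <- truthRecords(pc$manifest)
  expect_equal(sum(tr$label == "BACTERIAL_REMOVED"), 20L)
  expect_equal(sum(tr$label == "NO_HIT_KEPT"), 10L)
  expect_equal(sum(tr$label == "NONBACTERIAL_KEPT"), 5L)
  # taxonomy covers every nt subject
  expect_true(all(unique(pc$ntHits$sseqid) %in% names(pc$taxonomy)))
  # no-hit contigs are absent from both tables
  nohit <- tr$contig_id[tr$label == "NO_HIT_KEPT"]
  expect_false(any(nohit %in% c(pc$refHits$qseqid, pc$ntHits$qseqid)))

  clean <- plantContaminants(ctg, bacterialFraction = 0, seed = 22)
  bestSubj <- clean$ntHits$sseqid
  expect_false(any(clean$taxonomy[bestSubj] == "Bacteria"))
})

test_that("planted ORFs are the unique longest Met ORF by construction", {
  po <- plantOrfs(60, peptideLengths = c(40, 120), strandMix = 0.5,
                  seed = 30)
  tr <- truthRecords(po$manifest)
  expect_equal(nrow(tr), 60L)
  expect_gt(sum(tr$strand == "-"), 10L)
  expect_gt(sum(tr$strand == "+"), 10L)
  for (i in seq_len(10)) {
    chk <- txpolish:::.naiveLongestMetOrf(as.character(po$contigs[[i]]))
    expect_equal(chk$count, 1L)
    expect_equal(c(chk$start, chk$end), c(tr$cds_start[i], tr$cds_end[i]))
    expect_equal(chk$length, nchar(tr$peptide[i]))
  }
  rerun <- plantOrfs(60, peptideLengths = c(40, 120), strandMix = 0.5,
                     seed = 30)
  expect_identical(as.character(rerun$contigs), as.character(po$contigs))
  expect_error(plantOrfs(5, peptideLengths = c(5, 20)), "10 aa")
})

test_that("designed count matrices carry their true Venn partition", {
  tissues <- c("root", "stem")
  mx <- makeCountMatrix(tissues, 20, c(root = 5, stem = 2), seed = 40)
  rc <- regionCounts(mx$partition)
  expect_equal(unname(rc["root"]), 5L)
  expect_equal(unname(rc["stem"]), 2L)
  expect_equal(unname(rc["root+stem"]), 13L)
  expect_identical(regionCounts(vennPartition(mx$counts)), rc)

  withZero <- makeCountMatrix(tissues, 20, c(root = 5), nAbsent = 3,
                              seed = 41)
  vp <- vennPartition(withZero$counts)
  expect_equal(absentCount(vp), 3L)
  expect_equal(sum(regionCounts(vp)), 17L)
  expect_error(makeCountMatrix(tissues, 5, c(root = 4, stem = 3)),
               "exceeds")
})

test_that("read-pair fixtures record valid trim truth and stay synchronized", {
  cst <- makeReadPairs(50, readLen = 80, qualityProfile = "constant",
                       qHigh = 40, seed = 50)
  expect_true(all(cst$truth$trim1 == 80L & cst$truth$trim2 == 80L))

  stp <- makeReadPairs(100, readLen = 80, qualityProfile = "step", seed = 51)
  expect_equal(length(stp$r1), length(stp$r2))
  expect_identical(names(stp$r1), names(stp$r2))
  # truth equals an in-test window scan on the decoded qualities
  q1 <- as(Biostrings::quality(stp$r1), "IntegerList")
  naive <- function(q) {
    for (i in seq_along(q)) if (mean(q[i:min(i + 3, length(q))]) < 15)
      return(i - 1L)
    length(q)
  }
  expect_identical(unname(vapply(q1, naive, integer(1L))),
                   as.integer(stp$truth$trim1))
  expect_error(makeReadPairs(10, readLen = 10), "at least 20")
})
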