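test_that("the sliding-window rule truncates at the first failing window", {
  expect_equal(trimPoint(rep(40, 30)), 30L)
  # window at index 5 (1-based) has mean 10 < 15; index 4 has mean 15, kept
  expect_equal(trimPoint(c(30, 30, 30, 30, 10, 10, 10, 10)), 4L)
  expect_equal(trimPoint(integer(0)), 0L)
  # read shorter than the window is one window of its own length
  expect_equal(trimPoint(c(20, 20)), 2L)
  expect_equal(trimPoint(c(10, 10)), 0L)
  # trailing sub-window is evaluated: a terminal Q2 base fails alone
  expect_equal(trimPoint(c(40, 40, 40, 40, 2)), 4L)
})

test_that("set-level trimming matches the per-read rule and only shortens", {
  rp <- makeReadPairs(200, readLen = 60, qualityProfile = "step", seed = 7)
  tr <- slidingWindowTrim(rp$r1)
  expect_identical(as.integer(Biostrings::width(tr)),
                   as.integer(rp$truth$trim1))
  # outputs are prefixes of inputs
  full <- as.character(Biostrings::DNAStringSet(rp$r1))
  cut <- as.character(Biostrings::DNAStringSet(tr))
  expect_identical(cut, substr(full, 1, nchar(cut)))
  expect_true(all(Biostrings::width(tr) <= Biostrings::width(rp$r1)))
})

test_that("adapter clipping needs a seeded, sufficiently scoring alignment", {
  ad <- as.character(illuminaAdapters()[[1]])
  full <- mkQualRead(paste0(strrep("ACGT", 20), ad), rep(40, 113))
  expect_equal(Biostrings::width(clipAdapter(full, ad)), 80L)
  # 10 exact terminal bases: score 6.0 < 10 and no 16-mer seed
  frag <- mkQualRead(paste0(strrep("ACGT", 20), substr(ad, 1, 10)),
                     rep(40, 90))
  expect_equal(Biostrings::width(clipAdapter(frag, ad)), 90L)
  # no 16-mer seed match anywhere
  clean <- mkQualRead(strrep("ACGT", 25), rep(40, 100))
  expect_equal(Biostrings::width(clipAdapter(clean, ad)), 100L)
  # a seed with 2 mismatches still clips when the score clears the bar
  noisy <- ad
  substr(noisy, 3, 3) <- "T"; substr(noisy, 9, 9) <- "C"
  r <- mkQualRead(paste0(strrep("ACGT", 20), noisy), rep(40, 113))
  expect_equal(Biostrings::width(clipAdapter(r, ad)), 80L)
  expect_error(clipAdapter(full, ""), "non-empty")
})

test_that("orphaned mates are dropped with the pair", {
  mk2 <- function(w1, w2) {
    list(r1 = mkQualReads(strrep("A", w1), list(rep(40, w1)), "p"),
         r2 = mkQualReads(strrep("A", w2), list(rep(40, w2)), "p"))
  }
  keep <- mk2(150, 150)
  expect_equal(filterPairs(keep$r1, keep$r2, 100)$stats$pairs_kept, 1L)
  orphan <- mk2(150, 90)
  st <- filterPairs(orphan$r1, orphan$r2, 100)$stats
  expect_equal(st$pairs_kept, 0L)
  expect_equal(st$pairs_dropped, 1L)
  both <- mk2(90, 90)
  expect_equal(filterPairs(both$r1, both$r2, 100)$stats$pairs_kept, 0L)
})

test_that("mate desynchronization and Phred+64 input are format errors", {
  r1 <- mkQualReads(c("ACGT", "ACGT"), list(rep(40, 4), rep(40, 4)),
                    c("a", "b"))
  r2 <- mkQualReads(c("ACGT", "ACGT"), list(rep(40, 4), rep(40, 4)),
                    c("a", "c"))
  expect_error(filterPairs(r1, r2), "out of sync")
  expect_error(filterPairs(r1, r2[1]), "out of sync")

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGT", "+", "hhhh"), f1)   # 'h' = Q71 under +33
  writeLines(c("@a", "ACGT", "+", "IIII"), f2)
  expect_error(readPairedFastq(f1, f2), "Phred\\+64")
})

test_that("trimPairs chains clip, window trim and pair filter", {
  ad <- as.character(illuminaAdapters()[[1]])
  rp <- makeReadPairs(300, readLen = 150, qualityProfile = "constant",
                      qHigh = 38, adapter = ad, adapterRate = 0.3,
                      seed = 13)
  out <- trimPairs(rp$r1, rp$r2, adapters = ad, minLen = 100)
  expect_equal(length(out$r1), length(out$r2))
  expect_equal(out$stats$pairs_in, 300L)
  expect_equal(out$stats$pairs_kept + out$stats$pairs_dropped, 300L)
  # adapter-bearing mates were clipped back to the recorded adapter start,
  # provided the fragment scores at least the simple-mode threshold of 10
  # (a perfect k-base fragment scores 0.6 * k, so k >= 17 is clippable)
  tr <- rp$truth
  clipped1 <- Biostrings::width(clipAdapter(rp$r1, ad))
  fragLen <- 150L - tr$adapter1 + 1L
  clippable <- !is.na(tr$adapter1) & fragLen >= 17L
  expect_true(all(clipped1[clippable] == tr$adapter1[clippable] - 1L))
  tooShort <- !is.na(tr$adapter1) & fragLen < 17L
  expect_true(all(clipped1[tooShort] == 150L))
  expect_true(all(clipped1[is.na(tr$adapter1)] == 150L))
})
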