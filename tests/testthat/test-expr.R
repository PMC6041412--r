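test_that("presence calls apply the detection threshold inclusively", {
  m <- rbind(t1 = c(root = 0, stem = 1), t2 = c(2, 0), t3 = c(1, 1))
  p <- presenceMatrix(m)
  expect_equal(unname(p), rbind(c(FALSE, TRUE), c(TRUE, FALSE),
                                c(TRUE, TRUE)),
               ignore_attr = TRUE)
  expect_equal(attr(p, "threshold"), 1)
  p5 <- presenceMatrix(m, threshold = 2)
  expect_equal(sum(p5), 1L)
  expect_error(presenceMatrix(m - 1), "non-negative")
  expect_error(presenceMatrix(unname(m)), "column names")
})

test_that("the Venn partition covers all 2^k - 1 regions exactly once", {
  m <- rbind(t1 = c(root = 5, stem = 0, leaf = 0),
             t2 = c(0, 3, 0), t3 = c(1, 1, 0), t4 = c(2, 2, 2),
             t5 = c(0, 0, 0))
  vp <- vennPartition(m)
  rc <- regionCounts(vp)
  expect_length(rc, 7L)
  expect_equal(unname(rc["root"]), 1L)
  expect_equal(unname(rc["stem"]), 1L)
  expect_equal(unname(rc["root+stem"]), 1L)
  expect_equal(unname(rc["root+stem+leaf"]), 1L)
  expect_equal(unname(rc["leaf"]), 0L)
  expect_equal(absentCount(vp), 1L)
  expect_equal(sum(rc) + absentCount(vp), nrow(m))
})

test_that("the partition matches the brute-force oracle and conserves totals", {
  set.seed(95)
  for (i in 1:300) {
    n <- sample(1:100, 1); k <- sample(2:5, 1)
    p <- matrix(stats::runif(n * k) < 0.5, n, k,
                dimnames = list(NULL, sprintf("T%d", 1:k)))
    vp <- vennPartition(p)
    rc <- regionCounts(vp)
    expect_equal(sum(rc) + absentCount(vp), n)
    want <- bruteVenn(p)
    expect_equal(absentCount(vp), want$nAbsent)
    nonzero <- rc[rc > 0L]
    expect_identical(nonzero[sort(names(nonzero))],
                     want$regions[sort(names(want$regions))])
  }
})

test_that("tissue-exclusive summaries pick singleton regions", {
  mx <- makeCountMatrix(c("leaf", "stem", "root"), 60,
                        c(leaf = 10, stem = 4, root = 25), seed = 96)
  ts <- tissueSpecificCounts(vennPartition(mx$counts))
  expect_equal(unname(ts$exclusive),
               c(10L, 4L, 25L))
  expect_equal(ts$min$tissue, "stem")
  expect_equal(ts$min$count, 4L)
  expect_equal(ts$max$tissue, "root")
  expect_equal(ts$max$count, 25L)
})

test_that("the Venn TSV round-trips region counts", {
  mx <- makeCountMatrix(c("a", "b"), 30, c(a = 7, b = 3), nAbsent = 2,
                        seed = 97)
  vp <- vennPartition(mx$counts)
  f <- tempfile(fileext = ".tsv")
  writeVennTsv(vp, f, threshold = 1)
  tab <- utils::read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_identical(stats::setNames(as.integer(tab$count), tab$region),
                   regionCounts(vp))
  hdr <- readLines(f, n = 2)
  expect_match(hdr[2], "absent in all tissues: 2")
})
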