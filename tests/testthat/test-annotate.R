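test_that("best hits collapse HSPs and void ambiguous ties", {
  hits <- rbind(hitRow("q1", "s1", 200), hitRow("q1", "s2", 150),
                # q2: two HSPs against the same subject are fine
                hitRow("q2", "s1", 300), hitRow("q2", "s1", 250),
                # q3: top bitscore shared by two different subjects -> void
                hitRow("q3", "s1", 180), hitRow("q3", "s2", 180))
  bh <- bestHits(hits)
  expect_equal(bh$voided, "q3")
  b <- stats::setNames(bh$best$subject, bh$best$query)
  expect_equal(unname(b["q1"]), "s1")
  expect_equal(unname(b["q2"]), "s1")
  expect_false("q3" %in% names(b))
  empty <- bestHits(emptyHitTable())
  expect_equal(nrow(empty$best), 0L)
})

test_that("reciprocal best hits require agreement in both directions", {
  fwd <- rbind(hitRow("q1", "s1", 200), hitRow("q2", "s2", 180),
               hitRow("q3", "s3", 150))
  rev <- rbind(hitRow("s1", "q1", 190),          # reciprocal
               hitRow("s2", "q9", 170),          # points elsewhere
               hitRow("s3", "q3", 140))          # reciprocal
  rbh <- reciprocalBestHits(fwd, rev)
  expect_equal(rbh$query, c("q1", "q3"))
  expect_equal(rbh$subject, c("s1", "s3"))
  expect_equal(rbh$forward_bitscore, c(200, 150))
  expect_equal(rbh$reverse_bitscore, c(190, 140))
})

test_that("RBH agrees with the brute-force double argmax on random matrices", {
  set.seed(90)
  for (i in 1:300) {
    nq <- sample(1:10, 1); ns <- sample(1:10, 1)
    # coarse scores force frequent ties
    sc <- matrix(sample(1:6, nq * ns, replace = TRUE), nq, ns,
                 dimnames = list(sprintf("q%02d", 1:nq),
                                 sprintf("s%02d", 1:ns)))
    h <- scoresToHits(sc)
    got <- reciprocalBestHits(h$fwd, h$rev)[, c("query", "subject")]
    rownames(got) <- NULL
    want <- bruteRbh(sc)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("annotation transfer joins function fields and flags gaps", {
  rbh <- data.frame(query = c("p1", "p2"), subject = c("AT1", "AT9"),
                    forward_bitscore = c(1, 1), reverse_bitscore = c(1, 1),
                    stringsAsFactors = FALSE)
  fun <- data.frame(gene = "AT1", description = "kinase", symbol = "KIN1",
                    stringsAsFactors = FALSE)
  expect_warning(ann <- transferAnnotation(rbh, fun, reference = "tair"),
                 "missing")
  expect_equal(ann$tair_gene, c("AT1", "AT9"))
  expect_equal(ann$tair_description, c("kinase", ""))
  expect_equal(ann$tair_symbol, c("KIN1", ""))

  ann2 <- transferAnnotation(rbh[1, ], fun)
  comb <- combineAnnotations(
    list(a = suppressWarnings(transferAnnotation(rbh, fun, "tair")),
         b = ann2),
    go = data.frame(query = "p1", go_terms = "GO:0004672"))
  expect_equal(nrow(comb), 2L)
  expect_equal(comb$go_terms, c("GO:0004672", NA))
  expect_true(all(c("tair_description", "ref_description") %in% names(comb)))
})
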