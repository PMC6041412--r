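#' Sliding-window quality trim point
#'
#' Scans windows of `window` bases from the 5' end and truncates the read at
#' the start of the first window whose mean Phred score drops below `meanQ`
#' (strict `<`). Windows are evaluated at every start position; a trailing
#' window shorter than `window` (including a read shorter than the window) is
#' evaluated as a single window of its own length.
#'
#' @param quals integer (or numeric) vector of per-base Phred scores.
#' @param window window length in bases (default 4).
#' @param meanQ mean-quality threshold (default 15).
#' @return `trimPoint` returns the length of the kept prefix (0 when the very
#'   first window already fails).
#' @examples
#' trimPoint(c(30, 30, 30, 30, 10, 10, 10, 10))  # 4
#' trimPoint(rep(40, 50))                        # 50
#' @export
trimPoint <- function(quals, window = 4L, meanQ = 15) {
  stopifnot(window >= 1L)
  L <- length(quals)
  if (L == 0L) return(0L)
  if (anyNA(quals)) stop("qualities contain NA", call. = FALSE)
  cs <- cumsum(c(0, as.numeric(quals)))
  i <- seq_len(L)
  wi <- pmin(window, L - i + 1L)
  means <- (cs[i + wi] - cs[i]) / wi
  fail <- which(means < meanQ)
  if (!length(fail)) L else fail[1L] - 1L
}

#' Paired-end read trimming with the window-4/Q15 rule
#'
#' `slidingWindowTrim` applies [trimPoint()] to every read of a
#' quality-scaled set and truncates sequences and qualities accordingly.
#' `clipAdapter` removes 3' adapter contamination in "simple" alignment mode:
#' for each adapter, candidate alignment starts are found by matching the
#' adapter's first 16-mer against the read with at most `seedMismatches`
#' mismatches; each candidate is scored ungapped (match +0.6, mismatch
#' -3.0) over the best-scoring seed-containing extension towards the read
#' end, and if the best alignment over all adapters scores at least
#' `simpleThreshold` the read is truncated at that alignment's start.
#' `filterPairs` drops a pair when either mate is shorter than `minLen`, so
#' no orphan reads survive. `trimPairs` chains the three in the conventional
#' order adapter clip, then window trim, then pair/length filter.
#'
#' Adapters shorter than the 16-base seed can never be matched and are
#' ignored with a warning; a "palindrome" mode against adapter read-through
#' of full fragments is not implemented (the `palindromeThreshold` argument
#' is accepted for interface compatibility but unused).
#'
#' @param reads,reads1,reads2 [Biostrings::QualityScaledDNAStringSet] objects
#'   (Phred+33); `reads1`/`reads2` are synchronized mates.
#' @param adapters adapter sequences (`DNAStringSet` or character vector).
#' @param window,meanQ see [trimPoint()].
#' @param seedMismatches maximum mismatches in the 16-mer seed (default 2).
#' @param simpleThreshold minimum simple-mode alignment score for a clip
#'   (default 10).
#' @param palindromeThreshold accepted, unused (see Details).
#' @param minLen minimum surviving mate length in nt (default 100).
#' @return `slidingWindowTrim` and `clipAdapter` return the trimmed
#'   `QualityScaledDNAStringSet`; `filterPairs` and `trimPairs` return
#'   `list(r1 =, r2 =, stats = list(...))` with pair tallies.
#' @examples
#' q <- Biostrings::PhredQuality(paste(rep("I", 8), collapse = ""))
#' r <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(read1 = "ACGTACGT")), q)
#' Biostrings::width(slidingWindowTrim(r))  # stays 8: all Q40
#' @export
slidingWindowTrim <- function(reads, window = 4L, meanQ = 15) {
  .checkQualReads(reads)
  if (!length(reads)) return(reads)
  qints <- methods::as(Biostrings::quality(reads), "IntegerList")
  keep <- vapply(qints, trimPoint, integer(1L),
                 window = window, meanQ = meanQ)
  .truncateReads(reads, keep)
}

#' @rdname slidingWindowTrim
#' @export
clipAdapter <- function(reads, adapters, seedMismatches = 2L,
                        simpleThreshold = 10, palindromeThreshold = 30) {
  .checkQualReads(reads)
  adapters <- .asDNAStringSet(adapters, "adapters")
  if (!length(adapters) || any(Biostrings::width(adapters) == 0L))
    stop("adapters must be non-empty sequences", call. = FALSE)
  short <- Biostrings::width(adapters) < 16L
  if (any(short)) {
    warning("ignoring ", sum(short), " adapter(s) shorter than the 16-nt seed")
    adapters <- adapters[!short]
  }
  if (!length(reads) || !length(adapters)) return(reads)

  seqs <- Biostrings::DNAStringSet(reads)
  seqChars <- as.character(seqs)
  L <- Biostrings::width(seqs)
  bestScore <- rep(-Inf, length(reads))
  clipAt <- rep(NA_integer_, length(reads))        # alignment start (1-based)

  for (ai in seq_along(adapters)) {
    aChar <- as.character(adapters[[ai]])
    aInt <- utf8ToInt(aChar)
    A <- length(aInt)
    seed <- Biostrings::subseq(adapters[[ai]], 1L, 16L)
    hits <- Biostrings::vmatchPattern(seed, seqs,
                                      max.mismatch = seedMismatches)
    starts <- IRanges::start(hits)
    for (ri in which(lengths(starts) > 0L)) {
      rInt <- utf8ToInt(seqChars[ri])
      for (j in unique(starts[[ri]])) {
        ov <- min(A, L[ri] - j + 1L)
        if (ov < 16L) next
        mm <- aInt[seq_len(ov)] != rInt[j:(j + ov - 1L)]
        sc <- cumsum(ifelse(mm, -3.0, 0.6))
        s <- max(sc[16:ov])                        # seed-containing prefixes
        if (s > bestScore[ri] ||
            (s == bestScore[ri] && !is.na(clipAt[ri]) && j < clipAt[ri])) {
          bestScore[ri] <- s
          clipAt[ri] <- j
        }
      }
    }
  }
  keep <- L
  clipped <- which(bestScore >= simpleThreshold)
  keep[clipped] <- clipAt[clipped] - 1L
  .truncateReads(reads, keep)
}

#' @rdname slidingWindowTrim
#' @export
filterPairs <- function(reads1, reads2, minLen = 100L) {
  .checkQualReads(reads1); .checkQualReads(reads2)
  .checkMateSync(reads1, reads2)
  ok1 <- Biostrings::width(reads1) >= minLen
  ok2 <- Biostrings::width(reads2) >= minLen
  keep <- ok1 & ok2
  list(r1 = reads1[keep], r2 = reads2[keep],
       stats = list(pairs_in = length(reads1),
                    pairs_kept = sum(keep),
                    pairs_dropped = sum(!keep),
                    mate1_short = sum(!ok1),
                    mate2_short = sum(!ok2)))
}

#' @rdname slidingWindowTrim
#' @export
trimPairs <- function(reads1, reads2, adapters = NULL, window = 4L,
                      meanQ = 15, minLen = 100L, seedMismatches = 2L,
                      simpleThreshold = 10, palindromeThreshold = 30) {
  .checkMateSync(reads1, reads2)
  basesIn <- sum(Biostrings::width(reads1)) + sum(Biostrings::width(reads2))
  if (!is.null(adapters)) {
    reads1 <- clipAdapter(reads1, adapters, seedMismatches, simpleThreshold,
                          palindromeThreshold)
    reads2 <- clipAdapter(reads2, adapters, seedMismatches, simpleThreshold,
                          palindromeThreshold)
  }
  reads1 <- slidingWindowTrim(reads1, window, meanQ)
  reads2 <- slidingWindowTrim(reads2, window, meanQ)
  res <- filterPairs(reads1, reads2, minLen)
  basesOut <- sum(Biostrings::width(res$r1)) + sum(Biostrings::width(res$r2))
  res$stats$bases_in <- basesIn
  res$stats$bases_out <- basesOut
  res$stats$bases_trimmed <- basesIn - basesOut
  res
}

.checkQualReads <- function(reads) {
  if (!is(reads, "QualityScaledDNAStringSet"))
    stop("reads must be a QualityScaledDNAStringSet (Phred+33)",
         call. = FALSE)
  qw <- Biostrings::width(Biostrings::quality(reads))
  if (any(qw != Biostrings::width(reads)))
    stop("sequence and quality lengths differ", call. = FALSE)
  invisible(TRUE)
}

# Truncate each read (sequence + qualities) to its kept prefix length.
.truncateReads <- function(reads, keep) {
  stopifnot(length(keep) == length(reads))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::subseq(Biostrings::DNAStringSet(reads), start = 1L,
                       width = keep),
    Biostrings::PhredQuality(
      Biostrings::subseq(methods::as(Biostrings::quality(reads),
                                     "BStringSet"),
                         start = 1L, width = keep)))
}
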