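# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive each quantity from first principles and
# share no code with the implementation under test.

# quality-scaled reads from a sequence and an integer quality vector
mkQualRead <- function(seq, quals, id = "r1") {
  stopifnot(nchar(seq) == length(quals))
  dna <- Biostrings::DNAStringSet(stats::setNames(seq, id))
  Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(intToUtf8(quals + 33L)))
}

mkQualReads <- function(seqs, qualsList, ids = sprintf("r%d", seq_along(seqs))) {
  dna <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  qs <- vapply(qualsList, function(q) intToUtf8(q + 33L), character(1L))
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(qs))
}

# one 12-column hit row
hitRow <- function(q, s, bit, ev = 1e-30, pid = 90, len = 150) {
  data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = ev, bitscore = bit,
             stringsAsFactors = FALSE)
}

# brute-force Nx: walk prefixes of the descending-sorted lengths
bruteNx <- function(lengths, x) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  need <- x / 100 * sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= need) return(s[i])
  }
  stop("unreachable")
}

# brute-force six-frame ORF candidate enumeration (regex-based, independent
# of the codon bookkeeping in findOrfs); returns sorted orf_key/peptide/met
bruteOrfs <- function(seqChar, minAa = 1L) {
  L <- nchar(seqChar)
  gcode <- Biostrings::GENETIC_CODE
  rows <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqChar)))
    else seqChar
    for (frame in 1:3) {
      ncod <- (L - frame + 1L) %/% 3L
      if (ncod < 1L) next
      pos <- frame + 3L * (seq_len(ncod) - 1L)
      cods <- substring(s2, pos, pos + 2L)
      aa <- unname(gcode[cods])
      aa[is.na(aa)] <- "X"
      aaStr <- paste(aa, collapse = "")
      segs <- gregexpr("[^*]+", aaStr)[[1L]]
      if (segs[1L] == -1L) next
      for (si in seq_along(segs)) {
        cs <- segs[si]
        ce <- cs + attr(segs, "match.length")[si] - 1L
        pep <- substr(aaStr, cs, ce)
        stopAfter <- ce < ncod   # a '*' codon follows the segment
        starts <- list()
        mpos <- regexpr("M", pep, fixed = TRUE)
        if (mpos > 0L) starts[[length(starts) + 1L]] <-
            list(cod = cs + as.integer(mpos) - 1L, met = TRUE)
        if (mpos != 1L) starts[[length(starts) + 1L]] <-
            list(cod = cs, met = FALSE)
        for (st in starts) {
          lenAa <- ce - st$cod + 1L
          if (lenAa < minAa) next
          lastCod <- if (stopAfter) ce + 1L else ce
          ntS <- frame + 3L * (st$cod - 1L)
          ntE <- frame + 3L * lastCod - 1L
          if (strand == "-") { t <- ntS; ntS <- L - ntE + 1L; ntE <- L - t + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            orf_key = sprintf("%s:%d-%d", strand, ntS, ntE),
            peptide = substr(aaStr, st$cod, ce),
            met_initiated = st$met, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orf_key = character(), peptide = character(),
               met_initiated = logical(), stringsAsFactors = FALSE)
  out[order(out$orf_key, out$met_initiated), , drop = FALSE]
}

# brute-force reciprocal best hits on a full score matrix (rows = queries,
# cols = subjects): double strict argmax with tie voiding
bruteRbh <- function(scores) {
  pairs <- list()
  for (i in seq_len(nrow(scores))) {
    ri <- scores[i, ]
    if (sum(ri == max(ri)) != 1L) next
    j <- which.max(ri)
    cj <- scores[, j]
    if (sum(cj == max(cj)) != 1L) next
    if (which.max(cj) == i)
      pairs[[length(pairs) + 1L]] <- c(rownames(scores)[i],
                                       colnames(scores)[j])
  }
  if (!length(pairs))
    return(data.frame(query = character(), subject = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, pairs)
  out <- data.frame(query = m[, 1L], subject = m[, 2L],
                    stringsAsFactors = FALSE)
  out[order(out$query), , drop = FALSE]
}

# full-matrix hit tables from a score matrix, for feeding reciprocalBestHits
scoresToHits <- function(scores) {
  idx <- expand.grid(i = seq_len(nrow(scores)), j = seq_len(ncol(scores)))
  fwd <- hitRow(rownames(scores)[idx$i], colnames(scores)[idx$j],
                scores[cbind(idx$i, idx$j)])
  rev <- hitRow(colnames(scores)[idx$j], rownames(scores)[idx$i],
                scores[cbind(idx$i, idx$j)])
  list(fwd = fwd, rev = rev)
}

# brute-force venn partition: per-transcript subset label counting
bruteVenn <- function(presence) {
  labels <- apply(presence, 1L, function(p)
    paste(colnames(presence)[p], collapse = "+"))
  tab <- table(labels[labels != ""])
  list(regions = stats::setNames(as.integer(tab),
                                 as.character(names(tab))),
       nAbsent = sum(labels == ""))
}
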