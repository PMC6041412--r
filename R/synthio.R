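#' Standard Illumina TruSeq adapter sequences
#'
#' The two 33-nt TruSeq indexed-adapter read-through sequences, the default
#' adapters planted and searched by the synthetic fixtures.
#'
#' @return A named `DNAStringSet` of length 2.
#' @export
illuminaAdapters <- function() {
  Biostrings::DNAStringSet(c(
    TruSeq_R1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    TruSeq_R2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"))
}

# sample() that never falls into the scalar-x trap
.sampleFrom <- function(x, n = 1L, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

#' Generate random contigs with recorded truth
#'
#' Uniform-length, fixed-GC random nucleotide contigs. Identical seed and
#' parameters reproduce byte-identical sequences and manifest.
#'
#' @param n number of contigs (>= 1).
#' @param lengthRange integer interval of contig lengths in nt.
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @return `list(contigs = DNAStringSet, manifest = FixtureManifest)`.
#' @export
makeContigs <- function(n, lengthRange = c(300L, 3000L), gc = 0.4,
                        seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length(lengthRange) != 2L || lengthRange[1L] < 1L ||
      lengthRange[2L] < lengthRange[1L])
    stop("invalid length range", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  .withSeed(seed, {
    lens <- .sampleFrom(seq.int(lengthRange[1L], lengthRange[2L]), n,
                        replace = TRUE)
    seqs <- vapply(lens, .randomDna, character(1L), gc = gc)
    ids <- sprintf("ctg%05d", seq_len(n))
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "contigs",
      truth = data.frame(contig_id = ids, length = lens,
                         stringsAsFactors = FALSE),
      params = list(n = n, lengthRange = lengthRange, gc = gc))
    list(contigs = contigs, manifest = manifest)
  })
}

#' Plant adapter fragments into contigs
#'
#' Overwrites a window of each selected contig with a 5' fragment of the
#' adapter covering at least `minFrac` of its length (fragments are kept
#' at >= 75% of the adapter so detection at word size 4 is well-posed).
#' Every planted span is recorded 1-based closed in the manifest.
#'
#' @param contigs `DNAStringSet` (modified copies are returned).
#' @param adapter a single adapter sequence, length >= 10 nt and no longer
#'   than the shortest contig.
#' @param rate fraction of contigs to plant into (exactly `round(rate * n)`
#'   contigs are selected).
#' @param seed RNG seed.
#' @param minFrac minimum planted fraction of the adapter (default 0.75).
#' @param ids optional explicit contig ids to plant into (overrides `rate`).
#' @return `list(contigs =, manifest =)`; manifest truth has columns
#'   `contig_id`, `start`, `end`.
#' @export
plantAdapters <- function(contigs, adapter, rate = 0.1, seed = 1L,
                          minFrac = 0.75, ids = NULL) {
  contigs <- .asDNAStringSet(contigs, "contigs")
  aChar <- .asSingleSeq(adapter)
  A <- nchar(aChar)
  if (A < 10L) stop("adapter must be at least 10 nt", call. = FALSE)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (A > min(Biostrings::width(contigs)))
    stop("adapter longer than the shortest contig", call. = FALSE)
  .withSeed(seed, {
    if (is.null(ids)) {
      nSel <- round(rate * length(contigs))
      ids <- if (nSel > 0L) .sampleFrom(names(contigs), nSel) else character()
    }
    seqs <- as.character(contigs)
    truth <- data.frame(contig_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    for (id in ids) {
      W <- nchar(seqs[id])
      fragLen <- .sampleFrom(seq.int(ceiling(minFrac * A), A))
      pos <- .sampleFrom(seq_len(W - fragLen + 1L))
      substr(seqs[id], pos, pos + fragLen - 1L) <- substr(aChar, 1L, fragLen)
      truth <- rbind(truth, data.frame(contig_id = id, start = pos,
                                       end = pos + fragLen - 1L,
                                       stringsAsFactors = FALSE))
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(contigs)
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "adapters", truth = truth,
      params = list(adapter = aChar, rate = rate, minFrac = minFrac))
    list(contigs = out, manifest = manifest)
  })
}

#' Plant contamination structure: truth labels, hit tables, taxonomy
#'
#' Splits the contig set into plant-like contigs (given a reference-genome
#' hit passing all three triage thresholds), bacterial-like contigs (no
#' passing reference hit, best general-database hit mapping to a bacterial
#' subject), optional non-bacterial-contaminant contigs (best hit to a
#' non-bacterial, non-reference taxon) and contigs with no hits at all.
#' Bacterial-like sequences are re-synthesized at a distinct GC content
#' purely for realism; classification evidence is exclusively the hit
#' tables. Decoy secondary hits (strictly lower bitscore) and failing
#' reference hits are sprinkled in to exercise the thresholds.
#'
#' @param contigs `DNAStringSet`.
#' @param bacterialFraction fraction labeled bacterial (exact count
#'   `round(fraction * n)`).
#' @param noHitFraction fraction with no hits in either table.
#' @param nonbacterialFraction fraction whose best general hit is
#'   non-bacterial (default 0).
#' @param gcBacterial GC content of re-synthesized bacterial-like sequences.
#' @param seed RNG seed.
#' @return `list(contigs =, refHits =, ntHits =, taxonomy =, manifest =)`;
#'   manifest truth has columns `contig_id`, `label` with the expected
#'   triage label.
#' @export
plantContaminants <- function(contigs, bacterialFraction = 0.2,
                              noHitFraction = 0.1,
                              nonbacterialFraction = 0,
                              gcBacterial = 0.65, seed = 1L) {
  contigs <- .asDNAStringSet(contigs, "contigs")
  fr <- c(bacterialFraction, noHitFraction, nonbacterialFraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("fractions must be in [0, 1] and sum to at most 1", call. = FALSE)
  n <- length(contigs)
  .withSeed(seed, {
    nB <- round(bacterialFraction * n)
    nH <- round(noHitFraction * n)
    nX <- round(nonbacterialFraction * n)
    ord <- .sampleFrom(names(contigs), n)
    bact <- ord[seq_len(nB)]
    nohit <- ord[nB + seq_len(nH)]
    nonb <- ord[nB + nH + seq_len(nX)]
    plant <- ord[seq.int(nB + nH + nX + 1L, length.out = n - nB - nH - nX)]

    seqs <- as.character(contigs)
    for (id in bact)
      seqs[id] <- .randomDna(nchar(seqs[id]), gc = gcBacterial)

    ref <- emptyHitTable()
    nt <- emptyHitTable()
    tax <- character(0)
    mkHit <- function(q, s, pid, len, ev, bit) {
      data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
                 mismatch = round(len * (100 - pid) / 100), gapopen = 0L,
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = ev, bitscore = bit, stringsAsFactors = FALSE)
    }
    failingRefHit <- function(q) {
      mode <- .sampleFrom(1:3)
      if (mode == 1L)        # too short
        mkHit(q, "Jcurcas_scf1", 90, .sampleFrom(40:100), 1e-8, 80)
      else if (mode == 2L)   # too divergent
        mkHit(q, "Jcurcas_scf1", .sampleFrom(60:80), 150, 1e-8, 90)
      else                   # too weak
        mkHit(q, "Jcurcas_scf1", 90, 150, .sampleFrom(c(1e-4, 1e-3)), 40)
    }
    for (id in plant) {
      ref <- rbind(ref, mkHit(id, sprintf("Jcurcas_scf%d", .sampleFrom(1:8)),
                              stats::runif(1, 81, 99),
                              .sampleFrom(101:400),
                              10^-stats::runif(1, 6, 60),
                              stats::runif(1, 150, 700)))
      if (stats::runif(1) < 0.3) ref <- rbind(ref, failingRefHit(id))
      if (stats::runif(1) < 0.2) {
        s <- sprintf("plantdb_%d", .sampleFrom(1:20))
        nt <- rbind(nt, mkHit(id, s, 90, 200, 1e-30, 300))
        tax[s] <- "Viridiplantae"
      }
    }
    for (id in bact) {
      if (stats::runif(1) < 0.5) ref <- rbind(ref, failingRefHit(id))
      s <- sprintf("bact_genome_%d", .sampleFrom(1:12))
      bit <- stats::runif(1, 200, 600)
      nt <- rbind(nt, mkHit(id, s, stats::runif(1, 85, 99),
                            .sampleFrom(120:500), 10^-stats::runif(1, 20, 80),
                            bit))
      tax[s] <- "Bacteria"
      if (stats::runif(1) < 0.5) {       # strictly weaker non-bacterial decoy
        d <- sprintf("plantdb_%d", .sampleFrom(1:20))
        nt <- rbind(nt, mkHit(id, d, 85, 100, 1e-10, bit - 50))
        tax[d] <- "Viridiplantae"
      }
    }
    for (id in nonb) {
      if (stats::runif(1) < 0.5) ref <- rbind(ref, failingRefHit(id))
      s <- sprintf("fungal_%d", .sampleFrom(1:6))
      bit <- stats::runif(1, 150, 500)
      nt <- rbind(nt, mkHit(id, s, stats::runif(1, 80, 98),
                            .sampleFrom(120:400), 10^-stats::runif(1, 10, 60),
                            bit))
      tax[s] <- "Fungi"
      if (stats::runif(1) < 0.5) {       # strictly weaker bacterial decoy
        d <- sprintf("bact_genome_%d", .sampleFrom(1:12))
        nt <- rbind(nt, mkHit(id, d, 85, 100, 1e-10, bit - 50))
        tax[d] <- "Bacteria"
      }
    }
    lab <- function(ids, l)
      data.frame(contig_id = ids, label = rep(l, length(ids)),
                 stringsAsFactors = FALSE)
    truth <- rbind(lab(plant, "PLANT_REFERENCE"),
                   lab(bact, "BACTERIAL_REMOVED"),
                   lab(nonb, "NONBACTERIAL_KEPT"),
                   lab(nohit, "NO_HIT_KEPT"))
    truth <- truth[match(names(contigs), truth$contig_id), , drop = FALSE]
    rownames(truth) <- NULL
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(contigs)
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "contaminants", truth = truth,
      params = list(bacterialFraction = bacterialFraction,
                    noHitFraction = noHitFraction,
                    nonbacterialFraction = nonbacterialFraction,
                    gcBacterial = gcBacterial))
    list(contigs = out, refHits = ref, ntHits = nt, taxonomy = tax,
         manifest = manifest)
  })
}

#' Plant a single known CDS into each synthetic contig
#'
#' Each contig is built around exactly one Met-initiated, stop-terminated
#' CDS of known coordinates and strand: random flanks, an in-frame guard
#' stop immediately 5' of the start codon, the planted codons, a stop and a
#' 3' flank. At generation time an internal brute-force six-frame scan
#' verifies that the planted ORF is the strictly longest Met-initiated ORF
#' on the contig (the contig is resampled otherwise), so representative
#' selection is guaranteed a unique right answer.
#'
#' @param n number of contigs.
#' @param peptideLengths amino-acid length interval of the planted peptide
#'   (minimum 10 aa).
#' @param strandMix probability a contig's CDS lies on the minus strand.
#' @param flankRange interval of flank lengths in nt.
#' @param gc GC content of flanks.
#' @param seed RNG seed.
#' @param maxTries resampling attempts per contig before giving up.
#' @return `list(contigs =, manifest =)`; manifest truth has columns
#'   `contig_id`, `strand`, `cds_start`, `cds_end` (1-based inclusive
#'   forward-strand, stop codon included), `peptide`.
#' @export
plantOrfs <- function(n, peptideLengths = c(50L, 300L), strandMix = 0.5,
                      flankRange = c(30L, 90L), gc = 0.4, seed = 1L,
                      maxTries = 50L) {
  if (peptideLengths[1L] < 10L)
    stop("minimum peptide length is 10 aa", call. = FALSE)
  if (strandMix < 0 || strandMix > 1)
    stop("strandMix must be in [0, 1]", call. = FALSE)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1L, paste,
                  collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  nonstop <- setdiff(codons, stops)
  .withSeed(seed, {
    ids <- sprintf("orfctg%04d", seq_len(n))
    seqs <- character(n)
    truth <- data.frame(contig_id = ids, strand = NA_character_,
                        cds_start = NA_integer_, cds_end = NA_integer_,
                        peptide = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        pepLen <- .sampleFrom(seq.int(peptideLengths[1L],
                                      peptideLengths[2L]))
        f1 <- .sampleFrom(seq.int(flankRange[1L], flankRange[2L]))
        f2 <- .sampleFrom(seq.int(flankRange[1L], flankRange[2L]))
        body <- paste(.sampleFrom(nonstop, pepLen - 1L, replace = TRUE),
                      collapse = "")
        sPlus <- paste0(.randomDna(f1, gc), .sampleFrom(stops), "ATG", body,
                        .sampleFrom(stops), .randomDna(f2, gc))
        csPlus <- f1 + 4L
        cePlus <- csPlus + 3L * (pepLen + 1L) - 1L
        minus <- stats::runif(1) < strandMix
        contigSeq <- if (minus) .revcomp(sPlus) else sPlus
        L <- nchar(contigSeq)
        cds <- if (minus) c(L - cePlus + 1L, L - csPlus + 1L)
               else c(csPlus, cePlus)
        chk <- .naiveLongestMetOrf(contigSeq)
        if (chk$length == pepLen && chk$count == 1L &&
            chk$start == cds[1L] && chk$end == cds[2L]) {
          pep <- as.character(Biostrings::translate(
            Biostrings::DNAString(paste0("ATG", body))))
          seqs[i] <- contigSeq
          truth$strand[i] <- if (minus) "-" else "+"
          truth$cds_start[i] <- cds[1L]
          truth$cds_end[i] <- cds[2L]
          truth$peptide[i] <- pep
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not construct an unambiguous planted ORF after ",
             maxTries, " attempts", call. = FALSE)
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "orfs", truth = truth,
      params = list(peptideLengths = peptideLengths, strandMix = strandMix,
                    flankRange = flankRange, gc = gc))
    list(contigs = contigs, manifest = manifest)
  })
}

# Brute-force six-frame scan: the longest Met-initiated ORF (aa length
# excluding the stop), how many distinct Met starts achieve that length, and
# the forward-strand CDS interval (stop included when present) of the best.
# Deliberately naive; used only to certify generated fixtures.
.naiveLongestMetOrf <- function(seqChar) {
  gc <- Biostrings::GENETIC_CODE
  best <- list(length = 0L, count = 0L, start = NA_integer_,
               end = NA_integer_)
  L <- nchar(seqChar)
  for (strand in c("+", "-")) {
    s2 <- if (strand == "-") .revcomp(seqChar) else seqChar
    for (frame in 1:3) {
      ncod <- (L - frame + 1L) %/% 3L
      if (ncod < 1L) next
      starts <- frame + 3L * (seq_len(ncod) - 1L)
      cods <- substring(s2, starts, starts + 2L)
      aa <- unname(gc[cods])
      aa[is.na(aa)] <- "X"
      stopIdx <- which(aa == "*")
      for (m in which(aa == "M")) {
        nxt <- stopIdx[stopIdx > m]
        hasStop <- length(nxt) > 0L
        endCod <- if (hasStop) nxt[1L] - 1L else ncod
        len <- endCod - m + 1L
        ntS <- frame + 3L * (m - 1L)
        ntE <- frame + 3L * (if (hasStop) endCod + 1L else endCod) - 1L
        if (strand == "-") { tmp <- ntS; ntS <- L - ntE + 1L
                             ntE <- L - tmp + 1L }
        if (len > best$length) {
          best <- list(length = len, count = 1L, start = ntS, end = ntE)
        } else if (len == best$length) best$count <- best$count + 1L
      }
    }
  }
  best
}

#' Generate a transcripts-by-tissues count matrix with designed exclusivity
#'
#' A designed number of transcripts per tissue receives nonzero counts only
#' in that tissue; an optional set is all-zero; the remainder is shared with
#' nonzero counts in every tissue. The true Venn partition is returned with
#' the manifest.
#'
#' @param tissues character vector of tissue labels (non-empty).
#' @param nTranscripts total number of transcripts.
#' @param exclusiveDesign named integer vector (names in `tissues`) of
#'   per-tissue exclusive transcript counts.
#' @param nAbsent number of all-zero transcripts (default 0).
#' @param countRange interval nonzero counts are drawn from.
#' @param seed RNG seed.
#' @return `list(counts = matrix, partition = VennPartition, manifest =)`.
#' @export
makeCountMatrix <- function(tissues, nTranscripts,
                            exclusiveDesign = integer(0), nAbsent = 0L,
                            countRange = c(5L, 500L), seed = 1L) {
  if (!length(tissues)) stop("tissues must be non-empty", call. = FALSE)
  if (length(exclusiveDesign) &&
      !all(names(exclusiveDesign) %in% tissues))
    stop("exclusiveDesign names must be tissue labels", call. = FALSE)
  if (sum(exclusiveDesign) + nAbsent > nTranscripts)
    stop("design exceeds the number of transcripts", call. = FALSE)
  .withSeed(seed, {
    ids <- sprintf("tx%05d", seq_len(nTranscripts))
    ord <- .sampleFrom(ids, nTranscripts)
    counts <- matrix(0, nrow = nTranscripts, ncol = length(tissues),
                     dimnames = list(ids, tissues))
    pat <- stats::setNames(rep("all", nTranscripts), ids)
    off <- 0L
    for (t in names(exclusiveDesign)) {
      kk <- exclusiveDesign[[t]]
      sel <- ord[off + seq_len(kk)]; off <- off + kk
      counts[sel, t] <- .sampleFrom(seq.int(countRange[1L], countRange[2L]),
                                    kk, replace = TRUE)
      pat[sel] <- t
    }
    if (nAbsent > 0L) {
      sel <- ord[off + seq_len(nAbsent)]; off <- off + nAbsent
      pat[sel] <- "absent"
    }
    shared <- ord[off + seq_len(nTranscripts - off)]
    if (length(shared))
      counts[shared, ] <- .sampleFrom(seq.int(countRange[1L],
                                              countRange[2L]),
                                      length(shared) * length(tissues),
                                      replace = TRUE)
    regions <- stats::setNames(
      integer(2L^length(tissues) - 1L), names(.tissueSubsets(tissues)))
    for (t in names(exclusiveDesign))
      regions[t] <- as.integer(exclusiveDesign[[t]])
    regions[paste(tissues, collapse = "+")] <- length(shared)
    partition <- methods::new("VennPartition", tissues = tissues,
                              regions = regions,
                              nAbsent = as.integer(nAbsent))
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "counts",
      truth = data.frame(transcript_id = ids, pattern = unname(pat[ids]),
                         stringsAsFactors = FALSE),
      params = list(tissues = tissues, nTranscripts = nTranscripts,
                    exclusiveDesign = as.list(exclusiveDesign),
                    nAbsent = nAbsent))
    list(counts = counts, partition = partition, manifest = manifest)
  })
}

#' Generate paired reads with known quality-trim truth
#'
#' Phred+33 paired reads whose per-read trim point under the sliding-window
#' rule is computed at generation time by an independent naive window scan
#' and recorded in the truth table. The `"step"` profile holds quality
#' around `qHigh` up to a per-read drop position and around `qLow` after
#' it; `"constant"` holds `qHigh` throughout (trim point = read length).
#' Optionally a 3' adapter fragment is written into a fraction of reads.
#'
#' @param nPairs number of read pairs.
#' @param readLen read length in nt (>= 20).
#' @param qualityProfile `"step"` or `"constant"`.
#' @param qHigh,qLow central Phred scores of the two quality regimes.
#' @param adapter optional adapter sequence for 3' contamination.
#' @param adapterRate fraction of reads carrying the adapter.
#' @param window,meanQ trimming rule parameters used for the recorded truth.
#' @param seed RNG seed.
#' @return `list(r1 =, r2 = QualityScaledDNAStringSet, truth = data.frame(
#'   id, trim1, trim2, adapter1, adapter2), manifest =)`.
#' @export
makeReadPairs <- function(nPairs, readLen = 150L,
                          qualityProfile = c("step", "constant"),
                          qHigh = 35L, qLow = 2L, adapter = NULL,
                          adapterRate = 0, window = 4L, meanQ = 15,
                          seed = 1L) {
  if (readLen < 20L) stop("readLen must be at least 20", call. = FALSE)
  qualityProfile <- match.arg(qualityProfile)
  .withSeed(seed, {
    ids <- sprintf("read%06d", seq_len(nPairs))
    mkMate <- function() {
      seqs <- vapply(rep.int(readLen, nPairs), .randomDna, character(1L),
                     gc = 0.5)
      quals <- matrix(0L, nrow = nPairs, ncol = readLen)
      for (i in seq_len(nPairs)) {
        q <- qHigh + .sampleFrom(-2:2, readLen, replace = TRUE)
        if (qualityProfile == "step") {
          p <- .sampleFrom(seq.int(max(2L, readLen %/% 5L), readLen + 1L))
          if (p <= readLen)
            q[p:readLen] <- qLow + .sampleFrom(0:3, readLen - p + 1L,
                                               replace = TRUE)
        }
        quals[i, ] <- q
      }
      adPos <- rep(NA_integer_, nPairs)
      if (!is.null(adapter) && adapterRate > 0) {
        aChar <- .asSingleSeq(adapter)
        nAd <- round(adapterRate * nPairs)
        sel <- if (nAd > 0L) .sampleFrom(seq_len(nPairs), nAd) else integer()
        for (i in sel) {
          fragLen <- .sampleFrom(seq.int(16L, min(nchar(aChar), readLen)))
          pos <- readLen - fragLen + 1L
          substr(seqs[i], pos, readLen) <- substr(aChar, 1L, fragLen)
          adPos[i] <- pos
        }
      }
      trims <- vapply(seq_len(nPairs), function(i)
        .naiveTrimPoint(quals[i, ], window, meanQ), integer(1L))
      qchars <- vapply(seq_len(nPairs), function(i)
        intToUtf8(quals[i, ] + 33L), character(1L))
      dna <- Biostrings::DNAStringSet(seqs)
      names(dna) <- ids
      reads <- Biostrings::QualityScaledDNAStringSet(
        dna, Biostrings::PhredQuality(qchars))
      list(reads = reads, trims = trims, adPos = adPos)
    }
    m1 <- mkMate(); m2 <- mkMate()
    truth <- data.frame(id = ids, trim1 = m1$trims, trim2 = m2$trims,
                        adapter1 = m1$adPos, adapter2 = m2$adPos,
                        stringsAsFactors = FALSE)
    manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
      kind = "reads", truth = truth,
      params = list(nPairs = nPairs, readLen = readLen,
                    qualityProfile = qualityProfile, qHigh = qHigh,
                    qLow = qLow, adapterRate = adapterRate,
                    window = window, meanQ = meanQ))
    list(r1 = m1$reads, r2 = m2$reads, truth = truth, manifest = manifest)
  })
}

# Naive per-read window scan, the generation-time oracle for trim points.
.naiveTrimPoint <- function(q, window = 4L, meanQ = 15) {
  L <- length(q)
  for (i in seq_len(L)) {
    e <- min(i + window - 1L, L)
    if (mean(q[i:e]) < meanQ) return(i - 1L)
  }
  L
}

#' End-to-end cleanup fixture with per-contig expected fate
#'
#' Composes [makeContigs()], [plantContaminants()] and [plantAdapters()]
#' into one fixture for the whole cleanup pipeline, then derives each
#' contig's expected fate (`KEPT`, `ADAPTER_CLIP_TOO_SHORT`, `BACTERIAL`,
#' `TOO_SHORT`) from first principles: adapter spans are located by an
#' internal naive diagonal scan (independent of the scanning code under
#' test), clip survival and final length are computed arithmetically and
#' the triage label comes from the planted contamination truth.
#'
#' @param nContigs number of contigs.
#' @param lengthRange contig length interval.
#' @param adapterRate fraction of contigs with a planted adapter fragment.
#' @param bacterialFraction,noHitFraction,nonbacterialFraction see
#'   [plantContaminants()].
#' @param adapter adapter sequence planted and expected (default first
#'   TruSeq adapter).
#' @param clipMinLen,finalMinLen cleanup cutoffs (defaults 200 and 400).
#' @param seed RNG seed.
#' @return `list(contigs =, adapters =, refHits =, ntHits =, taxonomy =,
#'   manifest =)`; manifest truth columns: `contig_id`, `triage_label`,
#'   `expected_fate`, `expected_length` (NA when removed), `adapter_planted`.
#' @export
makeCleanupFixture <- function(nContigs = 500L,
                               lengthRange = c(300L, 3000L),
                               adapterRate = 0.1, bacterialFraction = 0.2,
                               noHitFraction = 0.1,
                               nonbacterialFraction = 0.05,
                               adapter = NULL, clipMinLen = 200L,
                               finalMinLen = 400L, seed = 1L) {
  if (is.null(adapter))
    adapter <- as.character(illuminaAdapters()[[1L]])
  base <- makeContigs(nContigs, lengthRange, gc = 0.4, seed = seed)
  cont <- plantContaminants(base$contigs, bacterialFraction, noHitFraction,
                            nonbacterialFraction, seed = seed + 1L)
  withAd <- plantAdapters(cont$contigs, adapter, rate = adapterRate,
                          seed = seed + 2L)
  contigs <- withAd$contigs
  planted <- withAd$manifest@truth$contig_id

  labels <- cont$manifest@truth
  fate <- character(nContigs); expLen <- rep(NA_integer_, nContigs)
  for (i in seq_len(nContigs)) {
    id <- names(contigs)[i]
    seqChar <- as.character(contigs[[i]])
    W <- nchar(seqChar)
    spans <- .naiveAdapterSpans(seqChar, adapter)
    if (nrow(spans)) {
      bounds <- c(0L, as.vector(t(spans)), W + 1L)
      segs <- matrix(bounds, ncol = 2L, byrow = TRUE)
      lens <- segs[, 2L] - segs[, 1L] - 1L
      survivor <- if (any(lens > 0L)) max(lens) else 0L
      if (survivor < clipMinLen) { fate[i] <- "ADAPTER_CLIP_TOO_SHORT"; next }
      W <- survivor
    }
    lab <- labels$label[labels$contig_id == id]
    if (lab == "BACTERIAL_REMOVED") { fate[i] <- "BACTERIAL"; next }
    if (W < finalMinLen) { fate[i] <- "TOO_SHORT"; next }
    fate[i] <- "KEPT"; expLen[i] <- W
  }
  truth <- data.frame(contig_id = names(contigs),
                      triage_label = labels$label,
                      expected_fate = fate, expected_length = expLen,
                      adapter_planted = names(contigs) %in% planted,
                      stringsAsFactors = FALSE)
  manifest <- methods::new("FixtureManifest", seed = as.integer(seed),
    kind = "cleanup", truth = truth,
    params = list(nContigs = nContigs, adapterRate = adapterRate,
                  bacterialFraction = bacterialFraction,
                  noHitFraction = noHitFraction,
                  nonbacterialFraction = nonbacterialFraction,
                  clipMinLen = clipMinLen, finalMinLen = finalMinLen))
  list(contigs = contigs, adapters = Biostrings::DNAStringSet(
         stats::setNames(adapter, "adapter")),
       refHits = cont$refHits, ntHits = cont$ntHits,
       taxonomy = cont$taxonomy, manifest = manifest)
}

# Naive adapter-span finder: substring-table seeding plus a per-diagonal
# scan with an explicit running-score loop. Same defined quantity as
# scanAdapters() (best segment per seeded diagonal, Karlin-Altschul filter),
# written independently for generation-time truth.
.naiveAdapterSpans <- function(seqChar, adapterChar, wordSize = 4L,
                               evalueMax = 0.01, lambda = 1.28, K = 0.46) {
  L <- nchar(seqChar); A <- nchar(adapterChar)
  if (L < wordSize || A < wordSize)
    return(cbind(start = integer(), end = integer()))
  cK <- substring(seqChar, seq_len(L - wordSize + 1L),
                  seq_len(L - wordSize + 1L) + wordSize - 1L)
  aK <- substring(adapterChar, seq_len(A - wordSize + 1L),
                  seq_len(A - wordSize + 1L) + wordSize - 1L)
  diags <- integer(0)
  for (p in seq_along(aK)) {
    if (grepl("N", aK[p], fixed = TRUE)) next
    hit <- which(cK == aK[p])
    if (length(hit)) diags <- c(diags, hit - p)
  }
  cChars <- strsplit(seqChar, "", fixed = TRUE)[[1L]]
  aChars <- strsplit(adapterChar, "", fixed = TRUE)[[1L]]
  spans <- cbind(start = integer(), end = integer())
  for (d in unique(diags)) {
    cs <- max(1L, 1L + d); ce <- min(L, A + d)
    run <- 0; runStart <- cs
    top <- -Inf; topS <- topE <- NA_integer_
    for (p in cs:ce) {
      match <- cChars[p] == aChars[p - d] && cChars[p] != "N"
      run <- run + if (match) 1 else -2
      if (run > top) { top <- run; topS <- runStart; topE <- p }
      if (run < 0) { run <- 0; runStart <- p + 1L }
    }
    if (K * L * A * exp(-lambda * top) <= evalueMax)
      spans <- rbind(spans, cbind(start = topS, end = topE))
  }
  .mergeIntervals(spans[, "start"], spans[, "end"])
}
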