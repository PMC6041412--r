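#' Detect residual adapter fragments in assembled contigs
#'
#' Word-based seed-and-extend search, modelled on an ungapped nucleotide
#' alignment at small word size: every exact `wordSize`-mer shared between an
#' adapter and the contig seeds its alignment diagonal, and on every seeded
#' diagonal the maximum-scoring ungapped segment (match +1, mismatch -2;
#' leftmost segment on score ties) is located. A segment of score S is
#' reported as an adapter span when its Karlin-Altschul expectation
#' `K * m * n * exp(-lambda * S)` (m = contig length, n = adapter length)
#' is at most `evalueMax`. Overlapping or adjacent spans are merged.
#'
#' @param contig a `DNAString`, single-sequence `DNAStringSet` or character
#'   string.
#' @param adapters adapter sequences (`DNAStringSet` or character).
#' @param wordSize exact-match word size seeding a diagonal (default 4,
#'   minimum 2).
#' @param evalueMax maximum expectation for a reported span (default 0.01).
#' @param lambda,K Karlin-Altschul parameters for the +1/-2 scoring scheme
#'   (defaults 1.28 and 0.46).
#' @return An [IRanges::IRanges] of merged adapter spans on the contig
#'   (1-based, closed).
#' @examples
#' ad <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
#' ctg <- paste0(strrep("ACGT", 30), ad, strrep("TTGCA", 20))
#' scanAdapters(ctg, ad)
#' @seealso [clipContig()], [runCleanup()]
#' @export
scanAdapters <- function(contig, adapters, wordSize = 4L, evalueMax = 0.01,
                         lambda = 1.28, K = 0.46) {
  if (wordSize < 2L) stop("wordSize must be at least 2", call. = FALSE)
  contig <- .asSingleSeq(contig)
  adapters <- .asDNAStringSet(adapters, "adapters")
  if (!length(adapters) || any(Biostrings::width(adapters) == 0L))
    stop("adapters must be non-empty sequences", call. = FALSE)
  cInt <- .dnaCode(contig)
  spans <- cbind(start = integer(), end = integer())
  for (ai in seq_along(adapters)) {
    aInt <- .dnaCode(as.character(adapters[[ai]]))
    sp <- .diagonalSpans(cInt, aInt, wordSize, evalueMax, lambda, K)
    spans <- rbind(spans, sp)
  }
  m <- .mergeIntervals(spans[, "start"], spans[, "end"])
  IRanges::IRanges(start = m[, "start"], end = m[, "end"])
}

# Base codes A=0 C=1 G=2 T=3, N (or other IUPAC) = NA.
.dnaCode <- function(x) {
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
  map[utf8ToInt(toupper(x))]
}

# Rolling k-mer integer codes (NA where any base is ambiguous).
.kmerCodes <- function(v, k) {
  n <- length(v) - k + 1L
  if (n < 1L) return(integer(0))
  code <- v[seq_len(n)]
  for (j in seq_len(k - 1L))
    code <- code * 4L + v[seq_len(n) + j]
  code
}

# All spans from seeded diagonals between one contig and one adapter,
# as a start/end matrix of segments passing the e-value filter.
.diagonalSpans <- function(cInt, aInt, wordSize, evalueMax, lambda, K) {
  L <- length(cInt); A <- length(aInt)
  out <- cbind(start = integer(), end = integer())
  if (A < wordSize || L < wordSize) return(out)
  ck <- .kmerCodes(cInt, wordSize)
  ak <- .kmerCodes(aInt, wordSize)
  akOk <- which(!is.na(ak))
  if (!length(akOk)) return(out)
  # minimum score that can pass the e-value cut, to skip hopeless diagonals
  minS <- log(K * L * A / evalueMax) / lambda
  diags <- integer(0)
  for (p in akOk) {
    hits <- which(ck == ak[p])
    if (length(hits)) diags <- c(diags, hits - p)
  }
  for (d in unique(diags)) {
    cs <- max(1L, 1L + d); ce <- min(L, A + d)
    if (ce - cs + 1L < wordSize) next
    v <- ifelse(!is.na(cInt[cs:ce]) & !is.na(aInt[(cs:ce) - d]) &
                  cInt[cs:ce] == aInt[(cs:ce) - d], 1, -2)
    seg <- .bestSegment(v)
    if (seg["score"] >= minS) {
      ev <- K * L * A * exp(-lambda * seg["score"])
      if (ev <= evalueMax)
        out <- rbind(out, cbind(start = cs + seg[["start"]] - 1L,
                                end = cs + seg[["end"]] - 1L))
    }
  }
  out
}

# Maximum-scoring contiguous segment (Kadane); leftmost segment on ties.
.bestSegment <- function(v) {
  best <- -Inf; bs <- be <- 0L
  cur <- 0; cstart <- 1L
  for (i in seq_along(v)) {
    cur <- cur + v[i]
    if (cur > best) { best <- cur; bs <- cstart; be <- i }
    if (cur < 0) { cur <- 0; cstart <- i + 1L }
  }
  c(score = best, start = bs, end = be)
}

#' Clip adapter spans out of a contig
#'
#' Removes the given spans and keeps the longest remaining segment (leftmost
#' on length ties) as the new sequence; the contig is discarded when that
#' segment is shorter than `minLen` (the assembler's 200-nt report cutoff by
#' default).
#'
#' @param contig a `DNAString`/character sequence.
#' @param spans an [IRanges::IRanges] (or 2-column start/end matrix) of
#'   adapter spans, 1-based closed, within the contig.
#' @param minLen minimum surviving segment length (default 200).
#' @return A list with `sequence` (character, or `NA` when removed), `kept`
#'   (logical), `segment` (start/end of the kept segment or `NULL`),
#'   `bases_removed` and `new_length`.
#' @export
clipContig <- function(contig, spans, minLen = 200L) {
  seqChar <- as.character(.asSingleSeq(contig))
  W <- nchar(seqChar)
  if (is(spans, "IRanges")) {
    sp <- cbind(start = IRanges::start(spans), end = IRanges::end(spans))
  } else sp <- spans
  if (nrow(sp) == 0L)
    return(list(sequence = seqChar, kept = TRUE, segment = c(1L, W),
                bases_removed = 0L, new_length = W))
  if (any(sp[, "start"] < 1L) || any(sp[, "end"] > W) ||
      any(sp[, "start"] > sp[, "end"]))
    stop("adapter span out of contig bounds", call. = FALSE)
  sp <- .mergeIntervals(sp[, "start"], sp[, "end"])
  # complementary segments
  bounds <- c(0L, as.vector(t(sp)), W + 1L)
  segs <- matrix(bounds, ncol = 2L, byrow = TRUE)  # (end_prev, start_next)
  segStart <- segs[, 1L] + 1L
  segEnd <- segs[, 2L] - 1L
  lens <- segEnd - segStart + 1L
  ok <- lens > 0L
  removed <- sum(sp[, "end"] - sp[, "start"] + 1L)
  if (!any(ok) || max(lens[ok]) < minLen)
    return(list(sequence = NA_character_, kept = FALSE, segment = NULL,
                bases_removed = removed, new_length = 0L))
  i <- which(ok)[which.max(lens[ok])]   # leftmost longest
  list(sequence = substr(seqChar, segStart[i], segEnd[i]), kept = TRUE,
       segment = c(segStart[i], segEnd[i]),
       bases_removed = W - lens[i], new_length = lens[i])
}

#' Two-stage contamination triage of assembled contigs
#'
#' Stage one checks hits against a related plant reference genome: a contig
#' is accepted as `PLANT_REFERENCE` when any reference hit simultaneously
#' satisfies e-value `< refEvalue`, alignment length `> refAlnLen` and
#' percent identity `> refIdentity`. Contigs failing stage one are triaged by
#' their best hit in a general nucleotide database: no hit at all keeps the
#' contig (`NO_HIT_KEPT`); a best hit whose subject maps to the bacterial
#' group removes it (`BACTERIAL_REMOVED`); any other best hit keeps it
#' (`NONBACTERIAL_KEPT`). The best hit is the maximum bitscore, with ties
#' broken by minimum e-value, then maximum alignment length, then subject id
#' (ascending). A subject missing from the taxonomy map is a data error,
#' never a silent keep.
#'
#' @param contigIds character vector of contig identifiers to triage.
#' @param refHits,ntHits 12-column hit tables (see [readHitTable()]); `NULL`
#'   is treated as no hits.
#' @param taxonomy named character vector mapping every `ntHits` subject to a
#'   group (see [readTaxonomyMap()]).
#' @param refEvalue,refAlnLen,refIdentity stage-one thresholds (defaults
#'   1e-5, 100 nt, 80%).
#' @param bacterialGroup taxonomy group triggering removal (default
#'   `"Bacteria"`).
#' @return data.frame with columns `contig_id`, `label`, `subject_id`,
#'   `bitscore`, `evalue` (supporting best hit, `NA` where none).
#' @export
classifyContamination <- function(contigIds, refHits = NULL, ntHits = NULL,
                                  taxonomy = NULL, refEvalue = 1e-5,
                                  refAlnLen = 100, refIdentity = 80,
                                  bacterialGroup = "Bacteria") {
  refHits <- if (is.null(refHits)) emptyHitTable() else .asHitTable(refHits)
  ntHits <- if (is.null(ntHits)) emptyHitTable() else .asHitTable(ntHits)
  taxonomy <- if (is.null(taxonomy)) character(0) else .asTaxonomyMap(taxonomy)
  missing_subj <- setdiff(unique(ntHits$sseqid), names(taxonomy))
  if (length(missing_subj))
    stop("subject(s) absent from taxonomy map: ",
         paste(utils::head(missing_subj, 3L), collapse = ", "),
         call. = FALSE)

  refPass <- refHits[refHits$evalue < refEvalue &
                       refHits$length > refAlnLen &
                       refHits$pident > refIdentity, , drop = FALSE]
  refBy <- split(refPass, refPass$qseqid)
  ntBy <- split(ntHits, ntHits$qseqid)

  n <- length(contigIds)
  label <- character(n); subj <- rep(NA_character_, n)
  bits <- rep(NA_real_, n); ev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    id <- contigIds[i]
    rp <- refBy[[id]]
    if (!is.null(rp) && nrow(rp)) {
      j <- order(-rp$bitscore, rp$evalue, -rp$length, rp$sseqid)[1L]
      label[i] <- "PLANT_REFERENCE"
      subj[i] <- rp$sseqid[j]; bits[i] <- rp$bitscore[j]; ev[i] <- rp$evalue[j]
      next
    }
    nt <- ntBy[[id]]
    if (is.null(nt) || !nrow(nt)) { label[i] <- "NO_HIT_KEPT"; next }
    j <- order(-nt$bitscore, nt$evalue, -nt$length, nt$sseqid)[1L]
    subj[i] <- nt$sseqid[j]; bits[i] <- nt$bitscore[j]; ev[i] <- nt$evalue[j]
    label[i] <- if (identical(unname(taxonomy[subj[i]]), bacterialGroup))
      "BACTERIAL_REMOVED" else "NONBACTERIAL_KEPT"
  }
  data.frame(contig_id = contigIds, label = label, subject_id = subj,
             bitscore = bits, evalue = ev, stringsAsFactors = FALSE)
}

#' Final contig length filter
#'
#' Removes contigs shorter than `minLen` (default 400 nt; a contig of exactly
#' `minLen` survives).
#'
#' @param contigs a `DNAStringSet`.
#' @param minLen minimum retained length in nt.
#' @return `list(contigs =, removed = <ids>, n_removed =)`.
#' @export
lengthFilter <- function(contigs, minLen = 400L) {
  contigs <- .asDNAStringSet(contigs, "contigs")
  keep <- Biostrings::width(contigs) >= minLen
  list(contigs = contigs[keep], removed = names(contigs)[!keep],
       n_removed = sum(!keep))
}

#' Run the full post-assembly cleanup
#'
#' Applies the three cleanup stages in order: (1) adapter scan and clip
#' ([scanAdapters()] + [clipContig()]), (2) contamination triage
#' ([classifyContamination()]), (3) final length filter ([lengthFilter()]).
#' Returns the cleaned contig set and a [CleanupReport-class] whose counts
#' reconcile exactly at every stage.
#'
#' @param contigs input `DNAStringSet` (unique names required).
#' @param adapters adapter sequences; `NULL` skips the clipping stage's scan
#'   (all contigs pass unclipped).
#' @param refHits,ntHits,taxonomy see [classifyContamination()].
#' @param clipMinLen minimum surviving segment after clipping (default 200).
#' @param finalMinLen final length cutoff (default 400).
#' @param wordSize,scanEvalue,lambda,K adapter-scan parameters, see
#'   [scanAdapters()].
#' @param refEvalue,refAlnLen,refIdentity,bacterialGroup triage thresholds,
#'   see [classifyContamination()].
#' @return `list(contigs = DNAStringSet, report = CleanupReport)`.
#' @export
runCleanup <- function(contigs, adapters = NULL, refHits = NULL,
                       ntHits = NULL, taxonomy = NULL, clipMinLen = 200L,
                       finalMinLen = 400L, wordSize = 4L, scanEvalue = 0.01,
                       lambda = 1.28, K = 0.46, refEvalue = 1e-5,
                       refAlnLen = 100, refIdentity = 80,
                       bacterialGroup = "Bacteria") {
  contigs <- .asDNAStringSet(contigs, "contigs")
  if (anyDuplicated(names(contigs)))
    stop("contig ids must be unique", call. = FALSE)
  removals <- data.frame(contig_id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)

  ## stage 1: adapter clip
  n_in1 <- length(contigs)
  clips <- data.frame(contig_id = character(), n_spans = integer(),
                      bases_removed = integer(), new_length = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(adapters) && n_in1) {
    adapters <- .asDNAStringSet(adapters, "adapters")
    seqs <- as.character(contigs)
    keepSeq <- seqs
    drop <- logical(n_in1)
    for (i in seq_len(n_in1)) {
      spans <- scanAdapters(seqs[i], adapters, wordSize = wordSize,
                            evalueMax = scanEvalue, lambda = lambda, K = K)
      if (!length(spans)) next
      cl <- clipContig(seqs[i], spans, minLen = clipMinLen)
      clips <- rbind(clips, data.frame(
        contig_id = names(contigs)[i], n_spans = length(spans),
        bases_removed = cl$bases_removed,
        new_length = cl$new_length, stringsAsFactors = FALSE))
      if (cl$kept) keepSeq[i] <- cl$sequence else drop[i] <- TRUE
    }
    if (any(drop))
      removals <- rbind(removals, data.frame(
        contig_id = names(contigs)[drop], stage = "adapter_clip",
        reason = "ADAPTER_CLIP_TOO_SHORT", stringsAsFactors = FALSE))
    contigs <- Biostrings::DNAStringSet(keepSeq[!drop])
    names(contigs) <- names(keepSeq)[!drop]
  }
  st1 <- data.frame(stage = "adapter_clip", n_in = n_in1,
                    n_removed = n_in1 - length(contigs),
                    n_out = length(contigs))

  ## stage 2: contamination triage
  n_in2 <- length(contigs)
  triage <- classifyContamination(names(contigs), refHits, ntHits, taxonomy,
                                  refEvalue = refEvalue,
                                  refAlnLen = refAlnLen,
                                  refIdentity = refIdentity,
                                  bacterialGroup = bacterialGroup)
  bact <- triage$contig_id[triage$label == "BACTERIAL_REMOVED"]
  if (length(bact))
    removals <- rbind(removals, data.frame(
      contig_id = bact, stage = "contamination", reason = "BACTERIAL",
      stringsAsFactors = FALSE))
  contigs <- contigs[!names(contigs) %in% bact]
  st2 <- data.frame(stage = "contamination", n_in = n_in2,
                    n_removed = n_in2 - length(contigs),
                    n_out = length(contigs))

  ## stage 3: length filter
  n_in3 <- length(contigs)
  lf <- lengthFilter(contigs, finalMinLen)
  if (length(lf$removed))
    removals <- rbind(removals, data.frame(
      contig_id = lf$removed, stage = "length_filter", reason = "TOO_SHORT",
      stringsAsFactors = FALSE))
  contigs <- lf$contigs
  st3 <- data.frame(stage = "length_filter", n_in = n_in3,
                    n_removed = lf$n_removed, n_out = length(contigs))

  report <- methods::new("CleanupReport", stages = rbind(st1, st2, st3),
                         removals = removals, clips = clips, triage = triage)
  methods::validObject(report)
  list(contigs = contigs, report = report)
}

.asSingleSeq <- function(x) {
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(x[[1L]])
  } else if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop("expected a single non-empty sequence", call. = FALSE)
  toupper(x)
}
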