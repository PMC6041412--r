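#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code. `frame` is 1-3 on the given strand; for the minus
#' strand the sequence is reverse-complemented first, so
#' `translateFrame(s, 1, "-")` equals `translateFrame(revcomp(s), 1, "+")`.
#' Any codon containing an ambiguous base translates to `X`. Stop codons are
#' rendered as `*` in the returned frame translation (they delimit ORFs and
#' are never part of an emitted peptide).
#'
#' @param dna a `DNAString` or character sequence over the ACGTN alphabet
#'   (anything else is a format error).
#' @param frame reading frame, 1, 2 or 3.
#' @param strand `"+"` or `"-"`.
#' @return Character string of amino acids (possibly containing `*`).
#' @examples
#' translateFrame("ATGAAA")            # "MK"
#' translateFrame("ATGNNN")            # "MX"
#' @export
translateFrame <- function(dna, frame = 1L, strand = "+") {
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'",
                                     call. = FALSE)
  s <- .asSingleSeq(dna)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside the ACGTN alphabet",
         call. = FALSE)
  d <- Biostrings::DNAString(s)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  L <- length(d)
  ncod <- (L - frame + 1L) %/% 3L
  if (ncod < 1L) return("")
  d <- Biostrings::subseq(d, frame, frame + 3L * ncod - 1L)
  # no.init.codon: a frame translation has no initiation context, so
  # alternative start codons (TTG/CTG) must not be rendered as M
  as.character(Biostrings::translate(d, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Enumerate ORF candidates in all six frames
#'
#' For every maximal stop-to-stop segment of each frame (segments at the
#' sequence edge are bounded by the sequence end), two candidates are
#' derived: the longest Met-initiated ORF within the segment (from the
#' segment's first Met to its end) and, when the segment does not itself
#' start with Met, the full open segment as a 5'-partial candidate
#' (`met_initiated = FALSE`). Candidates shorter than `minAa` amino acids
#' are dropped. Coordinates are 1-based inclusive on the forward strand and
#' include the terminating stop codon when one exists.
#'
#' @param contigs a `DNAStringSet` (or single sequence) of length >= 3 nt
#'   each.
#' @param minAa minimum peptide length in amino acids (default 30; lower it
#'   to enumerate short ORFs).
#' @return data.frame with columns `contig_id`, `orf_key`, `strand`,
#'   `frame`, `cds_start`, `cds_end`, `peptide`, `length_aa`,
#'   `met_initiated`, `has_stop`, `source`.
#' @examples
#' findOrfs("ATGAAATAA", minAa = 1)    # MK at 1..9 on "+"
#' @export
findOrfs <- function(contigs, minAa = 30L) {
  contigs <- .asDNAStringSet(contigs, "contigs")
  .checkAlphabet(contigs)
  if (any(Biostrings::width(contigs) < 3L))
    stop("contigs must be at least 3 nt long", call. = FALSE)
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    out[[i]] <- .findOrfsOne(names(contigs)[i],
                             as.character(contigs[[i]]), minAa)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .emptyOrfFrame()
  rownames(res) <- NULL
  res
}

.emptyOrfFrame <- function() {
  data.frame(contig_id = character(), orf_key = character(),
             strand = character(), frame = integer(), cds_start = integer(),
             cds_end = integer(), peptide = character(),
             length_aa = integer(), met_initiated = logical(),
             has_stop = logical(), source = character(),
             stringsAsFactors = FALSE)
}

.findOrfsOne <- function(id, seqChar, minAa) {
  L <- nchar(seqChar)
  rows <- list()
  for (strand in c("+", "-")) {
    for (frame in 1:3) {
      aa <- translateFrame(seqChar, frame, strand)
      nc <- nchar(aa)
      if (nc == 0L) next
      codons <- strsplit(aa, "", fixed = TRUE)[[1L]]
      stops <- which(codons == "*")
      segStart <- c(1L, stops + 1L)
      segEnd <- c(stops - 1L, nc)
      hasStop <- c(rep(TRUE, length(stops)), FALSE)
      for (k in seq_along(segStart)) {
        cs <- segStart[k]; ce <- segEnd[k]
        if (ce < cs) next
        pep <- substr(aa, cs, ce)
        cands <- list()
        mpos <- regexpr("M", pep, fixed = TRUE)
        if (mpos > 0L)
          cands[[length(cands) + 1L]] <-
            list(cs = cs + as.integer(mpos) - 1L, met = TRUE)
        if (mpos != 1L)    # full open segment, 5'-partial
          cands[[length(cands) + 1L]] <- list(cs = cs, met = FALSE)
        for (cand in cands) {
          lenAa <- ce - cand$cs + 1L
          if (lenAa < minAa) next
          ceEff <- if (hasStop[k]) ce + 1L else ce
          ntS <- frame + 3L * (cand$cs - 1L)
          ntE <- frame + 3L * ceEff - 1L
          if (strand == "-") {
            fS <- L - ntE + 1L; fE <- L - ntS + 1L
          } else { fS <- ntS; fE <- ntE }
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = id,
            orf_key = sprintf("%s:%s:%d-%d", id, strand, fS, fE),
            strand = strand, frame = frame, cds_start = fS, cds_end = fE,
            peptide = substr(aa, cand$cs, ce), length_aa = lenAa,
            met_initiated = cand$met, has_stop = hasStop[k],
            source = "internal", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Merge ORF candidate sets from multiple predictors
#'
#' Candidates identical in (contig, strand, CDS start, CDS end) collapse to
#' a single record whose `source` field lists all contributing predictors;
#' nothing else is lost.
#'
#' @param internal candidate data.frame from [findOrfs()].
#' @param ... further candidate data.frames (same columns; `source` should
#'   name the external predictor).
#' @param contigLengths optional named vector of contig lengths for bounds
#'   validation of external candidates.
#' @return Deduplicated candidate data.frame.
#' @export
mergeCandidates <- function(internal, ..., contigLengths = NULL) {
  sets <- c(list(internal), list(...))
  sets <- sets[!vapply(sets, is.null, logical(1L))]
  all <- do.call(rbind, sets)
  if (is.null(all) || !nrow(all)) return(.emptyOrfFrame())
  if (!is.null(contigLengths)) {
    lim <- contigLengths[all$contig_id]
    bad <- is.na(lim) | all$cds_start < 1L | all$cds_end > lim
    if (any(bad))
      stop("candidate coordinates out of contig bounds: ",
           paste(utils::head(all$orf_key[bad], 3L), collapse = ", "),
           call. = FALSE)
  }
  key <- paste(all$contig_id, all$strand, all$cds_start, all$cds_end)
  src <- vapply(split(all$source, key)[unique(key)],
                function(s) paste(sort(unique(unlist(strsplit(s, ",")))),
                                  collapse = ","),
                character(1L))
  out <- all[!duplicated(key), , drop = FALSE]
  out$source <- unname(src[paste(out$contig_id, out$strand, out$cds_start,
                                 out$cds_end)])
  rownames(out) <- NULL
  out
}

#' Select the representative peptide of one contig
#'
#' Implements the selection and keep rules applied to merged ORF candidate
#' sets: by default the longest Met-initiated candidate wins (ties: lower CDS
#' start; if no candidate is Met-initiated, the longest candidate overall),
#' with reason `LONGEST_MET`. But if any candidate has a significant
#' protein-database hit (e-value `< evalueKeep`), the hit evidence overrides
#' length: the candidate with the highest bitscore wins (ties: longer
#' peptide, then lower CDS start), with reason `HIT_SCORE`. The winner is
#' kept only if its peptide is longer than `minKeepAa` amino acids
#' (`LENGTH_GT_100`) or it has a significant hit (`HIT_E_LT_1e10`);
#' otherwise `kept = FALSE` with reason `NOT_KEPT`.
#'
#' `selectRepresentatives` applies the rule per contig across a whole
#' candidate table.
#'
#' @param candidates candidate data.frame (one contig for the singular form).
#' @param hits protein-database hits for the candidates: either a 12-column
#'   hit table whose `qseqid` equals the candidate `orf_key`, or a
#'   data.frame with columns `orf_key`, `bitscore`, `evalue` (optionally
#'   `sseqid`). `NULL` means no hits.
#' @param evalueKeep significance threshold for both the override and the
#'   keep rule (default 1e-10).
#' @param minKeepAa length threshold of the keep rule, strict `>` (default
#'   100).
#' @return One row (or one per contig) with the winning candidate's columns
#'   plus `selection_reason`, `kept`, `keep_reason`, `hit_subject`,
#'   `hit_bitscore`, `hit_evalue`.
#' @export
selectRepresentative <- function(candidates, hits = NULL,
                                 evalueKeep = 1e-10, minKeepAa = 100L) {
  if (is.null(candidates) || !nrow(candidates))
    stop("candidate list is empty", call. = FALSE)
  if (length(unique(candidates$contig_id)) != 1L)
    stop("selectRepresentative expects candidates of a single contig; use selectRepresentatives",
         call. = FALSE)
  hits <- .asOrfHits(hits)
  h <- hits[match(candidates$orf_key, hits$orf_key), , drop = FALSE]
  sig <- !is.na(h$evalue) & h$evalue < evalueKeep
  if (any(sig)) {
    idx <- which(sig)
    j <- idx[order(-h$bitscore[idx], -candidates$length_aa[idx],
                   candidates$cds_start[idx])][1L]
    reason <- "HIT_SCORE"
  } else {
    met <- candidates$met_initiated
    pool <- if (any(met)) which(met) else seq_len(nrow(candidates))
    j <- pool[order(-candidates$length_aa[pool],
                    candidates$cds_start[pool])][1L]
    reason <- "LONGEST_MET"
  }
  win <- candidates[j, , drop = FALSE]
  winSig <- sig[j]
  kept <- win$length_aa > minKeepAa || winSig
  keepReason <- if (winSig) "HIT_E_LT_1e10"
                else if (win$length_aa > minKeepAa) "LENGTH_GT_100"
                else "NOT_KEPT"
  win$selection_reason <- reason
  win$kept <- kept
  win$keep_reason <- keepReason
  win$hit_subject <- if (!is.na(h$evalue[j]) && "sseqid" %in% names(h))
    h$sseqid[j] else NA_character_
  win$hit_bitscore <- h$bitscore[j]
  win$hit_evalue <- h$evalue[j]
  rownames(win) <- NULL
  win
}

#' @rdname selectRepresentative
#' @export
selectRepresentatives <- function(candidates, hits = NULL,
                                  evalueKeep = 1e-10, minKeepAa = 100L) {
  if (is.null(candidates) || !nrow(candidates))
    return(NULL)
  hits <- .asOrfHits(hits)
  parts <- split(candidates, candidates$contig_id)
  out <- lapply(parts, selectRepresentative, hits = hits,
                evalueKeep = evalueKeep, minKeepAa = minKeepAa)
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.asOrfHits <- function(hits) {
  if (is.null(hits))
    return(data.frame(orf_key = character(), sseqid = character(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  if ("qseqid" %in% names(hits) && !"orf_key" %in% names(hits))
    names(hits)[names(hits) == "qseqid"] <- "orf_key"
  stopifnot(all(c("orf_key", "bitscore", "evalue") %in% names(hits)))
  if (!nrow(hits)) return(hits)
  # several HSPs per candidate: keep the best-scoring one
  o <- order(hits$orf_key, -hits$bitscore, hits$evalue)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$orf_key), , drop = FALSE]
}

#' Write representative peptides as FASTA and CDS coordinates as GFF3
#'
#' Peptide identifiers are `<contig>.p1` and match the GFF3 `ID` attribute.
#' CDS features are emitted 1-based inclusive with phase 0; the terminating
#' stop codon is included in the interval when present.
#'
#' @param representatives output of [selectRepresentatives()] (typically
#'   filtered to `kept`).
#' @param fastaPath,gffPath output paths; `NULL` skips the respective file.
#' @param keptOnly write only representatives with `kept = TRUE` (default
#'   TRUE).
#' @return Invisibly, the GRanges of emitted CDS features.
#' @export
writeOrfOutputs <- function(representatives, fastaPath = NULL,
                            gffPath = NULL, keptOnly = TRUE) {
  reps <- representatives
  if (keptOnly) reps <- reps[reps$kept, , drop = FALSE]
  ids <- if (nrow(reps)) paste0(reps$contig_id, ".p1") else character(0)
  gr <- GenomicRanges::GRanges(
    seqnames = reps$contig_id,
    ranges = IRanges::IRanges(reps$cds_start, reps$cds_end),
    strand = reps$strand)
  S4Vectors::mcols(gr)$type <- rep("CDS", length(gr))
  S4Vectors::mcols(gr)$phase <- rep(0L, length(gr))
  S4Vectors::mcols(gr)$ID <- ids
  if (!is.null(fastaPath)) {
    pep <- Biostrings::AAStringSet(reps$peptide)
    names(pep) <- ids
    Biostrings::writeXStringSet(pep, fastaPath)
  }
  if (!is.null(gffPath))
    rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(gr)
}
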