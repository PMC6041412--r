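#' Read and write 12-column tabular alignment hit files
#'
#' The tabular pairwise-alignment format used throughout the package is the
#' standard 12-column tab-separated layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, i.e. BLAST
#' `-outfmt 6`). Parsing is strict: every row must have exactly 12 fields and
#' numeric fields must parse, otherwise a format error naming the offending
#' line is raised.
#'
#' @param path path to a tab-separated hit file (no header).
#' @param hits data.frame of hits as returned by `readHitTable`.
#' @return `readHitTable` returns a data.frame with columns `qseqid`,
#'   `sseqid`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' h <- emptyHitTable()
#' h[1, ] <- list("q1", "s1", 97.5, 150, 3, 0, 1, 150, 10, 159, 1e-40, 250)
#' writeHitTable(h, tf)
#' readHitTable(tf)
#' @export
readHitTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHitTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop(sprintf("malformed hit table '%s': line %d has %d fields, expected 12",
                 path, which(nf != 12L)[1L], nf[nf != 12L][1L]), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                    pident = as.numeric(m[, 3L]),
                    length = as.integer(m[, 4L]),
                    mismatch = as.integer(m[, 5L]),
                    gapopen = as.integer(m[, 6L]),
                    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
                    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
                    evalue = as.numeric(m[, 11L]),
                    bitscore = as.numeric(m[, 12L]),
                    stringsAsFactors = FALSE)
  badnum <- which(!stats::complete.cases(out[c("pident", "length", "evalue",
                                               "bitscore")]))
  if (length(badnum))
    stop(sprintf("malformed hit table '%s': non-numeric field on line %d",
                 path, badnum[1L]), call. = FALSE)
  .validateHits(out)
  out
}

#' @rdname readHitTable
#' @export
writeHitTable <- function(hits, path) {
  hits <- .asHitTable(hits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname readHitTable
#' @export
emptyHitTable <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

.asHitTable <- function(hits) {
  if (!is.data.frame(hits))
    stop("hits must be a data.frame", call. = FALSE)
  if (!all(.HIT_COLS %in% names(hits))) {
    if (ncol(hits) == 12L) names(hits) <- .HIT_COLS
    else stop("hit table must have the 12 standard columns", call. = FALSE)
  }
  .validateHits(hits)
  hits[.HIT_COLS]
}

.validateHits <- function(hits) {
  if (!nrow(hits)) return(invisible(TRUE))
  if (any(hits$qstart > hits$qend))
    stop("invalid hit record: qstart > qend", call. = FALSE)
  if (any(hits$evalue < 0))
    stop("invalid hit record: negative e-value", call. = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("invalid hit record: percent identity outside [0, 100]",
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write a subject-taxonomy map
#'
#' Two-column tab-separated table mapping alignment subject identifiers to a
#' coarse taxonomic group (for contamination triage only the group
#' `"Bacteria"` is decision-relevant; anything else counts as non-bacterial).
#'
#' @param path path to a two-column TSV (`subject_id<TAB>group`, no header).
#' @param taxonomy named character vector (`names` = subject ids, values =
#'   groups) or a two-column data.frame.
#' @return `readTaxonomyMap` returns a named character vector.
#' @export
readTaxonomyMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("subject_id", "group"),
                          colClasses = "character", quote = "")
  stats::setNames(df$group, df$subject_id)
}

#' @rdname readTaxonomyMap
#' @export
writeTaxonomyMap <- function(taxonomy, path) {
  taxonomy <- .asTaxonomyMap(taxonomy)
  utils::write.table(data.frame(names(taxonomy), unname(taxonomy)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.asTaxonomyMap <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    stopifnot(ncol(taxonomy) >= 2L)
    taxonomy <- stats::setNames(as.character(taxonomy[[2L]]),
                                as.character(taxonomy[[1L]]))
  }
  if (is.null(names(taxonomy)))
    stop("taxonomy map must be named by subject id", call. = FALSE)
  taxonomy
}

#' Read and write a transcripts-by-tissues count matrix
#'
#' Tab-separated matrix with a header row of tissue labels and transcript
#' identifiers in the first column. Counts must be non-negative numbers.
#'
#' @param path path to the TSV file.
#' @param counts numeric matrix with transcript rownames and tissue colnames.
#' @return `readCountMatrix` returns a numeric matrix.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("count matrix contains non-numeric cells", call. = FALSE)
  m
}

#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(counts, path) {
  utils::write.table(data.frame(transcript = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired FASTQ library with quality validation
#'
#' Reads two mate files into [Biostrings::QualityScaledDNAStringSet] objects
#' (Phred+33). Files whose quality strings are plainly Phred+64 encoded
#' (decoded scores beyond Q50) are rejected with a format error rather than
#' silently mis-decoded. Mate files must contain the same number of records
#' with matching identifier stems (trailing `/1`, `/2` or a space-separated
#' tail are ignored).
#'
#' @param file1,file2 paths to the two mate FASTQ files (plain or gzip).
#' @param reads1,reads2 `QualityScaledDNAStringSet` mates to write.
#' @return `readPairedFastq` returns `list(r1 =, r2 =)` of
#'   `QualityScaledDNAStringSet`.
#' @export
readPairedFastq <- function(file1, file2) {
  r1 <- .readFastqQuiet(file1)
  r2 <- .readFastqQuiet(file2)
  .checkPhred33(r1, file1)
  .checkPhred33(r2, file2)
  .checkMateSync(r1, r2)
  list(r1 = r1, r2 = r2)
}

#' @rdname readPairedFastq
#' @export
writePairedFastq <- function(reads1, reads2, file1, file2) {
  Biostrings::writeQualityScaledXStringSet(reads1, file1)
  Biostrings::writeQualityScaledXStringSet(reads2, file2)
  invisible(c(file1, file2))
}

# readQualityScaledDNAStringSet warns about dropping the metadata columns it
# itself attaches during parsing; that warning carries no information here.
.readFastqQuiet <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

.checkPhred33 <- function(reads, path = "reads") {
  if (!length(reads)) return(invisible(TRUE))
  q <- unlist(methods::as(Biostrings::quality(reads), "IntegerList"),
              use.names = FALSE)
  if (length(q) && max(q) > 50L)
    stop(sprintf(
      "'%s' decodes to Phred scores above 50; input looks Phred+64 encoded, only Phred+33 is supported",
      path), call. = FALSE)
  invisible(TRUE)
}

.idStem <- function(ids) sub("/[12]$", "", sub("\\s.*$", "", ids))

.checkMateSync <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop(sprintf("mate files are out of sync: %d vs %d records",
                 length(r1), length(r2)), call. = FALSE)
  s1 <- .idStem(names(r1)); s2 <- .idStem(names(r2))
  bad <- which(s1 != s2)
  if (length(bad))
    stop(sprintf("mate files are out of sync: record %d ids '%s' vs '%s'",
                 bad[1L], s1[bad[1L]], s2[bad[1L]]), call. = FALSE)
  invisible(TRUE)
}
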