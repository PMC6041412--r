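#' Per-query best hits from a tabular alignment result
#'
#' For every query, the hit with the maximum bitscore is retained. Multiple
#' HSPs against the same subject collapse to the best-scoring one first; if
#' after that the top bitscore is shared by two or more *different*
#' subjects, the query is voided (no best hit is assigned) — a conservative,
#' deterministic tie policy.
#'
#' @param hits a 12-column hit table (data.frame or file path, see
#'   [readHitTable()]).
#' @return `list(best = data.frame(query, subject, bitscore, evalue),
#'   voided = character)`.
#' @export
bestHits <- function(hits) {
  if (is.character(hits) && length(hits) == 1L) hits <- readHitTable(hits)
  hits <- .asHitTable(hits)
  if (!nrow(hits))
    return(list(best = data.frame(query = character(), subject = character(),
                                  bitscore = numeric(), evalue = numeric(),
                                  stringsAsFactors = FALSE),
                voided = character()))
  # best HSP per (query, subject)
  o <- order(hits$qseqid, hits$sseqid, -hits$bitscore, hits$evalue)
  hs <- hits[o, , drop = FALSE]
  hs <- hs[!duplicated(paste(hs$qseqid, hs$sseqid)), , drop = FALSE]
  # rank subjects per query by bitscore
  o <- order(hs$qseqid, -hs$bitscore)
  hs <- hs[o, , drop = FALSE]
  first <- !duplicated(hs$qseqid)
  top <- hs[first, , drop = FALSE]
  # a query is voided when its 2nd-ranked subject ties the top bitscore
  second <- hs[!first, , drop = FALSE]
  second <- second[!duplicated(second$qseqid), , drop = FALSE]
  tieTop <- top$bitscore[match(second$qseqid, top$qseqid)]
  voided <- second$qseqid[second$bitscore == tieTop]
  best <- top[!top$qseqid %in% voided, , drop = FALSE]
  out <- data.frame(query = best$qseqid, subject = best$sseqid,
                    bitscore = best$bitscore, evalue = best$evalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(best = out, voided = sort(unique(voided)))
}

#' Reciprocal best hits between two peptide sets
#'
#' A pair (q, s) is a reciprocal best hit (RBH) when s is q's best hit in
#' the forward search and q is s's best hit in the reverse search. Queries
#' voided by bitscore ties in either direction (see [bestHits()]) can never
#' form a pair. RBHs are the standard conservative ortholog proxy used for
#' annotation transfer.
#'
#' @param forward,reverse either raw 12-column hit tables (data.frame or
#'   path) or the output of [bestHits()].
#' @return data.frame with columns `query`, `subject`, `forward_bitscore`,
#'   `reverse_bitscore`, sorted by `query`.
#' @export
reciprocalBestHits <- function(forward, reverse) {
  fb <- .asBestHitMap(forward)
  rb <- .asBestHitMap(reverse)
  f <- fb$best; r <- rb$best
  rmap <- stats::setNames(r$subject, r$query)
  hit <- !is.na(rmap[f$subject]) & rmap[f$subject] == f$query
  hit[is.na(hit)] <- FALSE
  pairs <- f[hit, , drop = FALSE]
  out <- data.frame(query = pairs$query, subject = pairs$subject,
                    forward_bitscore = pairs$bitscore,
                    reverse_bitscore = r$bitscore[match(pairs$subject,
                                                        r$query)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.asBestHitMap <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(c("best", "voided") %in% names(x))) return(x)
  bestHits(x)
}

#' Transfer functional annotation across reciprocal best hits
#'
#' Joins the RBH pairs with a reference functional table (gene id to
#' description and optional symbol). Subjects missing from the table yield
#' blank fields with a warning. `combineAnnotations` places the transfers
#' from several reference proteomes side by side, keyed by the peptide
#' query; an optional two-column GO-term table (query, terms) is merged in
#' as-is, never computed.
#'
#' @param rbhPairs data.frame from [reciprocalBestHits()].
#' @param functions reference table: data.frame whose first column is the
#'   gene id, with a `description` column (and optionally `symbol`), or a
#'   TSV path with a header.
#' @param reference short label of the reference set, used as a column
#'   prefix (default `"ref"`).
#' @param annotations named list of `transferAnnotation` outputs.
#' @param go optional data.frame (query, go_terms) merged into the combined
#'   table.
#' @return data.frame with one row per RBH peptide (`query`), the reference
#'   gene id and its functional fields.
#' @export
transferAnnotation <- function(rbhPairs, functions, reference = "ref") {
  if (is.character(functions) && length(functions) == 1L)
    functions <- utils::read.table(functions, sep = "\t", header = TRUE,
                                   quote = "", stringsAsFactors = FALSE)
  stopifnot(is.data.frame(functions), ncol(functions) >= 2L)
  geneCol <- names(functions)[1L]
  idx <- match(rbhPairs$subject, functions[[geneCol]])
  if (anyNA(idx))
    warning(sum(is.na(idx)), " RBH subject(s) missing from the '",
            reference, "' functional table; fields left blank")
  out <- data.frame(query = rbhPairs$query, stringsAsFactors = FALSE)
  out[[paste0(reference, "_gene")]] <- rbhPairs$subject
  for (col in names(functions)[-1L]) {
    v <- functions[[col]][idx]
    v[is.na(idx)] <- ""
    out[[paste0(reference, "_", col)]] <- v
  }
  out
}

#' @rdname transferAnnotation
#' @export
combineAnnotations <- function(annotations, go = NULL) {
  stopifnot(is.list(annotations), length(annotations) >= 1L)
  out <- annotations[[1L]]
  for (a in annotations[-1L])
    out <- merge(out, a, by = "query", all = TRUE, sort = FALSE)
  if (!is.null(go)) {
    stopifnot(ncol(go) >= 2L)
    names(go)[1:2] <- c("query", "go_terms")
    out <- merge(out, go[1:2], by = "query", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}
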