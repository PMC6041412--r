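#' Presence/absence calls from a count matrix
#'
#' A transcript is called present in a tissue when its count is at least
#' `threshold` (default 1 read; the detection criterion is a stated choice,
#' recorded in the output's `threshold` attribute, since raw presence of a
#' single multi-mapped read is already counted as detection). Raising the
#' threshold can only switch calls from present to absent.
#'
#' @param counts numeric matrix (transcripts x tissues, non-negative) or a
#'   TSV path (see [readCountMatrix()]).
#' @param threshold minimum count for a presence call.
#' @return Logical matrix of the same shape, with attribute `threshold`.
#' @export
presenceMatrix <- function(counts, threshold = 1) {
  if (is.character(counts) && length(counts) == 1L)
    counts <- readCountMatrix(counts)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("count matrix must have tissue column names", call. = FALSE)
  p <- counts >= threshold
  attr(p, "threshold") <- threshold
  p
}

#' Venn partition of transcripts over tissue subsets
#'
#' Assigns every transcript present in at least one tissue to exactly one
#' region — the subset of tissues it is present in — and counts all
#' `2^k - 1` regions; transcripts absent everywhere are tallied separately.
#' Region sums plus the absent count always equal the number of transcripts.
#'
#' @param presence logical matrix from [presenceMatrix()] (or a count
#'   matrix/path, in which case `threshold` is applied first).
#' @param threshold passed to [presenceMatrix()] when `presence` is numeric.
#' @return A [VennPartition-class] object.
#' @examples
#' m <- rbind(t1 = c(root = 5, stem = 0), t2 = c(9, 9), t3 = c(0, 1))
#' regionCounts(vennPartition(m))
#' @export
vennPartition <- function(presence, threshold = 1) {
  if (is.character(presence) || is.numeric(presence))
    presence <- presenceMatrix(presence, threshold)
  presence <- as.matrix(presence)
  stopifnot(is.logical(presence))
  tissues <- colnames(presence)
  if (is.null(tissues) || !length(tissues))
    stop("presence matrix must have tissue column names", call. = FALSE)
  k <- length(tissues)
  subsets <- .tissueSubsets(tissues)
  # region index of each transcript: binary code over tissue columns
  code <- as.integer(presence %*% 2L^(seq_len(k) - 1L))
  regions <- stats::setNames(integer(length(subsets)), names(subsets))
  tab <- table(code[code > 0L])
  hit <- match(as.integer(names(tab)), vapply(subsets, attr, integer(1L),
                                              "code"))
  regions[hit] <- as.integer(tab)
  methods::new("VennPartition", tissues = tissues, regions = regions,
               nAbsent = sum(code == 0L))
}

# All non-empty tissue subsets in binary-code order, named by "+"-joined
# member labels (tissue order preserved); each carries its binary code.
.tissueSubsets <- function(tissues) {
  k <- length(tissues)
  out <- list()
  for (code in seq_len(2L^k - 1L)) {
    members <- tissues[bitwAnd(code, 2L^(seq_len(k) - 1L)) > 0L]
    s <- structure(members, code = code)
    out[[paste(members, collapse = "+")]] <- s
  }
  out
}

#' Tissue-exclusive transcript counts
#'
#' The exclusive count of a tissue is the size of its singleton region in
#' the Venn partition (transcripts detected in that tissue and nowhere
#' else). The summary reports the tissues with the smallest and largest
#' exclusive counts (first in tissue order on ties).
#'
#' @param partition a [VennPartition-class].
#' @return `list(exclusive = named integer, min = list(tissue, count),
#'   max = list(tissue, count))`.
#' @export
tissueSpecificCounts <- function(partition) {
  stopifnot(is(partition, "VennPartition"))
  tissues <- tissueLabels(partition)
  ex <- regionCounts(partition)[tissues]
  names(ex) <- tissues
  imin <- which.min(ex); imax <- which.max(ex)
  list(exclusive = ex,
       min = list(tissue = tissues[imin], count = unname(ex[imin])),
       max = list(tissue = tissues[imax], count = unname(ex[imax])))
}

#' Write a Venn partition as a region-count table
#'
#' One row per non-empty tissue subset (members joined by `"+"`), plus the
#' region size; the all-absent tally and the detection threshold are written
#' as comment headers.
#'
#' @param partition a [VennPartition-class].
#' @param path output TSV path.
#' @param threshold detection threshold recorded in the header (optional).
#' @return Invisibly, the path.
#' @export
writeVennTsv <- function(partition, path, threshold = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(threshold))
    writeLines(sprintf("# presence threshold: count >= %s", threshold), con)
  writeLines(sprintf("# transcripts absent in all tissues: %d",
                     absentCount(partition)), con)
  writeLines("region\tcount", con)
  rc <- regionCounts(partition)
  writeLines(sprintf("%s\t%d", names(rc), rc), con)
  invisible(path)
}
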