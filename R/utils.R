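# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.asDNAStringSet <- function(x, what = "sequences") {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "seq1"
    return(out)
  }
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(out)))
      names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  stop(what, " must be a DNAStringSet, DNAString or character vector",
       call. = FALSE)
}

.checkAlphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stop("sequence(s) contain characters outside the ACGTN alphabet: ",
         paste(utils::head(names(seqs)[bad], 3L), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# Sample a random DNA string of length n at a given GC content.
.randomDna <- function(n, gc = 0.4) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Merge 1-based closed intervals given as a 2-column matrix; returns matrix.
.mergeIntervals <- function(starts, ends) {
  if (length(starts) == 0L)
    return(cbind(start = integer(), end = integer()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
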