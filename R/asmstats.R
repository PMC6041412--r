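#' Nx and expression-weighted ExNy assembly statistics
#'
#' `contigNx` computes the classical Nx statistic: the length of the contig
#' at which the cumulative sum of descending-sorted lengths first reaches at
#' least x% of the total assembly length. `exNx` computes the
#' expression-weighted variant (e.g. E90N50): contigs are ranked by
#' expression, the smallest prefix accounting for at least `e`% of total
#' expression is taken, and Nx is computed over that subset's lengths. Ties
#' in the expression ranking are broken by length (descending) then by
#' identifier (ascending) for determinism; rescaling all expression values by
#' a positive constant leaves the result unchanged.
#'
#' @param lengths contig lengths: a named numeric vector, a
#'   [Biostrings::DNAStringSet] (widths are used) or an unnamed numeric
#'   vector.
#' @param x percentage in (0, 100].
#' @param expression named non-negative numeric vector of expression values
#'   (counts or TPM; unit-free). Names must cover the same contigs as
#'   `lengths`; with unnamed inputs of equal size, positional matching is
#'   used.
#' @param e expression percentage in (0, 100] defining the subset.
#' @return The Nx (or ExNy) length in nt.
#' @examples
#' contigNx(c(1, 2, 3, 4, 5), 50)   # 4
#' contigNx(c(1, 2, 3, 4, 5), 90)   # 2
#' exNx(c(A = 1000, B = 500, C = 100), c(A = 90, B = 9, C = 1), e = 90)
#' @export
contigNx <- function(lengths, x = 50) {
  lengths <- .asLengths(lengths)
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 100)
    stop("x must be a percentage in (0, 100]", call. = FALSE)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= x / 100 * sum(s))[1L]
  s[i]
}

#' @rdname contigNx
#' @export
exNx <- function(lengths, expression, e = 90, x = 50) {
  lengths <- .asLengths(lengths)
  if (!is.numeric(e) || length(e) != 1L || e <= 0 || e > 100)
    stop("e must be a percentage in (0, 100]", call. = FALSE)
  if (is.null(names(expression))) {
    if (length(expression) != length(lengths) || is.null(names(lengths))) {
      if (length(expression) != length(lengths))
        stop("unnamed expression must match lengths positionally",
             call. = FALSE)
      names(lengths) <- names(expression) <- sprintf("c%d",
                                                     seq_along(lengths))
    } else names(expression) <- names(lengths)
  }
  if (is.null(names(lengths)))
    stop("lengths must be named when expression is named", call. = FALSE)
  miss <- setdiff(names(expression), names(lengths))
  if (length(miss))
    stop("expression ids absent from length set: ",
         paste(utils::head(miss, 3L), collapse = ", "), call. = FALSE)
  if (any(expression < 0)) stop("negative expression value", call. = FALSE)
  tot <- sum(expression)
  if (tot <= 0) stop("total expression must be positive", call. = FALSE)
  len <- lengths[names(expression)]
  o <- order(-expression, -len, names(expression))
  n <- which(cumsum(expression[o]) >= e / 100 * tot)[1L]
  contigNx(len[o][seq_len(n)], x)
}

#' Basic assembly summary
#'
#' Contig count, total size, mean/median length and the Nx curve for
#' x = 10, 20, ..., 90.
#'
#' @param contigs a `DNAStringSet`, or a (named) numeric vector of lengths.
#' @return A list with elements `count`, `total_bp`, `mean_length`,
#'   `median_length` and `nx` (data.frame with columns `x`, `nx`).
#' @export
assemblySummary <- function(contigs) {
  lengths <- .asLengths(contigs)
  if (!length(lengths)) stop("empty assembly", call. = FALSE)
  xs <- seq(10, 90, by = 10)
  list(count = length(lengths),
       total_bp = sum(lengths),
       mean_length = mean(lengths),
       median_length = stats::median(lengths),
       nx = data.frame(x = xs,
                       nx = vapply(xs, function(x) contigNx(lengths, x),
                                   numeric(1L))))
}

.asLengths <- function(x) {
  if (is(x, "XStringSet")) {
    out <- Biostrings::width(x)
    names(out) <- names(x)
    x <- out
  }
  if (!is.numeric(x))
    stop("lengths must be numeric or an XStringSet", call. = FALSE)
  if (length(x) && any(x < 1))
    stop("contig lengths must be positive", call. = FALSE)
  x
}
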