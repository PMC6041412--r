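#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.CLEANUP_STAGES <- c("adapter_clip", "contamination", "length_filter")
.REMOVAL_REASONS <- c("ADAPTER_CLIP_TOO_SHORT", "BACTERIAL", "TOO_SHORT")
.TRIAGE_LABELS <- c("PLANT_REFERENCE", "NO_HIT_KEPT", "NONBACTERIAL_KEPT",
                    "BACTERIAL_REMOVED")

#' CleanupReport: per-stage accounting of post-assembly cleanup
#'
#' Records, for the three cleanup stages (contig adapter clipping,
#' contamination triage, final length filter), the number of contigs entering,
#' removed and surviving, plus the per-contig removal reason and per-contig
#' clipping detail. The validity method enforces exact conservation:
#' `n_out == n_in - n_removed` at every stage, consecutive stages chain, and
#' the removals table reconciles with the stage counts.
#'
#' @slot stages data.frame with columns `stage`, `n_in`, `n_removed`, `n_out`.
#' @slot removals data.frame with columns `contig_id`, `stage`, `reason`.
#' @slot clips data.frame with columns `contig_id`, `n_spans`,
#'   `bases_removed`, `new_length` (one row per clipped contig).
#' @slot triage data.frame with columns `contig_id`, `label`, `subject_id`
#'   (the supporting best hit, `NA` when none).
#'
#' @seealso [runCleanup()], [stageCounts()], [removalReasons()]
#' @export
setClass("CleanupReport",
  representation(stages = "data.frame", removals = "data.frame",
                 clips = "data.frame", triage = "data.frame"))

setValidity("CleanupReport", function(object) {
  st <- object@stages
  msg <- character()
  need <- c("stage", "n_in", "n_removed", "n_out")
  if (!all(need %in% names(st)))
    return(paste("stages must have columns", paste(need, collapse = ", ")))
  if (any(st$n_out != st$n_in - st$n_removed))
    msg <- c(msg, "stage counts do not satisfy n_out == n_in - n_removed")
  if (nrow(st) > 1L && any(st$n_in[-1L] != st$n_out[-nrow(st)]))
    msg <- c(msg, "consecutive stages do not chain (n_in != previous n_out)")
  if (nrow(object@removals)) {
    if (!all(object@removals$reason %in% .REMOVAL_REASONS))
      msg <- c(msg, "unknown removal reason")
    tab <- table(factor(object@removals$stage, levels = st$stage))
    if (any(as.integer(tab) != st$n_removed))
      msg <- c(msg, "removals table does not reconcile with stage counts")
  } else if (sum(st$n_removed) != 0L) {
    msg <- c(msg, "stage counts report removals but removals table is empty")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' VennPartition: region sizes of a tissue presence/absence set system
#'
#' For k tissues there are `2^k - 1` non-empty tissue subsets; each transcript
#' detected in at least one tissue falls in exactly one region (the subset of
#' tissues it is present in). Transcripts absent everywhere are counted
#' separately in `nAbsent`.
#'
#' @slot tissues ordered tissue labels.
#' @slot regions named integer vector of length `2^k - 1`; names are the
#'   member tissue labels joined by `"+"` in tissue order.
#' @slot nAbsent number of transcripts with no presence call in any tissue.
#'
#' @seealso [vennPartition()], [regionCounts()], [tissueSpecificCounts()]
#' @export
setClass("VennPartition",
  representation(tissues = "character", regions = "integer",
                 nAbsent = "integer"))

setValidity("VennPartition", function(object) {
  k <- length(object@tissues)
  if (k < 1L) return("at least one tissue required")
  if (length(object@regions) != 2L^k - 1L)
    return(sprintf("expected %d regions for %d tissues, got %d",
                   2L^k - 1L, k, length(object@regions)))
  if (is.null(names(object@regions)) || anyNA(names(object@regions)))
    return("regions must be named by their tissue subsets")
  if (any(object@regions < 0L) || object@nAbsent < 0L)
    return("region counts must be non-negative")
  TRUE
})

#' FixtureManifest: ground truth for a synthetic fixture
#'
#' Every generator in the synthetic-fixture family returns, alongside its
#' artifacts, a manifest holding the seed, the generation parameters and a
#' truth table so that downstream stages can be verified by round-trip against
#' the planted features. The same seed and parameters always reproduce
#' byte-identical artifacts and an identical manifest.
#'
#' @slot seed integer seed the fixture was generated under.
#' @slot kind short label of the generator (e.g. `"contigs"`, `"orfs"`).
#' @slot truth data.frame of planted features, one row per feature.
#' @slot params list of the generation parameters.
#'
#' @seealso [makeContigs()], [plantAdapters()], [plantOrfs()]
#' @export
setClass("FixtureManifest",
  representation(seed = "integer", kind = "character", truth = "data.frame",
                 params = "list"))

setValidity("FixtureManifest", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single non-missing integer")
  if (length(object@kind) != 1L) return("kind must be a single string")
  TRUE
})

setMethod("show", "CleanupReport", function(object) {
  cat("CleanupReport\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-14s in %6d  removed %5d  out %6d\n",
                st$stage[i], st$n_in[i], st$n_removed[i], st$n_out[i]))
  if (nrow(object@removals)) {
    tab <- table(object@removals$reason)
    cat("  reasons:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
})

setMethod("show", "VennPartition", function(object) {
  k <- length(object@tissues)
  cat(sprintf("VennPartition over %d tissues (%s): %d regions, %d absent\n",
              k, paste(object@tissues, collapse = ", "),
              length(object@regions), object@nAbsent))
  nz <- object@regions[object@regions > 0L]
  if (length(nz)) {
    nz <- sort(nz, decreasing = TRUE)
    show_n <- utils::head(nz, 8L)
    cat("  top regions:",
        paste(sprintf("%s=%d", names(show_n), show_n), collapse = ", "), "\n")
  }
})

setMethod("show", "FixtureManifest", function(object) {
  cat(sprintf("FixtureManifest <%s> seed=%d, %d truth records\n",
              object@kind, object@seed, nrow(object@truth)))
})

#' Accessors for report and partition objects
#'
#' `stageCounts` returns the per-stage in/removed/out table of a
#' [CleanupReport-class]; `removalReasons` its per-contig removal table;
#' `triageLabels` its per-contig contamination labels. `regionCounts` returns
#' the named region-size vector of a [VennPartition-class], `tissueLabels` its
#' tissue order and `absentCount` the number of all-absent transcripts.
#' `truthRecords` and `fixtureSeed` access a [FixtureManifest-class].
#'
#' @param x a `CleanupReport`, `VennPartition` or `FixtureManifest`.
#' @return A data.frame, named integer vector, character vector or scalar,
#'   depending on the accessor.
#' @name accessors
#' @aliases stageCounts removalReasons triageLabels regionCounts tissueLabels
#'   absentCount truthRecords fixtureSeed
NULL

#' @rdname accessors
#' @export
stageCounts <- function(x) { stopifnot(is(x, "CleanupReport")); x@stages }

#' @rdname accessors
#' @export
removalReasons <- function(x) { stopifnot(is(x, "CleanupReport")); x@removals }

#' @rdname accessors
#' @export
triageLabels <- function(x) { stopifnot(is(x, "CleanupReport")); x@triage }

#' @rdname accessors
#' @export
regionCounts <- function(x) { stopifnot(is(x, "VennPartition")); x@regions }

#' @rdname accessors
#' @export
tissueLabels <- function(x) { stopifnot(is(x, "VennPartition")); x@tissues }

#' @rdname accessors
#' @export
absentCount <- function(x) { stopifnot(is(x, "VennPartition")); x@nAbsent }

#' @rdname accessors
#' @export
truthRecords <- function(x) { stopifnot(is(x, "FixtureManifest")); x@truth }

#' @rdname accessors
#' @export
fixtureSeed <- function(x) { stopifnot(is(x, "FixtureManifest")); x@seed }
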