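#' Pipeline configuration
#'
#' Collects every stage default in one validated object so deviations from
#' the canonical values are visible in the consolidated report header. Paths
#' may be `NULL`; stages whose inputs are missing are skipped by
#' [runPipeline()].
#'
#' @param contigsFasta path to the assembled contigs (required for the
#'   cleanup/stats/ORF stages).
#' @param reads1,reads2 paired FASTQ paths for the trimming stage.
#' @param adaptersFasta adapter FASTA used for read clipping and contig
#'   scanning (`NULL` uses the built-in TruSeq pair).
#' @param refHits,ntHits,taxonomy contamination-triage inputs (paths or
#'   in-memory objects).
#' @param swissprotHits protein-database hit table for representative
#'   selection (path or data.frame; query ids are candidate `orf_key`s).
#' @param forwardHits,reverseHits RBH hit tables for annotation transfer.
#' @param functionTable reference functional table (TSV with header).
#' @param counts tissue count matrix (TSV path or matrix).
#' @param outDir output directory.
#' @param window,meanQ,readMinLen read-trimming rule (defaults 4, 15, 100).
#' @param clipMinLen,finalMinLen contig cutoffs (defaults 200, 400).
#' @param refEvalue,refAlnLen,refIdentity triage thresholds (1e-5, 100, 80).
#' @param scanWord,scanEvalue contig adapter-scan parameters (4, 0.01).
#' @param keepAa,keepEvalue representative keep rule (100 aa, 1e-10).
#' @param presenceThreshold detection threshold for the Venn partition (1).
#' @param minOrfAa ORF enumeration floor in aa (30).
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(contigsFasta = NULL, reads1 = NULL, reads2 = NULL,
                           adaptersFasta = NULL, refHits = NULL,
                           ntHits = NULL, taxonomy = NULL,
                           swissprotHits = NULL, forwardHits = NULL,
                           reverseHits = NULL, functionTable = NULL,
                           counts = NULL, outDir = "txpolish_out",
                           window = 4L, meanQ = 15, readMinLen = 100L,
                           clipMinLen = 200L, finalMinLen = 400L,
                           refEvalue = 1e-5, refAlnLen = 100,
                           refIdentity = 80, scanWord = 4L,
                           scanEvalue = 0.01, keepAa = 100L,
                           keepEvalue = 1e-10, presenceThreshold = 1,
                           minOrfAa = 30L, seed = 1L) {
  cfg <- list(contigsFasta = contigsFasta, reads1 = reads1, reads2 = reads2,
              adaptersFasta = adaptersFasta, refHits = refHits,
              ntHits = ntHits, taxonomy = taxonomy,
              swissprotHits = swissprotHits, forwardHits = forwardHits,
              reverseHits = reverseHits, functionTable = functionTable,
              counts = counts, outDir = outDir, window = window,
              meanQ = meanQ, readMinLen = readMinLen,
              clipMinLen = clipMinLen, finalMinLen = finalMinLen,
              refEvalue = refEvalue, refAlnLen = refAlnLen,
              refIdentity = refIdentity, scanWord = scanWord,
              scanEvalue = scanEvalue, keepAa = keepAa,
              keepEvalue = keepEvalue,
              presenceThreshold = presenceThreshold, minOrfAa = minOrfAa,
              seed = seed)
  pos <- c("window", "meanQ", "refEvalue", "refAlnLen", "refIdentity",
           "scanWord", "scanEvalue", "keepAa", "keepEvalue")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number",
           call. = FALSE)
  # length cutoffs may be 0 (filter disabled), never negative
  for (f in c("readMinLen", "clipMinLen", "finalMinLen",
              "presenceThreshold"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop("config field '", f, "' must be a non-negative number",
           call. = FALSE)
  for (f in c("reads1", "reads2", "refHits", "ntHits", "taxonomy",
              "swissprotHits", "forwardHits", "reverseHits",
              "functionTable", "counts", "contigsFasta", "adaptersFasta"))
    if (is.character(cfg[[f]]) && length(cfg[[f]]) == 1L &&
        !file.exists(cfg[[f]]))
      stop("input file for '", f, "' does not exist: ", cfg[[f]],
           call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  vals <- unclass(config)
  yaml::write_yaml(vals[!vapply(vals, is.null, logical(1L))], path)
  invisible(path)
}

#' Run the post-assembly pipeline end to end
#'
#' Chains read trimming, contig cleanup, assembly statistics, representative
#' peptide selection, annotation transfer and tissue Venn partitioning on
#' whatever inputs the configuration provides, writing every stage artifact
#' plus a consolidated JSON report under `outDir`. With identical inputs and
#' configuration the run is fully deterministic (no stage draws random
#' numbers), so repeated runs produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()] (or a YAML path).
#' @return Invisibly, the consolidated report list (also written as
#'   `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  cfgRec <- unclass(config)[!vapply(unclass(config), is.null, logical(1L))]
  cfgRec$outDir <- NULL  # the report sits in outDir; recording the path
                         # would break byte-identity of re-runs elsewhere
  report <- list(schema_version = "1.0", config = cfgRec)

  adapters <- if (!is.null(config$adaptersFasta))
    Biostrings::readDNAStringSet(config$adaptersFasta) else
      illuminaAdapters()

  ## trim
  if (!is.null(config$reads1) && !is.null(config$reads2)) {
    rd <- readPairedFastq(config$reads1, config$reads2)
    tr <- trimPairs(rd$r1, rd$r2, adapters = adapters,
                    window = config$window, meanQ = config$meanQ,
                    minLen = config$readMinLen)
    writePairedFastq(tr$r1, tr$r2, out("trimmed_1.fastq"),
                     out("trimmed_2.fastq"))
    report$trim <- tr$stats
  }

  ## cleanup
  contigs <- NULL
  if (!is.null(config$contigsFasta)) {
    contigs <- Biostrings::readDNAStringSet(config$contigsFasta)
    refHits <- .maybeHits(config$refHits)
    ntHits <- .maybeHits(config$ntHits)
    taxonomy <- if (is.character(config$taxonomy) &&
                    length(config$taxonomy) == 1L)
      readTaxonomyMap(config$taxonomy) else config$taxonomy
    cl <- runCleanup(contigs, adapters = adapters, refHits = refHits,
                     ntHits = ntHits, taxonomy = taxonomy,
                     clipMinLen = config$clipMinLen,
                     finalMinLen = config$finalMinLen,
                     wordSize = config$scanWord,
                     scanEvalue = config$scanEvalue,
                     refEvalue = config$refEvalue,
                     refAlnLen = config$refAlnLen,
                     refIdentity = config$refIdentity)
    contigs <- cl$contigs
    Biostrings::writeXStringSet(contigs, out("cleaned.fasta"))
    report$cleanup <- list(
      stages = cl$report@stages,
      removal_reasons = as.list(table(cl$report@removals$reason)))

    ## stats
    summ <- assemblySummary(contigs)
    report$stats <- summ[c("count", "total_bp", "mean_length",
                           "median_length")]
    report$stats$n50 <- contigNx(contigs, 50)
    utils::write.table(summ$nx, out("nx_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ## orfs
    cands <- findOrfs(contigs, minAa = config$minOrfAa)
    spHits <- .maybeHits(config$swissprotHits)
    reps <- selectRepresentatives(cands, hits = spHits,
                                  evalueKeep = config$keepEvalue,
                                  minKeepAa = config$keepAa)
    if (!is.null(reps)) {
      writeOrfOutputs(reps, out("peptides.fasta"), out("cds.gff3"))
      utils::write.table(
        reps[c("contig_id", "orf_key", "selection_reason", "kept",
               "keep_reason", "length_aa")],
        out("selection_report.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      report$orfs <- list(contigs_with_candidates = length(unique(
                            cands$contig_id)),
                          representatives = nrow(reps),
                          kept = sum(reps$kept))
    }
  }

  ## annotation transfer
  if (!is.null(config$forwardHits) && !is.null(config$reverseHits)) {
    rbh <- reciprocalBestHits(.maybeHits(config$forwardHits),
                              .maybeHits(config$reverseHits))
    anno <- if (!is.null(config$functionTable))
      transferAnnotation(rbh, config$functionTable) else rbh
    utils::write.table(anno, out("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$annotation <- list(rbh_pairs = nrow(rbh))
  }

  ## tissue partition
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts)) readCountMatrix(config$counts)
              else config$counts
    vp <- vennPartition(counts, threshold = config$presenceThreshold)
    writeVennTsv(vp, out("venn.tsv"), threshold = config$presenceThreshold)
    ts <- tissueSpecificCounts(vp)
    report$venn <- list(tissues = tissueLabels(vp),
                        presence_threshold = config$presenceThreshold,
                        transcripts_detected = sum(regionCounts(vp)),
                        absent = absentCount(vp),
                        tissue_specific = as.list(ts$exclusive),
                        min = ts$min, max = ts$max)
  }

  .writeJson(report, out("report.json"))
  invisible(report)
}

.maybeHits <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) readHitTable(x) else x
}
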