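# Builds one complete synthetic input set on disk for the pipeline tests.
mkPipelineInputs <- function(dir, seed = 11L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ad <- illuminaAdapters()

  rp <- makeReadPairs(120, readLen = 150, qualityProfile = "step",
                      adapter = as.character(ad[[1]]), adapterRate = 0.2,
                      seed = seed)
  writePairedFastq(rp$r1, rp$r2, file.path(dir, "r1.fastq"),
                   file.path(dir, "r2.fastq"))

  fx <- makeCleanupFixture(nContigs = 40, seed = seed + 1L)
  po <- plantOrfs(5, peptideLengths = c(110, 250), seed = seed + 3L)
  Biostrings::writeXStringSet(c(fx$contigs, po$contigs),
                              file.path(dir, "contigs.fasta"))
  writeHitTable(fx$refHits, file.path(dir, "ref_hits.tsv"))
  writeHitTable(fx$ntHits, file.path(dir, "nt_hits.tsv"))
  writeTaxonomyMap(fx$taxonomy, file.path(dir, "taxonomy.tsv"))

  mx <- makeCountMatrix(c("leaf", "stem", "root"), 50,
                        c(leaf = 6, stem = 3, root = 10), nAbsent = 4,
                        seed = seed + 2L)
  writeCountMatrix(mx$counts, file.path(dir, "counts.tsv"))

  fwd <- rbind(hitRow("p1", "AT1", 300), hitRow("p2", "AT2", 250))
  rev <- rbind(hitRow("AT1", "p1", 290), hitRow("AT2", "p9", 240))
  writeHitTable(fwd, file.path(dir, "fwd.tsv"))
  writeHitTable(rev, file.path(dir, "rev.tsv"))
  utils::write.table(
    data.frame(gene = c("AT1", "AT2"), description = c("kinase", "unknown")),
    file.path(dir, "functions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  dir
}

mkPipelineConfig <- function(inDir, outDir) {
  pipelineConfig(
    contigsFasta = file.path(inDir, "contigs.fasta"),
    reads1 = file.path(inDir, "r1.fastq"),
    reads2 = file.path(inDir, "r2.fastq"),
    refHits = file.path(inDir, "ref_hits.tsv"),
    ntHits = file.path(inDir, "nt_hits.tsv"),
    taxonomy = file.path(inDir, "taxonomy.tsv"),
    forwardHits = file.path(inDir, "fwd.tsv"),
    reverseHits = file.path(inDir, "rev.tsv"),
    functionTable = file.path(inDir, "functions.tsv"),
    counts = file.path(inDir, "counts.tsv"),
    outDir = outDir)
}
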