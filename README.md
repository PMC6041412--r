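# txpolish

Post-assembly polishing, annotation transfer and expression partitioning
for de novo transcriptomes.

Large external tools (assembler, aligners, BUSCO) dominate a de novo
transcriptome project, but the numbers a study actually reports are shaped
by a chain of small, exactly specified computations in between: how reads
are trimmed, which contigs are discarded as adapter chimeras or bacterial
contamination, which of a contig's many ORFs becomes *the* peptide, which
cross-species hits count as orthologs, and how transcripts are split
across tissue sets. `txpolish` implements that chain as a deterministic,
testable R package in Bioconductor S4 style, together with a seeded
synthetic-data generator that plants ground truth for every stage.

## The rules, briefly

- **Read trimming** — sliding window (width 4, mean Q ≥ 15, cut before
  the first failing window), simple-mode adapter clipping (16-mer seed,
  ≤ 2 mismatches, score +0.6/−3.0, clip at score ≥ 10), 100-nt pair floor
  with orphan dropping.
- **Contig cleanup** — word-4 seed-and-extend adapter scan filtered at
  Karlin–Altschul expectation ≤ 0.01 (λ = 1.28, K = 0.46); clip keeps the
  longest remaining segment if ≥ 200 nt; two-stage contamination triage
  (reference pass: e < 1e−5 ∧ alignment > 100 ∧ identity > 80%; otherwise
  best nucleotide-database hit decides, bacterial ⇒ removed, no hit ⇒
  kept); final ≥ 400 nt filter.
- **Statistics** — Nx by cumulative sum over descending lengths; ExNy
  restricted to the top-expressed contigs covering y% of expression.
- **Peptides** — six-frame ORF enumeration (per stop-to-stop segment: the
  longest Met ORF plus, where applicable, the full open segment as a
  5′-partial); representative = longest Met ORF unless a significant hit
  (e < 1e−10) promotes the best-scoring candidate; kept iff > 100 aa or
  significant hit.
- **Orthology** — reciprocal best hits with conservative tie voiding.
- **Tissues** — presence at count ≥ 1 (stated, adjustable), exact Venn
  partition over all `2^k − 1` tissue subsets.

All intervals are 1-based closed (IRanges convention). See the methods
vignette (`vignettes/txpolish-methods.Rmd`) for the full definitions and
the reasoning behind each parameter.

## Worked example

Generate a 200-contig fixture with planted adapters and contamination,
clean it, and compare against the generator's manifest:

```r
library(txpolish)

fx <- makeCleanupFixture(nContigs = 200, seed = 1)
cl <- runCleanup(fx$contigs, adapters = fx$adapters,
                 refHits = fx$refHits, ntHits = fx$ntHits,
                 taxonomy = fx$taxonomy)
stageCounts(cl$report)
#>           stage n_in n_removed n_out
#> 1  adapter_clip  200         0   200
#> 2 contamination  200        40   160
#> 3 length_filter  160         6   154

nrow(cl$report@clips)        # contigs clipped (all survivors here)
#> [1] 21
contigNx(cl$contigs, 50)
#> [1] 2065
```

Every per-contig fate matches the manifest truth:

```r
tr <- truthRecords(fx$manifest)
fate <- setNames(rep("KEPT", nrow(tr)), tr$contig_id)
rm <- removalReasons(cl$report)
fate[rm$contig_id] <- rm$reason
mean(fate[tr$contig_id] == tr$expected_fate)
#> [1] 1
```

Planted CDS regions are recovered exactly by ORF selection:

```r
po <- plantOrfs(20, peptideLengths = c(110, 250), seed = 2)
reps <- selectRepresentatives(findOrfs(po$contigs))
table(reps$keep_reason)
#>
#> LENGTH_GT_100
#>            20
ptr <- truthRecords(po$manifest)
m <- match(ptr$contig_id, reps$contig_id)
mean(reps$cds_start[m] == ptr$cds_start & reps$cds_end[m] == ptr$cds_end)
#> [1] 1
```

Designed count matrices carry their true Venn partition:

```r
mx <- makeCountMatrix(c("leaf", "stem", "root"), 100,
                      c(leaf = 12, stem = 5, root = 20), nAbsent = 3,
                      seed = 3)
regionCounts(vennPartition(mx$counts))
#>           leaf           stem      leaf+stem           root      leaf+root
#>             12              5              0             20              0
#>      stem+root leaf+stem+root
#>              0             60
absentCount(vennPartition(mx$counts))
#> [1] 3
```

An end-to-end run over files on disk is one call:

```r
cfg <- pipelineConfig(contigsFasta = "contigs.fasta",
                      reads1 = "r1.fastq", reads2 = "r2.fastq",
                      refHits = "ref_hits.tsv", ntHits = "nt_hits.tsv",
                      taxonomy = "taxonomy.tsv", counts = "counts.tsv",
                      outDir = "out")
runPipeline(cfg)   # trimmed FASTQs, cleaned.fasta, peptides.fasta,
                   # cds.gff3, nx_curve.tsv, venn.tsv, report.json
```

Repeat runs are byte-identical. A thin shell front end with the same
stages lives at `inst/scripts/txpolish.R`.

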