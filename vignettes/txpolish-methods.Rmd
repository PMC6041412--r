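---
title: "Methods: post-assembly polishing of de novo transcriptomes"
author: "txpolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly polishing of de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

A de novo transcriptome project that starts from raw paired-end RNA-seq
reads and ends with an annotated, tissue-profiled peptide set rests on a
chain of small, exactly specified computations between the big external
tools (assembler, aligners, BUSCO). `txpolish` implements that chain as a
reusable, deterministic package:

1. read quality trimming and adapter clipping,
2. contig-level adapter scan/clip, contamination triage, length filtering,
3. assembly statistics (Nx and expression-weighted ExNy),
4. six-frame ORF enumeration and representative-peptide selection,
5. reciprocal-best-hit (RBH) annotation transfer,
6. tissue presence/absence Venn partitioning,

plus a seeded synthetic-data generator (`makeReadPairs()`,
`makeCleanupFixture()`, `plantOrfs()`, `makeCountMatrix()`, ...) that
plants ground truth for every stage, so each rule is testable against an
independently derived answer.

Every interval in the package is **1-based and closed** on both ends, the
Bioconductor/IRanges convention used by all coordinate carriers here.

# Read trimming

`slidingWindowTrim()` implements the classic sliding-window rule with
window width 4 and mean-quality threshold Q15: windows start at every
position; a window reaching past the read end is truncated to the
remaining bases (so trailing low-quality bases are still caught); the read
is cut immediately before the start of the first window whose mean quality
is strictly below the threshold. `trimPoint()` exposes the per-read rule.

`clipAdapter()` emulates "simple-mode" adapter clipping: the adapter's
first 16-mer is located in the read allowing up to 2 mismatches; from each
seed the full adapter prefix is scored against the read (match +0.6,
mismatch −3.0) and the read is cut at the alignment start when the best
score reaches the simple-clip threshold of 10. A consequence worth knowing
when interpreting results: a perfect k-base terminal fragment scores
0.6·k, so fragments of 16 bases or fewer can never be clipped — they are
left for the quality trimmer.

`filterPairs()` enforces the 100-nt post-trim length floor *per pair*:
when either mate falls short the whole pair is dropped, never leaving
orphaned singletons. `trimPairs()` chains clip → window trim → pair
filter and reports read/base accounting.

# Contig cleanup

`scanAdapters()` finds residual adapter in assembled contigs with a
word-seeded ungapped alignment at word size 4: every exact 4-mer shared
between adapter and contig seeds a diagonal; on each seeded diagonal the
maximum-scoring contiguous segment (match +1, mismatch −2; leftmost on
ties) is found by a single Kadane pass; a segment of score *S* is reported
when its Karlin–Altschul expectation `K·m·n·exp(−λS)` is at most 0.01,
with the standard ungapped +1/−2 parameters λ = 1.28, K = 0.46.
Word size 4 with a 0.01 expectation cut is deliberately permissive — the
point of a vector scan is sensitivity to short residual fragments.

`clipContig()` removes the detected spans and keeps the longest remaining
segment (leftmost on ties); the contig is discarded when that segment is
shorter than 200 nt, the assembler's own report floor. A segment of
exactly 200 nt survives.

`classifyContamination()` is a two-stage triage. Stage one accepts a
contig as plant-derived when any hit against the related reference genome
simultaneously satisfies e-value < 1e−5, alignment length > 100 and
identity > 80% (all strict). Contigs failing stage one are judged by their
single best hit in a general nucleotide database — maximum bitscore, ties
broken by minimum e-value, then maximum alignment length, then subject id
— and removed only when that best hit maps to the bacterial taxonomy
group; no hit at all keeps the contig (absence of evidence is not treated
as contamination). A subject id missing from the taxonomy map is raised as
a data error rather than silently kept.

`lengthFilter()` applies the final 400-nt floor (inclusive), and
`runCleanup()` chains the three stages into a `CleanupReport` whose
validity method enforces exact count reconciliation at every stage.

# Assembly statistics

`contigNx(lengths, x)` is the standard definition: sort lengths
descending, return the length at which the cumulative sum first reaches
x% of the total. `exNx(lengths, expression, e, x)` restricts the input to
the most-expressed contigs that together account for e% of total
expression (ties: longer contig first, then id) and computes Nx inside
that subset; it reduces to plain Nx at e = 100 with uniform expression and
is invariant to rescaling the expression vector, both properties verified
in the acceptance suite.

# ORF enumeration and representative peptides

`findOrfs()` translates all six frames with the standard genetic code
(`translateFrame()`; codons containing ambiguous bases become `X`, and no
initiation-codon special-casing is applied, so TTG/CTG never translate as
M). For each maximal stop-to-stop segment two candidates are derived: the
longest Met-initiated ORF in the segment, and — when the segment does not
begin with Met — the full open segment as a 5'-partial candidate.
Coordinates are forward-strand, 1-based inclusive, and include the
terminating stop codon when present.

`selectRepresentatives()` picks one peptide per contig: by default the
longest Met-initiated candidate (ties: smaller CDS start; no Met →
longest overall), reason `LONGEST_MET`. A significant protein-database
hit (e < 1e−10) overrides length: the highest-bitscore candidate wins,
reason `HIT_SCORE`. The winner is **kept** when its peptide exceeds 100 aa
(`LENGTH_GT_100`, strict) or it has a significant hit (`HIT_E_LT_1e10`;
this reason takes precedence when both hold); otherwise it is recorded
with `NOT_KEPT`. `writeOrfOutputs()` emits the kept peptides as FASTA
(ids `<contig>.p1`) and the CDS intervals as GFF3.

# Annotation transfer

`bestHits()` collapses multiple HSPs per query/subject pair to the best
one, then assigns each query its maximum-bitscore subject; queries whose
top bitscore is shared by two *different* subjects are voided — a
deterministic, conservative tie policy. `reciprocalBestHits()` pairs
(q, s) when each is the other's best hit; `transferAnnotation()` joins the
pairs to a reference functional table, leaving blank fields (with a
warning) for subjects missing from the table.

# Tissue partitioning

`presenceMatrix()` calls a transcript present in a tissue when its count
reaches the detection threshold (default: 1 read — a stated choice
recorded in the output, not a hidden constant). `vennPartition()` assigns
every detected transcript to exactly one of the `2^k − 1` tissue-subset
regions and tallies all regions plus the all-absent count; the
`VennPartition` validity method guarantees that region sums plus absent
always equal the transcript total.

# The synthetic generator

`synthio`-style generators make every stage testable offline:

- `makeReadPairs()` plants known trim points (step quality profiles) and
  terminal adapter fragments, recording truth computed by an independent
  naive per-read scan.
- `makeCleanupFixture()` composes contig generation, contamination
  planting and adapter planting, then derives each contig's expected fate
  (`KEPT`, `ADAPTER_CLIP_TOO_SHORT`, `BACTERIAL`, `TOO_SHORT`) and
  expected surviving length from first principles, using a separate naive
  adapter scanner rather than the code under test.
- `plantOrfs()` builds each contig around a single Met-initiated CDS with
  an in-frame guard stop just 5' of the start codon, and brute-force
  verifies at generation time that the planted ORF is the strictly longest
  Met ORF on the contig (resampling otherwise), so representative
  selection has a unique right answer.
- `makeCountMatrix()` designs a count matrix with exact tissue-exclusive
  and absent counts, returning the true `VennPartition` alongside.

Generator defaults are study conditions, not tuning knobs: read length
150, contig lengths 300–3000 at GC 0.4, adapter rate 10%, bacterial
fraction 20%, no-hit fraction 10%.

The generators emulate *decision structure*, not sequencer physics: no
quality-error coupling, no indels, no chimeras. They are sufficient for
verifying the rules above exactly, and nothing more is claimed.

# Worked example

```{r, eval = FALSE}
library(txpolish)

fx <- makeCleanupFixture(nContigs = 200, seed = 1)
cl <- runCleanup(fx$contigs, adapters = fx$adapters,
                 refHits = fx$refHits, ntHits = fx$ntHits,
                 taxonomy = fx$taxonomy)
stageCounts(cl$report)
contigNx(cl$contigs, 50)

po <- plantOrfs(20, peptideLengths = c(110, 250), seed = 2)
reps <- selectRepresentatives(findOrfs(po$contigs))
table(reps$keep_reason)
```

# Reproducibility

All computation is deterministic given the inputs; generators take
explicit seeds and restore the caller's RNG state. The consolidated
pipeline (`runPipeline()`) writes byte-identical artifacts across repeat
runs, which the acceptance suite checks literally.
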