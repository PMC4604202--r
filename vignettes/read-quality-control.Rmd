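---
title: "Quality control of paired-end Illumina reads with ReadQC"
author: "ReadQC maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of paired-end Illumina reads with ReadQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReadQC)
```

## Scope and model

ReadQC implements the "quick QC" workflow used to triage raw Illumina
resequencing data before any alignment: per-sample read/base statistics,
sliding-window quality trimming of the mate pairs, statistics again on the
trimmed output, and — when an alignment-derived coverage track is available
— a breadth-of-coverage summary. The unit of work is the *sample* (a pair
of FASTQ files); a manifest of samples is processed in worker-sized
batches so hundreds of samples can be pushed through on a multicore
machine while each worker touches only one sample at a time.

Downstream stages that conventionally belong to external tools — alignment,
variant calling, depth computation from BAM — are deliberately out of
scope. The coverage module starts where `bedtools genomecov -bga` ends: a
zero-inclusive bedgraph.

## The statistics engine

A FASTQ record is exactly four lines (header, sequence, `+` separator,
quality); multi-line wrapped sequences are rejected because the fixed
record form is what makes single-pass streaming trivial and safe. Files
are read in bounded chunks (5,000 records by default) from a plain or
`gzfile` connection, so memory is independent of file size. True
one-record-at-a-time iteration would be pathologically slow in R; chunked
streaming preserves the contract that matters — bounded memory — and every
statistic is independent of the chunking because the accumulator is an
exact fold.

Per record the engine accumulates: reads, bases, Q20/Q30 bases, length
range and sum, A/C/G/T/N composition, raw and decoded quality ranges, and
the read-length histogram. Decisions worth recording:

* **Non-ACGT codes count as N.** IUPAC ambiguity codes (R, Y, ...) are rare
  in Illumina output and are uncalled for QC purposes; folding them into N
  keeps the composition a 5-way partition, so A+T+G+C+N always equals the
  base total.
* **GC denominator includes N.** `gc = 100·(G+C)/all bases`, so the GC, AT
  and N fractions sum to 100%.
* **Two quality ranges are reported**: the raw encoded character range
  (useful for spotting a wrong offset at a glance) and the decoded phred
  range. They are distinct metrics, not one.
* **Empty sets report `NA` ranges**, never a fabricated 0.
* **Counters are doubles.** R integers are 32-bit; a single HiSeq lane
  exceeds 2^31 bases.

Accumulators merge by summing additive fields and min/max-ing ranges;
`mergeStats()` is commutative and associative with `emptyStats()` as
identity, which is what lets per-worker passes combine into exactly the
single-pass answer (this is tested property-style over random splits).

Quality decoding subtracts the phred offset, 33 by default (HiSeq/MiSeq)
or 64 for GAIIx-era files. A character below the offset is an error, not a
clamp: it almost always means the wrong offset was chosen, and silently
producing negative scores would corrupt every downstream threshold.

## The trimmer

The window is `max(1, round(0.1·L))` bases for a read of length `L`. The
scan finds the first window whose mean phred reaches the threshold `q`
(its start is the 5′ cut), then the first later window whose mean drops
below `q` (the base before it is the 3′ cut; end of read if none). Two
numerical choices:

* Window means are never computed as floating-point averages; the
  comparison is `sum(window) ≥ q·w` in exact integer arithmetic, so
  results cannot depend on rounding of ties.
* Reads shorter than ten bases get a window of one base, i.e. per-base
  thresholding; the window never exceeds the read.

With `truncateAtN` on (the default, mirroring the common `-n` trimming
flag) the retained segment is further truncated before its first N, and
the read is discarded when the retained length falls below `minLen`.
Defaults `q = 30`, `minLen = 50` are the conventional values for 100 bp
resequencing data.

Pair routing is exhaustive: both mates survive → the pair is kept; exactly
one survives → it is routed to the singletons file (singletons are worth
keeping because aligners accept them as single-end input); neither → both
count as discarded. The accounting identity
`2·pairsIn = 2·pairsKept + singletons + readsDiscarded` is enforced by the
`TrimOutcome` validity method — it cannot be violated silently.

**Idempotence.** Re-trimming trimmed output is expected to change nothing,
and the test suite verifies this over the simulated-Illumina world. It is
worth recording that the property is not a theorem for this algorithm
family: trimming shortens the read, the window is recomputed from the new
length, and a smaller window can in principle expose a short low-quality
pocket that a larger window averaged away. That requires several-fold
quality swings inside the retained segment, which the plateau-plus-tail
profile of real (and simulated) Illumina data does not produce; with
per-base noise at σ ≈ 3 around a plateau of 38 we observed zero violations
in 5,000 reads. A pathological hand-built read could violate it.

## Coverage summaries

`parseBedgraph()` expects the 4-column, zero-inclusive dialect
(`-bga`): 0-based half-open intervals that tile the genome, zero-depth
intervals included. Parsing is strict — non-integer fields or
`start ≥ end` fail with the line number — because a silently mis-parsed
coverage track produces plausible-looking but wrong breadths.
Intervals become a `GRanges` (1-based closed, the Bioconductor
convention) with a `depth` column.

Breadth at threshold `t` is the percentage of genome positions with depth
at least `t`, at thresholds 1, 2, 5, 10 and 15 by default; mean depth is
averaged over *all* genome positions, zeros included — for a tiled `-bga`
track the two conventions coincide, and including zeros is the
interpretation under which "mean depth" answers the design question "did I
sequence enough". The genome size is user-supplied; when omitted it falls
back to the summed interval length, but only after `validateBgaCover()`
confirms the track actually tiles a genome (sorted, non-overlapping,
lengths summing to the stated size). Both quantities are checked exactly
against a per-base array-expansion oracle on random tiled genomes up to
10 kb.

## The batch pipeline

Samples are assigned in manifest order to consecutive batches of at most
`workers` samples; batches run sequentially, samples within a batch
concurrently (`parallel::mclapply`). Three contracts matter more than raw
speed:

* **Determinism**: results are collected in manifest order and all report
  numbers are formatted with fixed rules (counts as plain integers,
  averages and percentages to two decimals — stable choices since no
  canonical layout exists for such reports), so the report file is
  byte-identical whatever the worker count.
* **Isolation**: a failing sample (missing file, malformed record, wrong
  offset) yields a `FAILED` row carrying its error message; other samples
  are untouched.
* **Conservation**: per row, `after_bases + bases_removed = before_bases`
  and the pair/singleton identity hold exactly; the after-statistics are
  computed by re-reading the trimmed files, so these identities also
  verify that what was written is what was counted.

The interface is a manifest file plus function arguments (and a thin
`qc.R` command-line script); an interactive menu would add nothing
testable.

## The simulator and what a green test establishes

The fixture generator emulates a small-scale resequencing benchmark:
a uniform-composition reference at a chosen GC fraction; uniformly placed
fragments with normal insert sizes (default 300 ± 30 bp); 100 bp mates
read off the two fragment ends (mate 2 reverse-complemented); a pair count
of `round(coverage·refLen/(2·readLen))`, i.e. 10-fold coverage by
default. Per-base phred scores are drawn around a plateau of 38 decaying
linearly over the final 30% of the read to a mean of 22 — the 3′
degradation pattern the trimmer exists to remove — with σ = 3 and an N
substitution rate of 0.2%, typical of a healthy run. Everything is
reproducible from the seed alone, to the byte.

The simulator deliberately has **no substitution-error model and no indel
model**: the QC stack consumes qualities and base identities, never truth
alignments, so positional quality structure plus N injection exercises
every code path. Consequently a green suite establishes correctness of the
*metrics and algorithms*, not robustness to real-instrument artifacts
(adapter read-through, optical duplicates, tile effects) — none of which
quick QC claims to detect.

## Known limitations

* Interleaved FASTQ, FASTA input and SAM/BAM input are not supported.
* Quality-encoding is declared, never auto-detected; a wrong declaration
  is reported as an error on first offending record rather than guessed
  around.
* The trimmer matches the documented behaviour of the classic
  sliding-window tools in parameters and intent but is not a byte-level
  clone of any particular release; cross-version differences exist for
  reads shorter than the window and for the interaction of N truncation
  with the window scan (here: windows first, then N truncation).
* Per-position quality curves, adapter detection and duplication estimates
  are out of scope.
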