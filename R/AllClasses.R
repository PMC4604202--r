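#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.table
#' @importFrom parallel detectCores mclapply
NULL

.BASES <- c("A", "C", "G", "T", "N")

.checkOffset <- function(offset) {
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || !offset %in% c(33L, 64L))
    stop("phred offset must be 33 or 64", call. = FALSE)
  offset
}

#' FastqStream: a streaming handle on a FASTQ file
#'
#' A lightweight S4 handle around an open (possibly gzip) connection to a
#' 4-line-record FASTQ file. Records are pulled in bounded chunks with
#' [readRecords()], so memory use is independent of file size. Created by
#' [openFastqStream()]; close with `close()`.
#'
#' @slot path input file path.
#' @slot gzip whether the file is gzip-compressed.
#' @slot chunkSize default number of records per [readRecords()] call.
#' @slot state internal mutable state (connection, record cursor).
#' @export
setClass("FastqStream",
  representation(path = "character", gzip = "logical",
                 chunkSize = "integer", state = "environment"))

#' PairedFastqStream: synchronized streaming over two mate files
#'
#' Streams mate-1 and mate-2 FASTQ files in lockstep, verifying mate identity
#' pairwise (read IDs compared after stripping a trailing `/1`/`/2` or a
#' whitespace-delimited comment). Created by [openPairedFastqStream()].
#'
#' @slot r1,r2 the two underlying [FastqStream-class] handles.
#' @slot state internal mutable state (pair cursor).
#' @export
setClass("PairedFastqStream",
  representation(r1 = "FastqStream", r2 = "FastqStream", state = "environment"))

#' ReadSetStats: accumulated read/base-level statistics of a read set
#'
#' The metric accumulator of the statistics engine: total reads and bases,
#' Q20/Q30 base counts, read-length range and sum, per-base composition over
#' \{A,C,G,T,N\}, the range of decoded phred scores, the range of raw quality
#' characters, and the full read-length histogram. All counters are stored as
#' doubles (base counts on production lanes exceed the 32-bit integer range).
#' Range slots hold `NA` sentinels while the set is empty.
#'
#' Build with [computeStats()] or incrementally with [emptyStats()] /
#' [updateStats()]; combine per-file accumulators with [mergeStats()].
#'
#' @slot nReads,nBases,q20Bases,q30Bases,sumLen additive counters.
#' @slot minLen,maxLen read-length range (`NA` when empty).
#' @slot baseCounts named counts for A, C, G, T, N (non-ACGT codes count as N).
#' @slot minQ,maxQ decoded phred score range (`NA` when empty).
#' @slot minQualChar,maxQualChar raw encoded quality character range.
#' @slot lengthHist read counts named by read length.
#' @slot offset phred offset (33 or 64) used to decode qualities.
#' @export
setClass("ReadSetStats",
  representation(nReads = "numeric", nBases = "numeric",
                 q20Bases = "numeric", q30Bases = "numeric",
                 sumLen = "numeric", minLen = "numeric", maxLen = "numeric",
                 baseCounts = "numeric", minQ = "numeric", maxQ = "numeric",
                 minQualChar = "character", maxQualChar = "character",
                 lengthHist = "numeric", offset = "integer"))

setValidity("ReadSetStats", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@baseCounts)), sort(.BASES)))
    msg <- c(msg, "baseCounts must be named A, C, G, T, N")
  else if (abs(sum(object@baseCounts) - object@nBases) > 0.5)
    msg <- c(msg, "nBases must equal the sum of baseCounts")
  if (object@q30Bases > object@q20Bases || object@q20Bases > object@nBases)
    msg <- c(msg, "expected q30Bases <= q20Bases <= nBases")
  if (object@nBases != object@sumLen)
    msg <- c(msg, "nBases must equal sumLen")
  if (length(object@lengthHist) &&
      abs(sum(object@lengthHist) - object@nReads) > 0.5)
    msg <- c(msg, "length histogram must sum to nReads")
  if (object@nReads > 0 &&
      (is.na(object@minLen) || is.na(object@maxLen) ||
       object@minLen > object@maxLen))
    msg <- c(msg, "minLen/maxLen inconsistent for a non-empty set")
  if (!object@offset %in% c(33L, 64L))
    msg <- c(msg, "offset must be 33 or 64")
  if (length(msg)) msg else TRUE
})

#' TrimParams: configuration of the sliding-window quality trimmer
#'
#' Defaults mirror the pipeline's trimming stage: phred cut-off 30, minimum
#' retained length 50 bases, truncation at the first ambiguous base (N)
#' enabled, sanger (offset 33) quality encoding.
#'
#' @slot q phred quality threshold a window mean must reach.
#' @slot minLen minimum retained read length in bases; shorter reads are
#'   discarded.
#' @slot truncateAtN truncate the retained segment before its first N.
#' @slot offset phred offset of the input encoding (33 or 64).
#' @export
setClass("TrimParams",
  representation(q = "numeric", minLen = "numeric", truncateAtN = "logical",
                 offset = "integer"))

setValidity("TrimParams", function(object) {
  msg <- character(0)
  if (length(object@q) != 1L || is.na(object@q) || object@q < 0)
    msg <- c(msg, "q must be a single non-negative number")
  if (length(object@minLen) != 1L || is.na(object@minLen) || object@minLen < 1)
    msg <- c(msg, "minLen must be >= 1")
  if (!object@offset %in% c(33L, 64L))
    msg <- c(msg, "offset must be 33 or 64")
  if (length(msg)) msg else TRUE
})

#' TrimOutcome: pair/singleton accounting of a trimming run
#'
#' Bookkeeping for one paired-end trimming run. The conservation identity
#' `2*pairsIn == 2*pairsKept + singletons + readsDiscarded` holds exactly:
#' every input read ends up kept-in-pair, kept-as-singleton, or discarded.
#'
#' @slot pairsIn input pair count.
#' @slot pairsKept pairs with both mates surviving.
#' @slot singletons reads surviving without their mate.
#' @slot readsDiscarded reads removed entirely.
#' @slot basesBefore,basesAfter total base counts entering and leaving.
#' @export
setClass("TrimOutcome",
  representation(pairsIn = "numeric", pairsKept = "numeric",
                 singletons = "numeric", readsDiscarded = "numeric",
                 basesBefore = "numeric", basesAfter = "numeric"))

setValidity("TrimOutcome", function(object) {
  msg <- character(0)
  if (2 * object@pairsIn !=
      2 * object@pairsKept + object@singletons + object@readsDiscarded)
    msg <- c(msg, "read conservation violated: 2*pairsIn != 2*pairsKept + singletons + readsDiscarded")
  if (object@basesAfter > object@basesBefore)
    msg <- c(msg, "basesAfter must not exceed basesBefore")
  if (any(c(object@pairsIn, object@pairsKept, object@singletons,
            object@readsDiscarded) < 0))
    msg <- c(msg, "negative counts")
  if (length(msg)) msg else TRUE
})

#' CoverageSummary: genome-wide breadth and mean depth
#'
#' Per-genome summary of a zero-inclusive bedgraph coverage track: the mean
#' read depth over all genome positions (zeros included) and the breadth of
#' coverage — the percentage of positions at depth >= t — for each requested
#' threshold (1X, 2X, 5X, 10X and 15X by default).
#'
#' @slot genomeSize genome length in bases.
#' @slot meanDepth mean per-position read depth.
#' @slot breadth named percentage vector, names are the depth thresholds.
#' @export
setClass("CoverageSummary",
  representation(genomeSize = "numeric", meanDepth = "numeric",
                 breadth = "numeric"))

setValidity("CoverageSummary", function(object) {
  msg <- character(0)
  if (length(object@genomeSize) != 1L || object@genomeSize <= 0)
    msg <- c(msg, "genomeSize must be a single positive number")
  if (any(object@breadth < -1e-9 | object@breadth > 100 + 1e-9))
    msg <- c(msg, "breadth percentages must lie in [0, 100]")
  if (is.unsorted(rev(object@breadth)))
    msg <- c(msg, "breadth must be non-increasing across ascending thresholds")
  if (length(msg)) msg else TRUE
})

#' SimParams: configuration of the paired-read simulator
#'
#' Describes a simulated sequencing experiment: a random reference of
#' `refLen` bases at GC fraction `gcTarget`, uniformly placed fragments of
#' normally distributed insert size, and fixed-length mate pairs read off the
#' two fragment ends. Defaults emulate a typical Illumina resequencing run at
#' kilobase scale: 100 bp pairs at 10-fold coverage, 300 +/- 30 bp inserts,
#' a flat phred-38 quality plateau decaying linearly over the final 30% of
#' the read to a mean of 22 (so the 3' tail exercises the trimmer), and an
#' ambiguous-base (N) rate of 0.2%, typical of a well-behaved Illumina run.
#'
#' @slot refLen reference length in bases.
#' @slot gcTarget probability that a reference base is G or C.
#' @slot coverage fold coverage targeted by the pair count.
#' @slot readLen read length in bases.
#' @slot insertMean,insertSd insert size distribution in bases.
#' @slot qualMean plateau mean phred score.
#' @slot qualSd per-base phred standard deviation.
#' @slot qualTailMean mean phred at the final read position.
#' @slot tailFraction fraction of the read over which the 3' decay acts.
#' @slot nRate per-base probability of substitution by N.
#' @slot offset phred offset used to encode qualities.
#' @slot seed integer seed; identical parameters give byte-identical output.
#' @export
setClass("SimParams",
  representation(refLen = "numeric", gcTarget = "numeric", coverage = "numeric",
                 readLen = "numeric", insertMean = "numeric",
                 insertSd = "numeric", qualMean = "numeric", qualSd = "numeric",
                 qualTailMean = "numeric", tailFraction = "numeric",
                 nRate = "numeric", offset = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character(0)
  if (object@readLen > object@insertMean)
    msg <- c(msg, "readLen must not exceed insertMean")
  if (object@gcTarget < 0 || object@gcTarget > 1)
    msg <- c(msg, "gcTarget must lie in [0, 1]")
  if (object@nRate < 0 || object@nRate > 1)
    msg <- c(msg, "nRate must lie in [0, 1]")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be positive")
  if (object@refLen < 1) msg <- c(msg, "refLen must be >= 1")
  if (!object@offset %in% c(33L, 64L)) msg <- c(msg, "offset must be 33 or 64")
  if (length(msg)) msg else TRUE
})
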