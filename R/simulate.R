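## Deterministic synthetic-data generators: random references, paired reads
## with a controlled quality profile and N injection, and bedgraph coverage
## fixtures. Everything is reproducible from the seed alone.

#' Construct simulation parameters
#'
#' See [SimParams-class] for the meaning and rationale of each field.
#' Defaults describe a 10 kb reference sequenced at 10-fold coverage with
#' 100 bp pairs — a kilobase-scale version of a typical simulated Illumina
#' resequencing benchmark.
#'
#' @param refLen,gcTarget,coverage,readLen,insertMean,insertSd,qualMean,qualSd,qualTailMean,tailFraction,nRate,offset,seed
#'   see [SimParams-class].
#' @return A [SimParams-class].
#' @export
simParams <- function(refLen = 10000, gcTarget = 0.5, coverage = 10,
                      readLen = 100, insertMean = 300, insertSd = 30,
                      qualMean = 38, qualSd = 3, qualTailMean = 22,
                      tailFraction = 0.3, nRate = 0.002, offset = 33L,
                      seed = 1L) {
  new("SimParams", refLen = as.numeric(refLen), gcTarget = as.numeric(gcTarget),
      coverage = as.numeric(coverage), readLen = as.numeric(readLen),
      insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
      qualMean = as.numeric(qualMean), qualSd = as.numeric(qualSd),
      qualTailMean = as.numeric(qualTailMean),
      tailFraction = as.numeric(tailFraction), nRate = as.numeric(nRate),
      offset = .checkOffset(offset), seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams: ", .fmtCount(object@refLen), " bp reference (GC ",
      object@gcTarget, "), ", object@coverage, "x coverage, ",
      object@readLen, " bp reads, insert ", object@insertMean, "+/-",
      object@insertSd, ", N rate ", object@nRate, ", seed ", object@seed,
      "\n", sep = "")
})

#' Generate a random reference sequence
#'
#' Bases are drawn independently with `P(G or C) = gcTarget` (split evenly
#' within each pair). The same seed always yields the same sequence.
#'
#' @param refLen reference length in bases.
#' @param gcTarget GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return A single character string over A/C/G/T.
#' @export
generateReference <- function(refLen, gcTarget = 0.5, seed = 1L) {
  stopifnot(refLen >= 1, gcTarget >= 0, gcTarget <= 1)
  set.seed(as.integer(seed))
  p <- c(A = (1 - gcTarget) / 2, C = gcTarget / 2,
         G = gcTarget / 2, T = (1 - gcTarget) / 2)
  paste(sample(names(p), refLen, replace = TRUE, prob = p), collapse = "")
}

## Per-position mean phred: a plateau at qualMean with a linear decay over
## the final tailFraction of the read down to qualTailMean.
.qualProfile <- function(p) {
  pos <- seq_len(p@readLen)
  tailLen <- max(1, round(p@tailFraction * p@readLen))
  prof <- rep(p@qualMean, p@readLen)
  if (tailLen > 1) {
    i <- (p@readLen - tailLen + 1):p@readLen
    prof[i] <- p@qualMean +
      (p@qualTailMean - p@qualMean) * (seq_along(i) - 1) / (tailLen - 1)
  }
  prof
}

.encodePhred <- function(phredMatrix, offset) {
  # rows = reads, cols = positions
  apply(phredMatrix, 1L, function(q) intToUtf8(q + offset))
}

#' Simulate paired-end reads from a reference
#'
#' Places `round(coverage * refLen / (2 * readLen))` fragments uniformly on
#' the reference with normally distributed insert sizes (clamped to
#' `[readLen, refLen]`). Mate 1 is the fragment's 5' end; mate 2 is the
#' reverse complement of its 3' end. Per-base phred scores are drawn around
#' the position profile of the [SimParams-class] (plateau with a decaying 3'
#' tail), clamped to `[2, 40]`; bases are replaced by N at rate `nRate`.
#' Identical parameters produce byte-identical files.
#'
#' @param reference reference sequence (single string), e.g. from
#'   [generateReference()].
#' @param params a [SimParams-class].
#' @param outR1,outR2 output FASTQ paths (`.gz` suffix compresses).
#' @return The number of pairs written, invisibly.
#' @export
simulateReads <- function(reference, params, outR1, outR2) {
  stopifnot(is(params, "SimParams"), is.character(reference),
            length(reference) == 1L)
  refLen <- nchar(reference)
  if (params@insertMean > refLen)
    stop("insertMean exceeds the reference length: infeasible geometry",
         call. = FALSE)
  readLen <- as.integer(params@readLen)
  nPairs <- as.integer(round(params@coverage * refLen / (2 * readLen)))
  set.seed(params@seed)
  insert <- pmin(pmax(round(rnorm(nPairs, params@insertMean,
                                  params@insertSd)), readLen), refLen)
  start <- floor(runif(nPairs, min = 1, max = refLen - insert + 2))
  start <- pmin(start, refLen - insert + 1)

  seq1 <- substring(reference, start, start + readLen - 1L)
  end2 <- start + insert - 1L
  seq2raw <- substring(reference, end2 - readLen + 1L, end2)
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq2raw)))

  prof <- .qualProfile(params)
  drawQuals <- function() {
    q <- round(rep(prof, each = nPairs) +
                 rnorm(nPairs * readLen, 0, params@qualSd))
    matrix(pmin(pmax(q, 2), 40), nrow = nPairs)
  }
  qual1 <- .encodePhred(drawQuals(), params@offset)
  qual2 <- .encodePhred(drawQuals(), params@offset)

  injectN <- function(seqs) {
    if (params@nRate <= 0) return(seqs)
    vapply(seqs, function(s) {
      hit <- which(runif(readLen) < params@nRate)
      if (length(hit)) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        ch[hit] <- "N"
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  seq1 <- injectN(seq1)
  seq2 <- injectN(seq2)

  ids <- sprintf("sim_%d", seq_len(nPairs))
  writeFastq(data.frame(readId = paste0(ids, "/1"), sequence = seq1,
                        quality = qual1, stringsAsFactors = FALSE), outR1)
  writeFastq(data.frame(readId = paste0(ids, "/2"), sequence = seq2,
                        quality = qual2, stringsAsFactors = FALSE), outR2)
  invisible(nPairs)
}

#' Write a bedgraph fixture that tiles one chromosome
#'
#' Emits contiguous 0-based half-open intervals on a single chromosome with
#' the given lengths and depths; the result validates under
#' [validateBgaCover()].
#'
#' @param genomeSize genome length in bases; must equal the summed segment
#'   lengths.
#' @param segments a list of `c(length, depth)` pairs (or a 2-column
#'   matrix, columns length then depth).
#' @param path output path.
#' @param chrom chromosome name.
#' @export
generateBedgraphFixture <- function(genomeSize, segments, path,
                                    chrom = "chr1") {
  if (is.list(segments)) segments <- do.call(rbind, segments)
  segments <- matrix(as.numeric(segments), ncol = 2L)
  if (any(segments[, 1L] < 1) || any(segments[, 2L] < 0))
    stop("segment lengths must be >= 1 and depths >= 0", call. = FALSE)
  if (sum(segments[, 1L]) != genomeSize)
    stop("segment lengths sum to ", .fmtCount(sum(segments[, 1L])),
         ", not genomeSize = ", .fmtCount(genomeSize), call. = FALSE)
  ends <- cumsum(segments[, 1L])
  starts <- c(0, ends[-length(ends)])
  writeLines(sprintf("%s\t%s\t%s\t%s", chrom, .fmtCount(starts),
                     .fmtCount(ends), .fmtCount(segments[, 2L])), path)
  invisible(NULL)
}
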