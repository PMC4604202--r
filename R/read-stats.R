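## The statistics engine: a single streaming pass accumulates every
## read/base-level metric plus the read-length histogram.

#' An empty statistics accumulator
#'
#' @param offset phred offset (33 or 64) that qualities will be decoded with.
#' @return A [ReadSetStats-class] with all counters zero and `NA` range
#'   sentinels; the identity element of [mergeStats()].
#' @export
emptyStats <- function(offset = 33L) {
  new("ReadSetStats", nReads = 0, nBases = 0, q20Bases = 0, q30Bases = 0,
      sumLen = 0, minLen = NA_real_, maxLen = NA_real_,
      baseCounts = setNames(numeric(5L), .BASES),
      minQ = NA_real_, maxQ = NA_real_,
      minQualChar = NA_character_, maxQualChar = NA_character_,
      lengthHist = setNames(numeric(0L), character(0L)),
      offset = .checkOffset(offset))
}

## Add a named count vector into another, unioning names; kept sorted by
## numeric key so accumulators are canonical regardless of arrival order.
.addNamed <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[order(as.numeric(names(out)))]
}

.minNA <- function(a, b) if (is.na(a)) b else if (is.na(b)) a else min(a, b)
.maxNA <- function(a, b) if (is.na(a)) b else if (is.na(b)) a else max(a, b)
.minChar <- function(a, b) {
  if (is.na(a)) b else if (is.na(b)) a
  else if (utf8ToInt(b) < utf8ToInt(a)) b else a
}
.maxChar <- function(a, b) {
  if (is.na(a)) b else if (is.na(b)) a
  else if (utf8ToInt(b) > utf8ToInt(a)) b else a
}

#' Advance an accumulator by a chunk of records
#'
#' Adds each record's contribution to every counter: read and base totals,
#' Q20/Q30 bases (phred >= 20 / >= 30), the \{A,C,G,T,N\} composition (any
#' character outside A/C/G/T counts toward N), length and quality ranges,
#' and the read-length histogram. A quality character below the accumulator's
#' phred offset raises an error naming the offending record.
#'
#' @param stats a [ReadSetStats-class].
#' @param records record data.frame as returned by [readRecords()] (one or
#'   more rows).
#' @return The advanced [ReadSetStats-class].
#' @seealso [computeStats()] for the one-call fold over a file.
#' @export
updateStats <- function(stats, records) {
  stopifnot(is(stats, "ReadSetStats"))
  if (!nrow(records)) return(stats)
  lens <- nchar(records$sequence)
  if (any(lens != nchar(records$quality)) || any(lens == 0L))
    stop("invalid records: sequence/quality length mismatch or empty",
         call. = FALSE)

  seqCodes <- utf8ToInt(paste(records$sequence, collapse = ""))
  baseTab <- tabulate(seqCodes, nbins = 127L)
  acgt <- c(A = baseTab[65L], C = baseTab[67L], G = baseTab[71L],
            T = baseTab[84L])
  counts <- c(acgt, N = length(seqCodes) - sum(acgt))

  qualCodes <- utf8ToInt(paste(records$quality, collapse = ""))
  low <- which(qualCodes < stats@offset)
  if (length(low)) {
    rec <- which(cumsum(lens) >= low[1L])[1L]
    stop("record ", rec, " ('", records$readId[rec],
         "'): quality character below phred offset ", stats@offset,
         "; wrong offset for this file?", call. = FALSE)
  }
  phred <- qualCodes - stats@offset

  hist <- table(lens)
  stats@nReads <- stats@nReads + nrow(records)
  stats@nBases <- stats@nBases + length(seqCodes)
  stats@sumLen <- stats@sumLen + sum(lens)
  stats@q20Bases <- stats@q20Bases + sum(phred >= 20L)
  stats@q30Bases <- stats@q30Bases + sum(phred >= 30L)
  stats@baseCounts <- stats@baseCounts + counts[.BASES]
  stats@minLen <- .minNA(stats@minLen, as.numeric(min(lens)))
  stats@maxLen <- .maxNA(stats@maxLen, as.numeric(max(lens)))
  stats@minQ <- .minNA(stats@minQ, as.numeric(min(phred)))
  stats@maxQ <- .maxNA(stats@maxQ, as.numeric(max(phred)))
  # compare by code point, not locale collation
  minC <- intToUtf8(min(qualCodes)); maxC <- intToUtf8(max(qualCodes))
  stats@minQualChar <- .minChar(stats@minQualChar, minC)
  stats@maxQualChar <- .maxChar(stats@maxQualChar, maxC)
  stats@lengthHist <- .addNamed(stats@lengthHist,
                                setNames(as.numeric(hist), names(hist)))
  stats
}

#' Compute read/base statistics over a FASTQ file or record set
#'
#' One streaming pass over the input, accumulating reads, bases, Q20 and Q30
#' bases, read-length range and average, quality range (both raw characters
#' and decoded phred scores), A/C/G/T/N composition, GC content and the
#' read-length distribution. Files may be plain or gzip-compressed; memory
#' use is bounded by `chunkSize` records.
#'
#' @param x a FASTQ file path, an open [FastqStream-class], or a record
#'   data.frame.
#' @param offset phred offset of the encoding, 33 (HiSeq/MiSeq, default) or
#'   64 (GAIIx-era).
#' @param chunkSize records read per chunk when `x` is a path.
#' @return A [ReadSetStats-class].
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTN", "+", "II5+!"), fq)
#' s <- computeStats(fq)
#' nBases(s); q20Bases(s); q30Bases(s); gcPercent(s)
#' @export
computeStats <- function(x, offset = 33L, chunkSize = 5000L) {
  stats <- emptyStats(offset)
  if (is.data.frame(x)) return(updateStats(stats, x))
  if (is.character(x)) {
    x <- openFastqStream(x, chunkSize = chunkSize)
    on.exit(close(x))
  }
  stopifnot(is(x, "FastqStream"))
  repeat {
    chunk <- readRecords(x)
    if (is.null(chunk)) break
    stats <- updateStats(stats, chunk)
  }
  stats
}

#' Merge two statistics accumulators
#'
#' Combines per-file (or per-worker) accumulators: additive counters sum,
#' ranges combine by min/max, histograms add. Merging with [emptyStats()] is
#' the identity; the operation is commutative and associative, so any split
#' of a read set merges to the single-pass result.
#'
#' @param x,y [ReadSetStats-class] objects decoded with the same phred offset.
#' @return The combined [ReadSetStats-class].
#' @aliases mergeStats,ReadSetStats,ReadSetStats-method
#' @export
setMethod("mergeStats", signature("ReadSetStats", "ReadSetStats"),
  function(x, y) {
    if (x@offset != y@offset)
      stop("cannot merge statistics decoded with different phred offsets",
           call. = FALSE)
    x@nReads <- x@nReads + y@nReads
    x@nBases <- x@nBases + y@nBases
    x@sumLen <- x@sumLen + y@sumLen
    x@q20Bases <- x@q20Bases + y@q20Bases
    x@q30Bases <- x@q30Bases + y@q30Bases
    x@baseCounts <- x@baseCounts + y@baseCounts
    x@minLen <- .minNA(x@minLen, y@minLen)
    x@maxLen <- .maxNA(x@maxLen, y@maxLen)
    x@minQ <- .minNA(x@minQ, y@minQ)
    x@maxQ <- .maxNA(x@maxQ, y@maxQ)
    x@minQualChar <- .minChar(x@minQualChar, y@minQualChar)
    x@maxQualChar <- .maxChar(x@maxQualChar, y@maxQualChar)
    x@lengthHist <- .addNamed(x@lengthHist, y@lengthHist)
    x
  })

#' Accessors for ReadSetStats
#'
#' @param x a [ReadSetStats-class].
#' @return `nReads`, `nBases`, `q20Bases`, `q30Bases`: single counts.
#'   `baseCounts`: named counts for A, C, G, T, N. `gcPercent`:
#'   `100 * (G + C) / nBases` over all bases including N (0 for an empty
#'   set). `meanReadLength`: average read length. `lengthRange`,
#'   `qualityRange`: `c(min, max)` of read length / decoded phred score (`NA`
#'   sentinels when empty). `qualityCharRange`: the raw encoded quality
#'   character range. `lengthHistogram`: read counts named by length,
#'   ascending. `phredOffset`: the decoding offset.
#' @name ReadSetStats-accessors
#' @aliases nReads,ReadSetStats-method nBases,ReadSetStats-method
#'   q20Bases,ReadSetStats-method q30Bases,ReadSetStats-method
#'   baseCounts,ReadSetStats-method gcPercent,ReadSetStats-method
#'   meanReadLength,ReadSetStats-method lengthRange,ReadSetStats-method
#'   qualityRange,ReadSetStats-method qualityCharRange,ReadSetStats-method
#'   lengthHistogram,ReadSetStats-method phredOffset,ReadSetStats-method
NULL

#' @rdname ReadSetStats-accessors
#' @export
setMethod("nReads", "ReadSetStats", function(x) x@nReads)
#' @rdname ReadSetStats-accessors
#' @export
setMethod("nBases", "ReadSetStats", function(x) x@nBases)
#' @rdname ReadSetStats-accessors
#' @export
setMethod("q20Bases", "ReadSetStats", function(x) x@q20Bases)
#' @rdname ReadSetStats-accessors
#' @export
setMethod("q30Bases", "ReadSetStats", function(x) x@q30Bases)
#' @rdname ReadSetStats-accessors
#' @export
setMethod("baseCounts", "ReadSetStats", function(x) x@baseCounts)
#' @rdname ReadSetStats-accessors
#' @export
setMethod("gcPercent", "ReadSetStats", function(x) {
  if (x@nBases == 0) 0
  else 100 * (x@baseCounts[["G"]] + x@baseCounts[["C"]]) / x@nBases
})
#' @rdname ReadSetStats-accessors
#' @export
setMethod("meanReadLength", "ReadSetStats", function(x) {
  if (x@nReads == 0) NA_real_ else x@sumLen / x@nReads
})
#' @rdname ReadSetStats-accessors
#' @export
setMethod("lengthRange", "ReadSetStats", function(x) c(x@minLen, x@maxLen))
#' @rdname ReadSetStats-accessors
#' @export
setMethod("qualityRange", "ReadSetStats", function(x) c(x@minQ, x@maxQ))
#' @rdname ReadSetStats-accessors
#' @export
setMethod("qualityCharRange", "ReadSetStats",
          function(x) c(x@minQualChar, x@maxQualChar))
#' @rdname ReadSetStats-accessors
#' @export
setMethod("lengthHistogram", "ReadSetStats", function(x) {
  h <- x@lengthHist
  h[order(as.numeric(names(h)))]
})
#' @rdname ReadSetStats-accessors
#' @export
setMethod("phredOffset", "ReadSetStats", function(x) x@offset)

#' Write the read-length distribution
#'
#' Two tab-separated columns, `length<TAB>count`, ascending by length; one
#' line per distinct read length (an empty set writes an empty file). The
#' companion file of the per-sample statistics report, intended for plotting.
#'
#' @param stats a [ReadSetStats-class].
#' @param path output path.
#' @export
writeLengthDistribution <- function(stats, path) {
  stopifnot(is(stats, "ReadSetStats"))
  h <- lengthHistogram(stats)
  writeLines(sprintf("%s\t%s", names(h), format(h, scientific = FALSE,
                                                trim = TRUE)), path)
  invisible(NULL)
}

.fmtCount <- function(x) format(x, scientific = FALSE, trim = TRUE)
.fmtNA <- function(x, fmt = "%.2f") ifelse(is.na(x), "NA", sprintf(fmt, x))

#' Format statistics as a plain-text report
#'
#' `key: value` lines covering the full metric set; averages and percentages
#' are reported to 2 decimal places, ranges of an empty set as `NA`.
#'
#' @param stats a [ReadSetStats-class].
#' @param label optional sample label placed on the first line.
#' @return Character vector of report lines.
#' @export
formatStats <- function(stats, label = NULL) {
  stopifnot(is(stats, "ReadSetStats"))
  bc <- baseCounts(stats)
  lr <- lengthRange(stats); qr <- qualityRange(stats)
  qc <- qualityCharRange(stats)
  c(if (!is.null(label)) paste0("sample: ", label),
    paste0("total reads: ", .fmtCount(nReads(stats))),
    paste0("total bases: ", .fmtCount(nBases(stats))),
    paste0("Q20 bases: ", .fmtCount(q20Bases(stats))),
    paste0("Q30 bases: ", .fmtCount(q30Bases(stats))),
    paste0("read length range: ", .fmtNA(lr[1], "%.0f"), "-",
           .fmtNA(lr[2], "%.0f")),
    paste0("average read length: ", .fmtNA(meanReadLength(stats))),
    paste0("quality range: ", ifelse(is.na(qc[1]), "NA", qc[1]), "-",
           ifelse(is.na(qc[2]), "NA", qc[2])),
    paste0("phred quality score range: ", .fmtNA(qr[1], "%.0f"), "-",
           .fmtNA(qr[2], "%.0f")),
    paste0("A count: ", .fmtCount(bc[["A"]])),
    paste0("T count: ", .fmtCount(bc[["T"]])),
    paste0("G count: ", .fmtCount(bc[["G"]])),
    paste0("C count: ", .fmtCount(bc[["C"]])),
    paste0("N count: ", .fmtCount(bc[["N"]])),
    paste0("GC content (%): ", sprintf("%.2f", gcPercent(stats))))
}

setMethod("show", "ReadSetStats", function(object) {
  cat("ReadSetStats (phred offset ", object@offset, ")\n", sep = "")
  cat(paste0("  ", formatStats(object)), sep = "\n")
})
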