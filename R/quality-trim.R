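## Sliding-window 5'/3' quality trimming with singleton routing.
##
## The window is 10% of the read length (minimum 1 base). The 5' cut is the
## start of the first window whose mean phred reaches the threshold; the 3'
## cut falls where the first subsequent window mean drops below it. Window
## means are compared as exact integer sums (sum >= q * window) so results
## are bit-stable. Optionally the retained segment is truncated before its
## first ambiguous base (N), then discarded if shorter than the minimum
## length.

#' Construct trimming parameters
#'
#' Defaults are the pipeline's stated trimming configuration: quality
#' threshold 30, minimum retained length 50, truncation at the first N
#' enabled, sanger (phred+33) encoding.
#'
#' @param q phred threshold for the window mean.
#' @param minLen minimum retained read length in bases.
#' @param truncateAtN truncate the retained segment before its first N.
#' @param offset phred offset of the input, 33 or 64.
#' @return A [TrimParams-class].
#' @export
trimParams <- function(q = 30, minLen = 50, truncateAtN = TRUE, offset = 33L) {
  new("TrimParams", q = as.numeric(q), minLen = as.numeric(minLen),
      truncateAtN = isTRUE(truncateAtN), offset = .checkOffset(offset))
}

#' Sliding-window size for a read length
#'
#' One tenth of the read length, rounded, never below one base.
#'
#' @param readLen read length in bases (>= 1).
#' @return Integer window size.
#' @examples
#' windowSize(100)  # 10
#' windowSize(5)    # 1
#' @export
windowSize <- function(readLen) {
  stopifnot(all(readLen >= 1))
  pmax(1L, as.integer(round(0.1 * readLen)))
}

## Core scan on a decoded phred vector. Returns c(start, end) of the
## retained segment (1-based inclusive) or NULL when no window passes.
.trimCoords <- function(phred, q) {
  len <- length(phred)
  w <- windowSize(len)
  nw <- len - w + 1L
  cs <- cumsum(as.numeric(phred))
  wsums <- cs[w:len] - c(0, cs)[1:nw]
  thr <- q * w
  firstPass <- which(wsums >= thr)
  if (!length(firstPass)) return(NULL)
  s <- firstPass[1L]
  fail <- which(wsums[s:nw] < thr)
  e <- if (!length(fail)) len else s + fail[1L] - 2L
  c(s, e)
}

#' Trim a single read
#'
#' Applies the sliding-window scan to one read and returns the retained
#' segment (sequence and quality sliced consistently), or `NULL` when the
#' read is discarded. Discarding is a value, not an error: it occurs when no
#' window passes the threshold or the retained segment is shorter than
#' `params@minLen`.
#'
#' @param sequence,quality the read's sequence and encoded quality strings
#'   (equal length).
#' @param params a [TrimParams-class].
#' @return `list(sequence=, quality=)` or `NULL` (discard).
#' @examples
#' trimRead("AAAAAAAAAA", "IIIII!!!!!", trimParams(q = 20, minLen = 5))
#' @export
trimRead <- function(sequence, quality, params = trimParams()) {
  stopifnot(is(params, "TrimParams"), nchar(sequence) == nchar(quality))
  phred <- decodeQuality(quality, params@offset)
  co <- .trimCoords(phred, params@q)
  if (is.null(co)) return(NULL)
  s <- co[1L]; e <- co[2L]
  if (params@truncateAtN) {
    nPos <- regexpr("N", substr(sequence, s, e), fixed = TRUE)
    if (nPos > 0L) e <- s + nPos - 2L
  }
  if (e - s + 1L < params@minLen) return(NULL)
  list(sequence = substr(sequence, s, e), quality = substr(quality, s, e))
}

#' Trim a set of reads
#'
#' Vectorized [trimRead()] over a record data.frame. Survivor rows carry the
#' trimmed sequence/quality; the `kept` vector marks survivors.
#'
#' @param records record data.frame (`readId`, `sequence`, `quality`).
#' @param params a [TrimParams-class].
#' @return `list(records = <trimmed survivors>, kept = <logical over input
#'   rows>, basesBefore =, basesAfter =)`.
#' @export
trimReads <- function(records, params = trimParams()) {
  stopifnot(is(params, "TrimParams"))
  n <- nrow(records)
  basesBefore <- sum(nchar(records$sequence))
  if (!n)
    return(list(records = .emptyRecords(), kept = logical(0),
                basesBefore = 0, basesAfter = 0))
  trimmed <- vector("list", n)
  for (i in seq_len(n))  # [i] <- list(...): NULL (discard) must not drop the slot
    trimmed[i] <- list(trimRead(records$sequence[i], records$quality[i], params))
  kept <- !vapply(trimmed, is.null, logical(1))
  out <- records[kept, , drop = FALSE]
  if (nrow(out)) {
    out$sequence <- vapply(trimmed[kept], `[[`, character(1), "sequence")
    out$quality <- vapply(trimmed[kept], `[[`, character(1), "quality")
  }
  rownames(out) <- NULL
  list(records = out, kept = kept, basesBefore = basesBefore,
       basesAfter = sum(nchar(out$sequence)))
}

#' Trim mate pairs with singleton routing
#'
#' Trims both mates of every pair. Pairs where both mates survive are kept
#' as pairs; where exactly one survives, the survivor becomes a singleton;
#' where neither survives, both reads are discarded. The returned
#' [TrimOutcome-class] satisfies the conservation identity
#' `2*pairsIn == 2*pairsKept + singletons + readsDiscarded` exactly.
#'
#' @param r1,r2 synchronized mate record data.frames (equal row counts).
#' @param params a [TrimParams-class].
#' @return `list(kept1=, kept2=, singles=, outcome=)`: the kept mate-1 and
#'   mate-2 records (row-aligned), the singleton records, and the
#'   [TrimOutcome-class].
#' @export
trimPairs <- function(r1, r2, params = trimParams()) {
  stopifnot(nrow(r1) == nrow(r2))
  t1 <- trimReads(r1, params)
  t2 <- trimReads(r2, params)
  bothKept <- t1$kept & t2$kept
  only1 <- t1$kept & !t2$kept
  only2 <- !t1$kept & t2$kept
  # index survivor rows back into the per-mate survivor tables
  kept1 <- t1$records[cumsum(t1$kept)[bothKept], , drop = FALSE]
  kept2 <- t2$records[cumsum(t2$kept)[bothKept], , drop = FALSE]
  singles <- rbind(t1$records[cumsum(t1$kept)[only1], , drop = FALSE],
                   t2$records[cumsum(t2$kept)[only2], , drop = FALSE])
  rownames(kept1) <- rownames(kept2) <- rownames(singles) <- NULL
  nSingle <- sum(only1) + sum(only2)
  basesAfter <- sum(nchar(kept1$sequence)) + sum(nchar(kept2$sequence)) +
    sum(nchar(singles$sequence))
  outcome <- new("TrimOutcome",
                 pairsIn = as.numeric(nrow(r1)),
                 pairsKept = as.numeric(sum(bothKept)),
                 singletons = as.numeric(nSingle),
                 readsDiscarded = as.numeric(2 * nrow(r1) -
                                               2 * sum(bothKept) - nSingle),
                 basesBefore = as.numeric(t1$basesBefore + t2$basesBefore),
                 basesAfter = as.numeric(basesAfter))
  list(kept1 = kept1, kept2 = kept2, singles = singles, outcome = outcome)
}

#' Trim a pair of FASTQ files
#'
#' Streams two mate files through [trimPairs()] chunk by chunk, writing kept
#' pairs to `<outPrefix>_R1.trimmed.fastq[.gz]` / `<outPrefix>_R2...` and
#' singletons to `<outPrefix>_singles.trimmed.fastq[.gz]`.
#'
#' @param pathR1,pathR2 input mate FASTQ paths (plain or gzip).
#' @param outPrefix output path prefix.
#' @param params a [TrimParams-class].
#' @param compress gzip-compress the outputs.
#' @param chunkSize pairs processed per chunk.
#' @return A [TrimOutcome-class]; the three output paths are attached as
#'   attribute `files` (named `r1`, `r2`, `singles`).
#' @export
trimFastqPair <- function(pathR1, pathR2, outPrefix, params = trimParams(),
                          compress = FALSE, chunkSize = 5000L) {
  ext <- if (compress) ".trimmed.fastq.gz" else ".trimmed.fastq"
  paths <- c(r1 = paste0(outPrefix, "_R1", ext),
             r2 = paste0(outPrefix, "_R2", ext),
             singles = paste0(outPrefix, "_singles", ext))
  mkCon <- function(p) if (compress) gzfile(p, "wt") else file(p, "wt")
  cons <- lapply(paths, mkCon)
  ps <- openPairedFastqStream(pathR1, pathR2, chunkSize = chunkSize)
  on.exit({ close(ps); for (co in cons) close(co) })
  total <- new("TrimOutcome", pairsIn = 0, pairsKept = 0, singletons = 0,
               readsDiscarded = 0, basesBefore = 0, basesAfter = 0)
  repeat {
    chunk <- readPairs(ps)
    if (is.null(chunk)) break
    res <- trimPairs(chunk$r1, chunk$r2, params)
    writeLines(.recordLines(res$kept1), cons[["r1"]])
    writeLines(.recordLines(res$kept2), cons[["r2"]])
    writeLines(.recordLines(res$singles), cons[["singles"]])
    o <- res$outcome
    total@pairsIn <- total@pairsIn + o@pairsIn
    total@pairsKept <- total@pairsKept + o@pairsKept
    total@singletons <- total@singletons + o@singletons
    total@readsDiscarded <- total@readsDiscarded + o@readsDiscarded
    total@basesBefore <- total@basesBefore + o@basesBefore
    total@basesAfter <- total@basesAfter + o@basesAfter
  }
  validObject(total)
  attr(total, "files") <- paths
  total
}

#' Accessors for TrimOutcome
#'
#' @param x a [TrimOutcome-class].
#' @return The corresponding count.
#' @name TrimOutcome-accessors
#' @aliases pairsIn,TrimOutcome-method pairsKept,TrimOutcome-method
#'   singletons,TrimOutcome-method readsDiscarded,TrimOutcome-method
#'   basesBefore,TrimOutcome-method basesAfter,TrimOutcome-method
NULL

#' @rdname TrimOutcome-accessors
#' @export
setMethod("pairsIn", "TrimOutcome", function(x) x@pairsIn)
#' @rdname TrimOutcome-accessors
#' @export
setMethod("pairsKept", "TrimOutcome", function(x) x@pairsKept)
#' @rdname TrimOutcome-accessors
#' @export
setMethod("singletons", "TrimOutcome", function(x) x@singletons)
#' @rdname TrimOutcome-accessors
#' @export
setMethod("readsDiscarded", "TrimOutcome", function(x) x@readsDiscarded)
#' @rdname TrimOutcome-accessors
#' @export
setMethod("basesBefore", "TrimOutcome", function(x) x@basesBefore)
#' @rdname TrimOutcome-accessors
#' @export
setMethod("basesAfter", "TrimOutcome", function(x) x@basesAfter)

setMethod("show", "TrimParams", function(object) {
  cat("TrimParams: q=", object@q, ", minLen=", object@minLen,
      ", truncateAtN=", object@truncateAtN, ", phred offset=", object@offset,
      "\n", sep = "")
})

setMethod("show", "TrimOutcome", function(object) {
  cat("TrimOutcome\n",
      "  pairs in:        ", .fmtCount(object@pairsIn), "\n",
      "  pairs kept:      ", .fmtCount(object@pairsKept), "\n",
      "  singletons:      ", .fmtCount(object@singletons), "\n",
      "  reads discarded: ", .fmtCount(object@readsDiscarded), "\n",
      "  bases: ", .fmtCount(object@basesBefore), " -> ",
      .fmtCount(object@basesAfter), "\n", sep = "")
})
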