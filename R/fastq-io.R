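## Streaming FASTQ input/output. Records travel as plain data.frames with
## columns readId / sequence / quality; a chunk of records, not a whole file,
## is the unit held in memory.

.gzipMagic <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

.emptyRecords <- function() {
  data.frame(readId = character(0), sequence = character(0),
             quality = character(0), stringsAsFactors = FALSE)
}

#' Open a FASTQ file for streaming
#'
#' Opens a plain or gzip-compressed FASTQ file (4-line records) and returns a
#' [FastqStream-class] handle from which records are pulled in bounded chunks
#' with [readRecords()]. Compression is detected from the gzip magic bytes
#' (`0x1f 0x8b`) when `mode = "auto"`.
#'
#' Records are validated as they are read: the header line must start with
#' `@`, the separator line with `+`, and sequence and quality must be
#' non-empty and equal in length. Violations raise an error naming the
#' 1-based record index. Sequences are uppercased; trailing carriage returns
#' are stripped.
#'
#' @param path path to the FASTQ file.
#' @param mode `"auto"` (detect gzip by magic bytes), `"plain"` or `"gzip"`.
#' @param chunkSize default records per [readRecords()] call.
#' @return A [FastqStream-class]; close it with `close()`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' fs <- openFastqStream(fq)
#' readRecords(fs)
#' close(fs)
#' @export
openFastqStream <- function(path, mode = c("auto", "plain", "gzip"),
                            chunkSize = 5000L) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("FASTQ file not found: ", path, call. = FALSE)
  gz <- switch(mode, auto = .gzipMagic(path), plain = FALSE, gzip = TRUE)
  con <- if (gz) gzfile(path, "rt") else file(path, "rt")
  state <- new.env(parent = emptyenv())
  state$con <- con
  state$nextRecord <- 1L
  state$open <- TRUE
  new("FastqStream", path = path, gzip = gz,
      chunkSize = as.integer(chunkSize), state = state)
}

#' Read the next chunk of records from a stream
#'
#' Pulls up to `n` records from a [FastqStream-class], or the next `n` mate
#' pairs from a [PairedFastqStream-class]. Returns `NULL` at end of file.
#'
#' @param x an open stream.
#' @param n maximum number of records (defaults to the stream's chunk size).
#' @return For a `FastqStream`, a data.frame with columns `readId`,
#'   `sequence`, `quality`; `NULL` when exhausted.
#' @aliases readRecords,FastqStream-method
#' @export
setMethod("readRecords", "FastqStream", function(x, n = NULL) {
  state <- x@state
  if (!state$open)
    stop("stream is closed: ", x@path, call. = FALSE)
  if (is.null(n)) n <- x@chunkSize
  lines <- readLines(state$con, n = 4L * as.integer(n))
  if (length(lines) == 0L) return(NULL)
  lines <- sub("\r$", "", lines)
  nFull <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record ", state$nextRecord + nFull, " in ", x@path,
         call. = FALSE)
  i <- seq.int(1L, by = 4L, length.out = nFull)
  hdr <- lines[i]; sq <- lines[i + 1L]; sep <- lines[i + 2L]; ql <- lines[i + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ record ", state$nextRecord + bad[1L] - 1L,
         ": header does not start with '@'", call. = FALSE)
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop("FASTQ record ", state$nextRecord + bad[1L] - 1L,
         ": separator line does not start with '+'", call. = FALSE)
  bad <- which(nchar(sq) != nchar(ql) | nchar(sq) == 0L)
  if (length(bad))
    stop("FASTQ record ", state$nextRecord + bad[1L] - 1L,
         ": sequence and quality lengths differ or are empty", call. = FALSE)
  state$nextRecord <- state$nextRecord + nFull
  data.frame(readId = substring(hdr, 2L), sequence = toupper(sq),
             quality = ql, stringsAsFactors = FALSE)
})

#' @export
setMethod("close", "FastqStream", function(con, ...) {
  if (con@state$open) {
    close(con@state$con)
    con@state$open <- FALSE
  }
  invisible(NULL)
})

#' Read a whole FASTQ file
#'
#' Convenience wrapper that streams `path` to exhaustion and returns all
#' records. Use [openFastqStream()] / [readRecords()] for bounded-memory
#' processing of large files.
#'
#' @inheritParams openFastqStream
#' @return data.frame with columns `readId`, `sequence`, `quality`.
#' @export
readFastq <- function(path, mode = c("auto", "plain", "gzip")) {
  fs <- openFastqStream(path, mode = match.arg(mode))
  on.exit(close(fs))
  out <- list()
  repeat {
    chunk <- readRecords(fs)
    if (is.null(chunk)) break
    out[[length(out) + 1L]] <- chunk
  }
  if (!length(out)) return(.emptyRecords())
  do.call(rbind, out)
}

.recordLines <- function(records) {
  if (!nrow(records)) return(character(0))
  as.vector(rbind(paste0("@", records$readId), records$sequence, "+",
                  records$quality))
}

#' Write FASTQ records
#'
#' Writes records as 4-line FASTQ, optionally gzip-compressed. Output
#' re-parses to the identical record sequence (round-trip identity).
#'
#' @param records data.frame with columns `readId`, `sequence`, `quality`.
#' @param path output path.
#' @param compress gzip-compress the output; defaults to `TRUE` when `path`
#'   ends in `.gz`.
#' @return Invisibly, the number of records written.
#' @export
writeFastq <- function(records, path, compress = endsWith(path, ".gz")) {
  stopifnot(all(c("readId", "sequence", "quality") %in% names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality)) ||
      any(nchar(records$sequence) == 0L))
    stop("invalid records: sequence/quality length mismatch or empty",
         call. = FALSE)
  con <- if (compress) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(.recordLines(records), con)
  invisible(nrow(records))
}

#' Decode an encoded quality string to phred scores
#'
#' Subtracts the phred offset from each character's code point. HiSeq/MiSeq
#' data use offset 33 (the default); legacy GAIIx data use offset 64. A
#' character below the offset signals that the wrong offset was chosen and
#' raises an error.
#'
#' @param quality a single quality string (or one character).
#' @param offset phred offset, 33 or 64.
#' @return Integer vector of phred scores, one per character.
#' @examples
#' decodeQuality("I")          # 40
#' decodeQuality("I", 64)      # 9
#' @export
decodeQuality <- function(quality, offset = 33L) {
  offset <- .checkOffset(offset)
  stopifnot(is.character(quality), length(quality) == 1L)
  scores <- utf8ToInt(quality) - offset
  if (any(scores < 0L))
    stop("quality character below phred offset ", offset,
         "; wrong offset for this file?", call. = FALSE)
  scores
}

## Strip a trailing "/1"/"/2" mate suffix or a whitespace-delimited comment,
## leaving the identifier shared by both mates.
.pairId <- function(readId) {
  sub("/[12]$", "", sub("[ \t].*$", "", readId))
}

#' Open two mate FASTQ files as a synchronized paired stream
#'
#' @param pathR1,pathR2 mate-1 and mate-2 FASTQ paths (plain or gzip).
#' @inheritParams openFastqStream
#' @return A [PairedFastqStream-class]; pull pairs with [readPairs()],
#'   close with `close()`.
#' @export
openPairedFastqStream <- function(pathR1, pathR2, chunkSize = 5000L) {
  state <- new.env(parent = emptyenv())
  state$nextPair <- 1L
  new("PairedFastqStream",
      r1 = openFastqStream(pathR1, chunkSize = chunkSize),
      r2 = openFastqStream(pathR2, chunkSize = chunkSize),
      state = state)
}

#' Read the next chunk of mate pairs
#'
#' Pulls up to `n` pairs, checking that mate identifiers agree pairwise
#' (after stripping a trailing `/1`/`/2` or whitespace comment). Unequal
#' record counts or mismatched identifiers raise a desynchronization error
#' naming the 1-based pair index.
#'
#' @param x a [PairedFastqStream-class].
#' @param n maximum number of pairs.
#' @return `list(r1 = <records>, r2 = <records>)` with equal row counts, or
#'   `NULL` when both files are exhausted.
#' @aliases readPairs,PairedFastqStream-method
#' @export
setMethod("readPairs", "PairedFastqStream", function(x, n = NULL) {
  if (is.null(n)) n <- x@r1@chunkSize
  a <- readRecords(x@r1, n)
  b <- readRecords(x@r2, n)
  if (is.null(a) && is.null(b)) return(NULL)
  na <- if (is.null(a)) 0L else nrow(a)
  nb <- if (is.null(b)) 0L else nrow(b)
  state <- x@state
  if (na != nb)
    stop("mate files desynchronized at pair ", state$nextPair + min(na, nb),
         ": unequal record counts", call. = FALSE)
  bad <- which(.pairId(a$readId) != .pairId(b$readId))
  if (length(bad))
    stop("mate files desynchronized at pair ", state$nextPair + bad[1L] - 1L,
         ": read IDs '", a$readId[bad[1L]], "' and '", b$readId[bad[1L]],
         "' do not match", call. = FALSE)
  state$nextPair <- state$nextPair + na
  list(r1 = a, r2 = b)
})

#' @export
setMethod("close", "PairedFastqStream", function(con, ...) {
  close(con@r1)
  close(con@r2)
  invisible(NULL)
})

#' Read two mate files fully, validating pairing
#'
#' @inheritParams openPairedFastqStream
#' @return `list(r1 = <records>, r2 = <records>)` in file order.
#' @export
readFastqPairs <- function(pathR1, pathR2) {
  ps <- openPairedFastqStream(pathR1, pathR2)
  on.exit(close(ps))
  r1 <- list(); r2 <- list()
  repeat {
    chunk <- readPairs(ps)
    if (is.null(chunk)) break
    r1[[length(r1) + 1L]] <- chunk$r1
    r2[[length(r2) + 1L]] <- chunk$r2
  }
  if (!length(r1)) return(list(r1 = .emptyRecords(), r2 = .emptyRecords()))
  list(r1 = do.call(rbind, r1), r2 = do.call(rbind, r2))
}

setMethod("show", "FastqStream", function(object) {
  cat("FastqStream on '", object@path, "' (",
      if (object@gzip) "gzip" else "plain", "), ",
      if (object@state$open) "open" else "closed",
      ", next record ", object@state$nextRecord, "\n", sep = "")
})

setMethod("show", "PairedFastqStream", function(object) {
  cat("PairedFastqStream:\n  R1: ", object@r1@path, "\n  R2: ",
      object@r2@path, "\n  next pair ", object@state$nextPair, "\n", sep = "")
})
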