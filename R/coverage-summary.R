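## Breadth-of-coverage summarization from zero-inclusive bedgraph tracks
## (the dialect produced by `bedtools genomecov -bga`, which tiles the
## genome including zero-depth intervals).

#' Parse a bedgraph coverage file
#'
#' Reads a 4-column tab-separated bedgraph (`chrom`, 0-based inclusive
#' `start`, exclusive `end`, integer `depth`) into a
#' [GenomicRanges::GRanges] with a `depth` metadata column. Coordinates are
#' converted to the 1-based closed convention GRanges uses; widths equal the
#' bedgraph interval lengths. Malformed lines (wrong column count,
#' non-integer fields, `start >= end`, negative depth) raise an error naming
#' the 1-based line number.
#'
#' @param path bedgraph file path.
#' @return A `GRanges` with metadata column `depth`, in file order.
#' @export
parseBedgraph <- function(path) {
  if (!file.exists(path))
    stop("bedgraph file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$depth <- numeric(0)
    return(gr)
  }
  lineNo <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("bedgraph line ", lineNo[bad[1L]], ": expected 4 tab-separated columns",
         call. = FALSE)
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  intRe <- "^[0-9]+$"
  bad <- which(!grepl(intRe, m[, 2L]) | !grepl(intRe, m[, 3L]) |
                 !grepl(intRe, m[, 4L]))
  if (length(bad))
    stop("bedgraph line ", lineNo[bad[1L]],
         ": start, end and depth must be non-negative integers", call. = FALSE)
  start <- as.numeric(m[, 2L]); end <- as.numeric(m[, 3L])
  bad <- which(start >= end)
  if (length(bad))
    stop("bedgraph line ", lineNo[bad[1L]], ": start must be < end",
         call. = FALSE)
  GenomicRanges::GRanges(m[, 1L],
                         IRanges::IRanges(start = start + 1, end = end),
                         depth = as.numeric(m[, 4L]))
}

#' Summarize coverage into breadth at depth thresholds and mean depth
#'
#' For a zero-inclusive coverage track, computes for each threshold `t` the
#' breadth of coverage — `100 * (bases at depth >= t) / genomeSize` — and the
#' mean read depth over all genome positions (zero-depth positions
#' included). The default thresholds are 1X, 2X, 5X, 10X and 15X.
#'
#' @param x a `GRanges` with a `depth` metadata column (from
#'   [parseBedgraph()]) or a bedgraph file path.
#' @param genomeSize genome length in bases. When `NULL`, the summed
#'   interval length is used, provided the intervals tile a genome
#'   ([validateBgaCover()] passes).
#' @param thresholds positive ascending integer depth thresholds.
#' @return A [CoverageSummary-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51, 81),
#'                              c(50, 80, 100)), depth = c(0, 5, 20))
#' summarizeCoverage(gr, genomeSize = 100)
#' @export
summarizeCoverage <- function(x, genomeSize = NULL,
                              thresholds = c(1, 2, 5, 10, 15)) {
  if (is.character(x)) x <- parseBedgraph(x)
  stopifnot(is(x, "GRanges"), "depth" %in% names(S4Vectors::mcols(x)))
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and strictly ascending", call. = FALSE)
  widths <- as.numeric(GenomicRanges::width(x))
  depth <- as.numeric(S4Vectors::mcols(x)$depth)
  covered <- sum(widths)
  if (is.null(genomeSize)) {
    if (!validateBgaCover(x, covered))
      stop("genomeSize omitted but intervals do not tile a genome; ",
           "supply genomeSize explicitly", call. = FALSE)
    genomeSize <- covered
  }
  if (length(genomeSize) != 1L || is.na(genomeSize) || genomeSize <= 0)
    stop("genomeSize must be a single positive number", call. = FALSE)
  br <- vapply(thresholds,
               function(t) 100 * sum(widths[depth >= t]) / genomeSize,
               numeric(1))
  new("CoverageSummary", genomeSize = as.numeric(genomeSize),
      meanDepth = sum(widths * depth) / genomeSize,
      breadth = setNames(br, as.character(thresholds)))
}

#' Check that intervals tile a genome (-bga convention)
#'
#' `TRUE` iff, per chromosome, the intervals are sorted and non-overlapping,
#' and the summed interval length equals `genomeSize` — the shape produced
#' by `bedtools genomecov -bga`, which emits zero-depth intervals so the
#' whole genome is covered exactly once.
#'
#' @param x a `GRanges` (order as parsed) or bedgraph path.
#' @param genomeSize genome length in bases.
#' @return Logical.
#' @export
validateBgaCover <- function(x, genomeSize) {
  if (is.character(x)) x <- parseBedgraph(x)
  stopifnot(is(x, "GRanges"))
  if (sum(as.numeric(GenomicRanges::width(x))) != genomeSize) return(FALSE)
  chrom <- as.character(GenomicRanges::seqnames(x))
  st <- GenomicRanges::start(x); en <- GenomicRanges::end(x)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 2L) next
    if (any(st[i][-1L] <= en[i][-length(i)])) return(FALSE)
  }
  TRUE
}

#' Accessors for CoverageSummary
#'
#' @param x a [CoverageSummary-class].
#' @return `genomeSize`: genome length; `meanDepth`: mean per-position
#'   depth; `breadth`: named percentage vector, names are thresholds.
#' @name CoverageSummary-accessors
#' @aliases genomeSize,CoverageSummary-method meanDepth,CoverageSummary-method
#'   breadth,CoverageSummary-method
NULL

#' @rdname CoverageSummary-accessors
#' @export
setMethod("genomeSize", "CoverageSummary", function(x) x@genomeSize)
#' @rdname CoverageSummary-accessors
#' @export
setMethod("meanDepth", "CoverageSummary", function(x) x@meanDepth)
#' @rdname CoverageSummary-accessors
#' @export
setMethod("breadth", "CoverageSummary", function(x) x@breadth)

setMethod("show", "CoverageSummary", function(object) {
  cat("CoverageSummary over ", .fmtCount(object@genomeSize), " bases\n",
      "  mean depth: ", sprintf("%.2f", object@meanDepth), "\n", sep = "")
  for (t in names(object@breadth))
    cat("  breadth >= ", t, "X: ", sprintf("%.2f", object@breadth[[t]]),
        "%\n", sep = "")
})
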