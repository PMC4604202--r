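## Quick-QC orchestration: per-sample stats -> trim -> stats, run over a
## manifest in worker-sized batches. Samples inside a batch run
## concurrently; batches run sequentially; results are merged in manifest
## order, so the report is byte-identical whatever the worker count.

#' Read a sample manifest
#'
#' Three tab-separated columns — `sample_id`, mate-1 path, mate-2 path —
#' with `#` comment lines and blank lines ignored. Relative read paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return data.frame with columns `sampleId`, `r1`, `r2`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(data.frame(sampleId = character(0), r1 = character(0),
                      r2 = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("manifest line ", which(lengths(parts) != 3L)[1L],
         ": expected 3 tab-separated columns (sample_id, r1, r2)",
         call. = FALSE)
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  if (anyDuplicated(m[, 1L]))
    stop("duplicate sample IDs in manifest: ",
         paste(unique(m[duplicated(m[, 1L]), 1L]), collapse = ", "),
         call. = FALSE)
  resolve <- function(p)
    ifelse(file.exists(p), p, file.path(dirname(path), p))
  data.frame(sampleId = m[, 1L], r1 = resolve(m[, 2L]), r2 = resolve(m[, 3L]),
             stringsAsFactors = FALSE)
}

#' Plan consecutive batches of samples
#'
#' Assigns samples, in manifest order, to consecutive batches of at most
#' `workers` samples: the worker count translates to the number of samples
#' processed at a given instance. By default all available processors are
#' used.
#'
#' @param x a manifest data.frame (from [readManifest()]) or a character
#'   vector of sample IDs.
#' @param workers batch size (>= 1).
#' @return List of character vectors of sample IDs; every sample appears
#'   exactly once.
#' @examples
#' planBatches(paste0("s", 1:5), workers = 2)  # sizes 2, 2, 1
#' @export
planBatches <- function(x, workers = parallel::detectCores()) {
  ids <- if (is.data.frame(x)) x$sampleId else as.character(x)
  workers <- as.integer(workers)
  if (length(workers) != 1L || is.na(workers) || workers < 1L)
    stop("workers must be a single integer >= 1", call. = FALSE)
  if (!length(ids)) return(list())
  unname(split(ids, (seq_along(ids) - 1L) %/% workers))
}

.statsRow <- function(stats, prefix) {
  lr <- lengthRange(stats)
  out <- list(nReads(stats), nBases(stats), q20Bases(stats), q30Bases(stats),
              lr[1], lr[2], meanReadLength(stats), gcPercent(stats))
  names(out) <- paste0(prefix, c("reads", "bases", "q20", "q30", "min_len",
                                 "max_len", "avg_len", "gc"))
  out
}

## Stats -> trim -> stats for one sample. Everything this writes lands in
## outdir under the sample ID.
.quickQCSample <- function(sampleId, r1, r2, params, outdir, compress) {
  message("[", sampleId, "] start")
  before <- mergeStats(computeStats(r1, offset = params@offset),
                       computeStats(r2, offset = params@offset))
  writeLengthDistribution(before,
                          file.path(outdir, paste0(sampleId, "_before_lengths.tsv")))
  outcome <- trimFastqPair(r1, r2, file.path(outdir, sampleId),
                           params = params, compress = compress)
  files <- attr(outcome, "files")
  after <- Reduce(mergeStats,
                  lapply(files, computeStats, offset = params@offset))
  writeLengthDistribution(after,
                          file.path(outdir, paste0(sampleId, "_after_lengths.tsv")))
  message("[", sampleId, "] done: ", .fmtCount(pairsKept(outcome)),
          " pairs kept, ", .fmtCount(singletons(outcome)), " singletons, ",
          .fmtCount(readsDiscarded(outcome)), " reads discarded")
  c(list(sample_id = sampleId, status = "OK"),
    .statsRow(before, "before_"), .statsRow(after, "after_"),
    list(pairs_in = pairsIn(outcome), pairs_kept = pairsKept(outcome),
         singletons = singletons(outcome),
         reads_discarded = readsDiscarded(outcome),
         bases_removed = basesBefore(outcome) - basesAfter(outcome),
         error = ""))
}

.failedRow <- function(sampleId, err) {
  row <- c(list(sample_id = sampleId, status = "FAILED"),
           .statsRow(emptyStats(), "before_"), .statsRow(emptyStats(), "after_"),
           list(pairs_in = NA_real_, pairs_kept = NA_real_,
                singletons = NA_real_, reads_discarded = NA_real_,
                bases_removed = NA_real_, error = gsub("[\t\n]+", " ", err)))
  for (k in grep("^(before|after)_", names(row))) row[[k]] <- NA_real_
  row
}

#' Run the quick-QC pipeline over a manifest
#'
#' For every sample: read/base statistics on the raw mate files, sliding-
#' window trimming to kept-pair and singleton FASTQ files, statistics on the
#' trimmed output (pairs plus singletons), and before/after read-length
#' distribution files. Samples within a batch run concurrently
#' ([planBatches()]); a failing sample is flagged `FAILED` in its report row
#' and does not disturb the others. The consolidated report is written to
#' `<outdir>/qc_report.tsv` and is byte-identical for any `workers` value.
#'
#' @param manifest manifest data.frame ([readManifest()]) or manifest path.
#' @param params a [TrimParams-class]; its offset is also used for decoding.
#' @param workers samples processed concurrently; defaults to all available
#'   processors.
#' @param outdir output directory (created if absent).
#' @param compress gzip-compress trimmed FASTQ outputs.
#' @return The report data.frame, one row per sample, invisibly carrying
#'   attribute `anyFailed`. Columns: `sample_id`, `status`, before/after
#'   metric blocks, trimming accounting, `error`.
#' @export
runQuickQC <- function(manifest, params = trimParams(),
                       workers = parallel::detectCores(), outdir,
                       compress = FALSE) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  stopifnot(is(params, "TrimParams"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  batches <- planBatches(manifest, workers)
  mcCores <- if (.Platform$OS.type == "windows") 1L else as.integer(workers)
  rows <- list()
  for (batch in batches) {
    sub <- manifest[match(batch, manifest$sampleId), , drop = FALSE]
    jobs <- lapply(seq_len(nrow(sub)), function(i) sub[i, , drop = FALSE])
    res <- parallel::mclapply(jobs, function(j) {
      tryCatch(.quickQCSample(j$sampleId, j$r1, j$r2, params, outdir, compress),
               error = function(e) .failedRow(j$sampleId, conditionMessage(e)))
    }, mc.cores = max(1L, min(mcCores, length(jobs))), mc.preschedule = FALSE)
    # a worker killed mid-run surfaces as a try-error from mclapply
    for (i in seq_along(res)) {
      if (inherits(res[[i]], "try-error"))
        res[[i]] <- .failedRow(jobs[[i]]$sampleId, as.character(res[[i]]))
    }
    rows <- c(rows, res)
  }
  report <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(report))
    report <- as.data.frame(.failedRow("x", ""),
                            stringsAsFactors = FALSE)[0, , drop = FALSE]
  rownames(report) <- NULL
  writeQCReport(report, file.path(outdir, "qc_report.tsv"))
  attr(report, "anyFailed") <- any(report$status == "FAILED")
  report
}

.fmtReportCol <- function(x, name) {
  if (!is.numeric(x)) return(as.character(x))
  if (grepl("avg_len$|gc$|^mean_depth$|^breadth_", name))
    ifelse(is.na(x), "NA", sprintf("%.2f", x))
  else ifelse(is.na(x), "NA", .fmtCount(x))
}

#' Write a QC report as TSV
#'
#' Fixed column order and number formatting (counts as integers, averages
#' and percentages to 2 decimals), so reports are byte-stable across runs
#' and worker counts.
#'
#' @param report report data.frame from [runQuickQC()] /
#'   [attachCoverage()].
#' @param path output path.
#' @export
writeQCReport <- function(report, path) {
  out <- report
  for (nm in names(out)) out[[nm]] <- .fmtReportCol(out[[nm]], nm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Attach coverage summaries to a QC report
#'
#' Appends mean-depth and breadth-at-threshold columns for every sample with
#' a bedgraph coverage track (as produced by `bedtools genomecov -bga` on
#' the sample's alignment). Samples without a track get blank columns; a
#' track that fails to parse or does not tile the genome flags that sample's
#' `coverage_status` as `FAILED` without touching its statistics columns.
#'
#' @param report report data.frame from [runQuickQC()].
#' @param bedgraphBySample named character vector or list mapping sample IDs
#'   to bedgraph paths.
#' @param genomeSize genome length in bases.
#' @param thresholds depth thresholds (default 1, 2, 5, 10, 15).
#' @return The extended report data.frame.
#' @export
attachCoverage <- function(report, bedgraphBySample, genomeSize,
                           thresholds = c(1, 2, 5, 10, 15)) {
  bedgraphBySample <- unlist(bedgraphBySample)
  covCols <- paste0("breadth_", thresholds, "x")
  report$coverage_status <- ""
  report$mean_depth <- NA_real_
  for (cc in covCols) report[[cc]] <- NA_real_
  for (sid in names(bedgraphBySample)) {
    i <- which(report$sample_id == sid)
    if (!length(i)) next
    res <- tryCatch({
      gr <- parseBedgraph(bedgraphBySample[[sid]])
      if (!validateBgaCover(gr, genomeSize))
        stop("intervals do not tile a genome of size ", genomeSize)
      summarizeCoverage(gr, genomeSize, thresholds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      report$coverage_status[i] <- "FAILED"
    } else {
      report$coverage_status[i] <- "OK"
      report$mean_depth[i] <- meanDepth(res)
      report[i, covCols] <- as.list(breadth(res))
    }
  }
  report
}
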