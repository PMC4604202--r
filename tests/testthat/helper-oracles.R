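# Independent oracles and in-code fixture builders. The oracles are
# deliberately naive (per-character loops, per-base array expansion,
# windowed re-scans without cumulative sums) so they share no code path
# with the streaming implementations they check.

quietly <- function(expr) suppressMessages(expr)

recordsDF <- function(readId, sequence, quality) {
  data.frame(readId = readId, sequence = sequence, quality = quality,
             stringsAsFactors = FALSE)
}

# Random FASTQ records with mixed lengths, full quality-character range for
# the offset, optional N injection and occasional IUPAC ambiguity codes.
randomRecords <- function(n, lenRange = c(30L, 150L), offset = 33L,
                          nRate = 0, iupacRate = 0) {
  lens <- sample(lenRange[1]:lenRange[2], n, replace = TRUE)
  alphabet <- c("A", "C", "G", "T")
  qchars <- strsplit(intToUtf8(offset:(offset + 40L)), "")[[1]]
  sequence <- character(n); quality <- character(n)
  for (i in seq_len(n)) {
    b <- sample(alphabet, lens[i], replace = TRUE)
    if (nRate > 0) b[runif(lens[i]) < nRate] <- "N"
    if (iupacRate > 0)
      b[runif(lens[i]) < iupacRate] <- sample(c("R", "Y", "K", "M", "S", "W"),
                                              1L)
    sequence[i] <- paste(b, collapse = "")
    quality[i] <- paste(sample(qchars, lens[i], replace = TRUE),
                        collapse = "")
  }
  recordsDF(sprintf("rr_%d", seq_len(n)), sequence, quality)
}

writeRecordsRaw <- function(records, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records)))
    writeLines(c(paste0("@", records$readId[i]), records$sequence[i], "+",
                 records$quality[i]), con)
  invisible(path)
}

# Whole-set per-character statistics oracle: one read at a time, one
# character at a time.
oracleStats <- function(records, offset = 33L) {
  res <- list(nReads = 0, nBases = 0, q20 = 0, q30 = 0, sumLen = 0,
              minLen = NA, maxLen = NA,
              base = c(A = 0, C = 0, G = 0, T = 0, N = 0),
              minQ = NA, maxQ = NA,
              minQualChar = NA_character_, maxQualChar = NA_character_,
              hist = numeric(0))
  for (i in seq_len(nrow(records))) {
    sq <- strsplit(toupper(records$sequence[i]), "", fixed = TRUE)[[1]]
    ql <- strsplit(records$quality[i], "", fixed = TRUE)[[1]]
    len <- length(sq)
    res$nReads <- res$nReads + 1
    res$sumLen <- res$sumLen + len
    res$minLen <- if (is.na(res$minLen)) len else min(res$minLen, len)
    res$maxLen <- if (is.na(res$maxLen)) len else max(res$maxLen, len)
    key <- as.character(len)
    res$hist[key] <- if (key %in% names(res$hist)) res$hist[[key]] + 1 else 1
    for (j in seq_len(len)) {
      res$nBases <- res$nBases + 1
      b <- sq[j]
      if (b == "A") res$base[["A"]] <- res$base[["A"]] + 1
      else if (b == "C") res$base[["C"]] <- res$base[["C"]] + 1
      else if (b == "G") res$base[["G"]] <- res$base[["G"]] + 1
      else if (b == "T") res$base[["T"]] <- res$base[["T"]] + 1
      else res$base[["N"]] <- res$base[["N"]] + 1
      q <- utf8ToInt(ql[j]) - offset
      if (q >= 20) res$q20 <- res$q20 + 1
      if (q >= 30) res$q30 <- res$q30 + 1
      res$minQ <- if (is.na(res$minQ)) q else min(res$minQ, q)
      res$maxQ <- if (is.na(res$maxQ)) q else max(res$maxQ, q)
      if (is.na(res$minQualChar) ||
          utf8ToInt(ql[j]) < utf8ToInt(res$minQualChar))
        res$minQualChar <- ql[j]
      if (is.na(res$maxQualChar) ||
          utf8ToInt(ql[j]) > utf8ToInt(res$maxQualChar))
        res$maxQualChar <- ql[j]
    }
  }
  res$gc <- if (res$nBases == 0) 0 else
    100 * (res$base[["G"]] + res$base[["C"]]) / res$nBases
  res
}

expectStatsMatchOracle <- function(stats, orc) {
  expect_identical(nReads(stats), orc$nReads)
  expect_identical(nBases(stats), orc$nBases)
  expect_identical(q20Bases(stats), orc$q20)
  expect_identical(q30Bases(stats), orc$q30)
  expect_identical(unname(baseCounts(stats)[c("A", "C", "G", "T", "N")]),
                   unname(orc$base))
  expect_identical(unname(lengthRange(stats)), as.numeric(c(orc$minLen,
                                                            orc$maxLen)))
  expect_identical(unname(qualityRange(stats)), as.numeric(c(orc$minQ,
                                                             orc$maxQ)))
  expect_identical(unname(qualityCharRange(stats)),
                   c(orc$minQualChar, orc$maxQualChar))
  expect_equal(gcPercent(stats), orc$gc)
  h <- lengthHistogram(stats)
  oh <- orc$hist[order(as.numeric(names(orc$hist)))]
  expect_identical(h, oh)
}

# Brute-force sliding-window trim oracle: recomputes window means one
# window at a time with sum()/length().
oracleTrimCoords <- function(phred, q) {
  len <- length(phred)
  w <- max(1, round(0.1 * len))
  starts <- 1:(len - w + 1)
  passes <- logical(length(starts))
  for (s in starts) passes[s] <- mean(phred[s:(s + w - 1)]) >= q
  if (!any(passes)) return(NULL)
  s <- which(passes)[1]
  e <- len
  for (k in s:max(starts)) {
    if (!passes[k]) { e <- k - 1; break }
  }
  c(s, e)
}

oracleTrimRead <- function(sequence, quality, q, minLen, truncateAtN = TRUE,
                           offset = 33L) {
  phred <- utf8ToInt(quality) - offset
  co <- oracleTrimCoords(phred, q)
  if (is.null(co)) return(NULL)
  s <- co[1]; e <- co[2]
  if (truncateAtN) {
    chars <- strsplit(substr(sequence, s, e), "", fixed = TRUE)[[1]]
    hit <- which(chars == "N")
    if (length(hit)) e <- s + hit[1] - 2
  }
  if (e - s + 1 < minLen) return(NULL)
  list(sequence = substr(sequence, s, e), quality = substr(quality, s, e))
}

# Per-base array-expansion coverage oracle for small genomes.
oracleCoverage <- function(segLens, segDepths, genomeSize,
                           thresholds = c(1, 2, 5, 10, 15)) {
  depth <- rep(0, genomeSize)
  pos <- 0
  for (i in seq_along(segLens)) {
    depth[(pos + 1):(pos + segLens[i])] <- segDepths[i]
    pos <- pos + segLens[i]
  }
  list(mean = mean(depth),
       breadth = vapply(thresholds,
                        function(t) 100 * sum(depth >= t) / genomeSize,
                        numeric(1)))
}

# Reads resembling the simulated Illumina world: high plateau, decaying 3'
# tail, mild per-base noise.
simWorldRecords <- function(n, readLen = 100L, nRate = 0.002) {
  prof <- c(rep(38, round(0.7 * readLen)),
            seq(38, 22, length.out = readLen - round(0.7 * readLen)))
  sequence <- character(n); quality <- character(n)
  for (i in seq_len(n)) {
    b <- sample(c("A", "C", "G", "T"), readLen, replace = TRUE)
    b[runif(readLen) < nRate] <- "N"
    sequence[i] <- paste(b, collapse = "")
    q <- pmin(pmax(round(prof + rnorm(readLen, 0, 3)), 2), 40)
    quality[i] <- intToUtf8(q + 33L)
  }
  recordsDF(sprintf("sw_%d", seq_len(n)), sequence, quality)
}

# A small simulated paired-end sample on disk; returns the manifest row.
makeSample <- function(dir, id, seed, refLen = 2000, coverage = 10,
                       nRate = 0.002) {
  ref <- generateReference(refLen, 0.5, seed)
  r1 <- file.path(dir, paste0(id, "_R1.fastq"))
  r2 <- file.path(dir, paste0(id, "_R2.fastq"))
  simulateReads(ref, simParams(refLen = refLen, coverage = coverage,
                               insertMean = 300, nRate = nRate,
                               seed = seed + 1000L), r1, r2)
  data.frame(sampleId = id, r1 = r1, r2 = r2, stringsAsFactors = FALSE)
}
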