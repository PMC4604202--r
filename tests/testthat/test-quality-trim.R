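test_that("the window is a tenth of the read length, never below one base", {
  expect_identical(windowSize(100), 10L)
  expect_identical(windowSize(5), 1L)
  expect_identical(windowSize(10), 1L)
  expect_identical(windowSize(1), 1L)
})

# Worked example: phreds 40,40,40,40,40,0,0,0,0,0; q=20 gives window size 1,
# a 5' cut at base 1 and a 3' cut after base 5.
test_that("the worked high-then-low read keeps its first five bases", {
  p5 <- trimParams(q = 20, minLen = 5)
  out <- trimRead("AAAAAAAAAA", "IIIII!!!!!", p5)
  expect_identical(out, list(sequence = "AAAAA", quality = "IIIII"))
  expect_null(trimRead("AAAAAAAAAA", "IIIII!!!!!", trimParams(q = 20,
                                                              minLen = 6)))
})

test_that("q = 0 with no N returns any read unchanged", {
  set.seed(21)
  recs <- randomRecords(20)
  p <- trimParams(q = 0, minLen = 1)
  for (i in seq_len(nrow(recs))) {
    out <- trimRead(recs$sequence[i], recs$quality[i], p)
    expect_identical(out$sequence, recs$sequence[i])
  }
})

test_that("N handling: truncation before the first N, switchable off", {
  sq <- paste0(strrep("A", 60), "N", strrep("A", 39))
  ql <- strrep("I", 100)
  out <- trimRead(sq, ql, trimParams(q = 30, minLen = 50))
  expect_identical(out$sequence, strrep("A", 60))
  out <- trimRead(sq, ql, trimParams(q = 30, minLen = 50, truncateAtN = FALSE))
  expect_identical(out$sequence, sq)
  # N before minLen bases kills the read
  expect_null(trimRead(paste0("N", strrep("A", 99)), ql,
                       trimParams(q = 30, minLen = 50)))
})

test_that("trim decisions match the brute-force window oracle on random reads", {
  set.seed(22)
  recs <- randomRecords(200, lenRange = c(5L, 120L))
  for (q in c(10, 25, 35)) {
    p <- trimParams(q = q, minLen = 5)
    for (i in seq_len(nrow(recs))) {
      got <- trimRead(recs$sequence[i], recs$quality[i], p)
      want <- oracleTrimRead(recs$sequence[i], recs$quality[i], q, 5)
      expect_identical(got, want)
    }
  }
})

test_that("no emitted read is shorter than the minimum length", {
  set.seed(23)
  recs <- simWorldRecords(200)
  res <- trimReads(recs, trimParams())
  expect_true(all(nchar(res$records$sequence) >= 50))
  expect_true(all(nchar(res$records$sequence) == nchar(res$records$quality)))
  expect_lte(res$basesAfter, res$basesBefore)
})

test_that("trimming already-trimmed output changes nothing", {
  set.seed(24)
  p <- trimParams()
  res <- trimReads(simWorldRecords(300), p)
  again <- trimReads(res$records, p)
  expect_identical(again$records, res$records)
  expect_identical(again$basesAfter, again$basesBefore)
})

test_that("pair routing: both mates, one mate, neither mate", {
  good <- strrep("I", 100); bad <- strrep("!", 100)
  sq <- strrep("A", 100)
  p <- trimParams()
  res <- trimPairs(recordsDF("a/1", sq, good), recordsDF("a/2", sq, good), p)
  expect_identical(pairsKept(res$outcome), 1)
  expect_identical(singletons(res$outcome), 0)
  res <- trimPairs(recordsDF("a/1", sq, good), recordsDF("a/2", sq, bad), p)
  expect_identical(pairsKept(res$outcome), 0)
  expect_identical(singletons(res$outcome), 1)
  expect_identical(readsDiscarded(res$outcome), 1)
  expect_identical(res$singles$readId, "a/1")
  res <- trimPairs(recordsDF("a/1", sq, bad), recordsDF("a/2", sq, bad), p)
  expect_identical(readsDiscarded(res$outcome), 2)
})

test_that("read conservation holds over random pair streams", {
  set.seed(25)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    r1 <- randomRecords(n, lenRange = c(40L, 110L), nRate = 0.02)
    r2 <- randomRecords(n, lenRange = c(40L, 110L), nRate = 0.02)
    res <- trimPairs(r1, r2, trimParams(q = 25, minLen = 40))
    o <- res$outcome
    expect_identical(2 * pairsIn(o),
                     2 * pairsKept(o) + singletons(o) + readsDiscarded(o))
    # recount from the emitted streams themselves
    expect_identical(pairsKept(o), as.numeric(nrow(res$kept1)))
    expect_identical(nrow(res$kept1), nrow(res$kept2))
    expect_identical(singletons(o), as.numeric(nrow(res$singles)))
    expect_identical(basesAfter(o),
                     as.numeric(sum(nchar(res$kept1$sequence)) +
                                  sum(nchar(res$kept2$sequence)) +
                                  sum(nchar(res$singles$sequence))))
  }
})

test_that("file-level trimming writes kept pairs and singletons that re-parse", {
  d <- withr::local_tempdir()
  set.seed(26)
  row <- makeSample(d, "t1", seed = 7, refLen = 1500)
  out <- trimFastqPair(row$r1, row$r2, file.path(d, "t1"))
  files <- attr(out, "files")
  expect_true(all(file.exists(files)))
  k1 <- readFastq(files[["r1"]]); k2 <- readFastq(files[["r2"]])
  sg <- readFastq(files[["singles"]])
  expect_identical(as.numeric(nrow(k1)), pairsKept(out))
  expect_identical(as.numeric(nrow(sg)), singletons(out))
  expect_identical(2 * pairsIn(out),
                   2 * pairsKept(out) + singletons(out) + readsDiscarded(out))
  expect_true(all(nchar(c(k1$sequence, k2$sequence, sg$sequence)) >= 50))
  # kept outputs remain synchronized mate files
  expect_silent(readFastqPairs(files[["r1"]], files[["r2"]]))
})
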