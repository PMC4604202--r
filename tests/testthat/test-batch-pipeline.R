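test_that("samples are planned into consecutive batches of worker size", {
  expect_identical(lengths(planBatches(paste0("s", 1:5), 2)), c(2L, 2L, 1L))
  expect_identical(planBatches(paste0("s", 1:5), 2)[[3]], "s5")
  expect_identical(planBatches("s1", 20), list("s1"))
  expect_identical(planBatches(character(0), 4), list())
  expect_error(planBatches("s1", 0), "workers")
  # every sample appears exactly once, in order
  plan <- planBatches(paste0("s", 1:11), 4)
  expect_identical(unlist(plan), paste0("s", 1:11))
})

test_that("manifests parse, skip comments, resolve paths and reject duplicates", {
  d <- withr::local_tempdir()
  file.create(file.path(d, c("a_1.fq", "a_2.fq")))
  man <- file.path(d, "manifest.tsv")
  writeLines(c("# a comment", "", "sampleA\ta_1.fq\ta_2.fq"), man)
  m <- readManifest(man)
  expect_identical(m$sampleId, "sampleA")
  expect_true(all(file.exists(m$r1, m$r2)))
  writeLines(c("a\tx\ty", "a\tx\ty"), man)
  expect_error(readManifest(man), "duplicate")
  writeLines("a\tx", man)
  expect_error(readManifest(man), "3 tab-separated")
})

test_that("a perfect-quality sample passes quick QC untouched", {
  d <- withr::local_tempdir()
  ref <- generateReference(2000, 0.5, 5)
  r1 <- file.path(d, "p_R1.fastq"); r2 <- file.path(d, "p_R2.fastq")
  simulateReads(ref, simParams(refLen = 2000, qualMean = 40, qualSd = 0,
                               qualTailMean = 40, nRate = 0, seed = 9),
                r1, r2)
  man <- data.frame(sampleId = "perfect", r1 = r1, r2 = r2,
                    stringsAsFactors = FALSE)
  rep <- quietly(runQuickQC(man, trimParams(), workers = 1, outdir = d))
  expect_identical(rep$status, "OK")
  expect_identical(rep$after_reads, rep$before_reads)
  expect_identical(rep$after_bases, rep$before_bases)
  expect_identical(rep$after_q30, rep$before_q30)
  expect_identical(rep$pairs_kept, rep$pairs_in)
  expect_identical(rep$singletons, 0)
  expect_identical(rep$bases_removed, 0)
})

test_that("quick QC reports are byte-identical for any worker count", {
  d <- withr::local_tempdir()
  man <- do.call(rbind, lapply(1:4, function(i)
    makeSample(d, paste0("s", i), seed = 100 + i, refLen = 1200)))
  out1 <- file.path(d, "w1"); out4 <- file.path(d, "w4")
  quietly(runQuickQC(man, trimParams(), workers = 1, outdir = out1))
  quietly(runQuickQC(man, trimParams(), workers = 4, outdir = out4))
  expect_identical(readLines(file.path(out1, "qc_report.tsv")),
                   readLines(file.path(out4, "qc_report.tsv")))
})

test_that("a broken sample is flagged FAILED without disturbing the others", {
  d <- withr::local_tempdir()
  ok <- makeSample(d, "good", seed = 11, refLen = 1200)
  man <- rbind(ok,
               data.frame(sampleId = "broken", r1 = ok$r1,
                          r2 = file.path(d, "missing_R2.fastq"),
                          stringsAsFactors = FALSE))
  rep <- quietly(runQuickQC(man, trimParams(), workers = 2, outdir = d))
  expect_identical(rep$status, c("OK", "FAILED"))
  expect_match(rep$error[2], "not found")
  expect_true(attr(rep, "anyFailed"))
  expect_false(is.na(rep$before_reads[1]))
  expect_true(is.na(rep$before_reads[2]))
  # per-row conservation on the surviving sample
  expect_identical(rep$after_bases[1] + rep$bases_removed[1],
                   rep$before_bases[1])
})

test_that("per-row conservation holds across a small cohort", {
  d <- withr::local_tempdir()
  man <- do.call(rbind, lapply(1:3, function(i)
    makeSample(d, paste0("c", i), seed = 200 + i, refLen = 1200)))
  rep <- quietly(runQuickQC(man, trimParams(), workers = 2, outdir = d))
  expect_identical(rep$after_bases + rep$bases_removed, rep$before_bases)
  expect_identical(2 * rep$pairs_in,
                   2 * rep$pairs_kept + rep$singletons + rep$reads_discarded)
  expect_true(all(file.exists(file.path(d, paste0(rep$sample_id,
                                                  "_before_lengths.tsv")))))
  expect_true(all(file.exists(file.path(d, paste0(rep$sample_id,
                                                  "_after_lengths.tsv")))))
})

test_that("coverage columns attach from bedgraph tracks, isolating failures", {
  d <- withr::local_tempdir()
  man <- makeSample(d, "cov1", seed = 33, refLen = 1200)
  rep <- quietly(runQuickQC(man, trimParams(), workers = 1, outdir = d))
  bgGood <- file.path(d, "good.bedgraph")
  generateBedgraphFixture(100, list(c(50, 0), c(30, 5), c(20, 20)), bgGood)

  ext <- attachCoverage(rep, list(cov1 = bgGood), genomeSize = 100)
  expect_identical(ext$coverage_status, "OK")
  expect_identical(ext$mean_depth, 5.5)
  expect_identical(ext$breadth_1x, 50)
  expect_identical(ext$breadth_15x, 20)
  expect_identical(ext$status, rep$status)  # stats columns untouched

  # empty mapping leaves rows blank
  blank <- attachCoverage(rep, list(), genomeSize = 100)
  expect_identical(blank$coverage_status, "")
  expect_true(is.na(blank$mean_depth))

  # a track that does not tile the genome fails that sample only
  bgBad <- file.path(d, "bad.bedgraph")
  writeLines("chr1\t0\t40\t2", bgBad)
  failed <- attachCoverage(rep, list(cov1 = bgBad), genomeSize = 100)
  expect_identical(failed$coverage_status, "FAILED")
  expect_identical(failed$before_bases, rep$before_bases)
})
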