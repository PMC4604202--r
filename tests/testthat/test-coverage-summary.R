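test_that("bedgraph lines parse to 1-based closed GRanges intervals", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t50\t0", bg)
  gr <- parseBedgraph(bg)
  expect_s4_class(gr, "GRanges")
  expect_identical(GenomicRanges::start(gr), 1L)
  expect_identical(GenomicRanges::end(gr), 50L)
  expect_identical(S4Vectors::mcols(gr)$depth, 0)
  writeLines(character(0), bg)
  expect_identical(length(parseBedgraph(bg)), 0L)
})

test_that("malformed bedgraph lines fail with their line number", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t50\t1", "chr1\t50\t50\t3"), bg)
  expect_error(parseBedgraph(bg), "line 2")
  writeLines("chr1\t0\tfifty\t3", bg)
  expect_error(parseBedgraph(bg), "line 1")
  writeLines("chr1\t0\t50", bg)
  expect_error(parseBedgraph(bg), "4 tab-separated")
})

# The toy genome: 100 bases as 50 @ 0x, 30 @ 5x, 20 @ 20x. Expansion of the
# 100 positions gives breadth 50/50/50/20/20 % and mean (30*5 + 20*20)/100.
test_that("the worked 100-base genome summarizes to the expansion oracle", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  generateBedgraphFixture(100, list(c(50, 0), c(30, 5), c(20, 20)), bg)
  cs <- summarizeCoverage(bg, genomeSize = 100)
  expect_identical(breadth(cs),
                   c(`1` = 50, `2` = 50, `5` = 50, `10` = 20, `15` = 20))
  expect_identical(meanDepth(cs), 5.5)
  orc <- oracleCoverage(c(50, 30, 20), c(0, 5, 20), 100)
  expect_identical(unname(breadth(cs)), orc$breadth)
  expect_identical(meanDepth(cs), orc$mean)
})

test_that("an all-zero track has zero breadth and zero mean depth", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), depth = 0)
  cs <- summarizeCoverage(gr, 1000)
  expect_true(all(breadth(cs) == 0))
  expect_identical(meanDepth(cs), 0)
})

test_that("default thresholds are exactly 1, 2, 5, 10 and 15", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), depth = 3)
  expect_identical(names(breadth(summarizeCoverage(gr, 10))),
                   c("1", "2", "5", "10", "15"))
  expect_error(summarizeCoverage(gr, 10, thresholds = c(5, 2)), "ascending")
  expect_error(summarizeCoverage(gr, genomeSize = -1), "positive")
})

test_that("tiling validation accepts -bga shapes and rejects others", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  generateBedgraphFixture(100, list(c(50, 0), c(30, 5), c(20, 20)), bg)
  gr <- parseBedgraph(bg)
  expect_true(validateBgaCover(gr, 100))
  expect_false(validateBgaCover(gr, 120))
  overlapping <- GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(c(1, 40), c(50, 89)),
                                        depth = c(1, 2))
  expect_false(validateBgaCover(overlapping, 100))
  # two chromosomes each tiled from zero are fine
  two <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                IRanges::IRanges(c(1, 1), c(60, 40)),
                                depth = c(1, 0))
  expect_true(validateBgaCover(two, 100))
})

test_that("summaries equal the per-base oracle on random tiled genomes", {
  set.seed(31)
  for (rep in 1:25) {
    nSeg <- sample(1:12, 1)
    segLens <- sample(1:800, nSeg, replace = TRUE)
    segDepths <- sample(0:30, nSeg, replace = TRUE)
    gsize <- sum(segLens)
    bg <- withr::local_tempfile(fileext = ".bedgraph")
    generateBedgraphFixture(gsize, cbind(segLens, segDepths), bg)
    gr <- parseBedgraph(bg)
    expect_true(validateBgaCover(gr, gsize))
    cs <- summarizeCoverage(gr, gsize)
    orc <- oracleCoverage(segLens, segDepths, gsize)
    expect_equal(unname(breadth(cs)), orc$breadth)
    expect_equal(meanDepth(cs), orc$mean)
    expect_false(is.unsorted(rev(breadth(cs))))  # monotone in threshold
  }
})

test_that("doubling every depth matches the oracle's view of the new track", {
  set.seed(32)
  segLens <- c(100, 250, 50, 600)
  segDepths <- c(0, 3, 8, 1)
  gsize <- sum(segLens)
  cs2 <- summarizeCoverage(
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(cumsum(c(1, segLens[-4])),
                                            cumsum(segLens)),
                           depth = 2 * segDepths), gsize)
  orc2 <- oracleCoverage(segLens, 2 * segDepths, gsize)
  expect_equal(unname(breadth(cs2)), orc2$breadth)
  expect_equal(meanDepth(cs2), orc2$mean)
})

test_that("genomeSize falls back to the tiled extent only when tiling holds", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  generateBedgraphFixture(100, list(c(50, 0), c(30, 5), c(20, 20)), bg)
  cs <- summarizeCoverage(bg)
  expect_identical(genomeSize(cs), 100)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 40), c(50, 89)),
                               depth = c(1, 2))
  expect_error(summarizeCoverage(gr), "tile")
})
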