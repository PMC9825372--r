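test_that("segmentation finds maximal positive runs with exact AUC", {
  tr <- trackFromDepths(c(0, 0, 5, 5, 0, 3, 0))
  b <- segmentBlocks(tr)
  expect_equal(length(b), 2L)
  expect_equal(b$auc, c(100, 30))
  expect_equal(b$max_depth, c(5, 3))
  expect_equal(start(b), c(21, 51))
  expect_equal(end(b), c(40, 60))

  expect_equal(length(segmentBlocks(trackFromDepths(rep(0, 10)))), 0L)

  one <- segmentBlocks(trackFromDepths(rep(2, 8)))
  expect_equal(length(one), 1L)
  expect_equal(one$auc, 2 * 80)
})

test_that("segmentation conserves total signal", {
  set.seed(11)
  for (i in 1:5) {
    d <- rpois(500, 0.4)
    tr <- trackFromDepths(d)
    b <- segmentBlocks(tr)
    expect_equal(sum(b$auc), sum(d) * 10)
  }
})

test_that("numeric calling keeps the top fraction with higher-quantile ties", {
  # frozen independent oracle values (numpy quantile, method='higher')
  x <- c(5, 1, 9, 3, 7, 7, 2, 8, 4, 6)
  expect_equal(primeseq:::quantileHigher(x, 1 - 0.01), 9)
  expect_equal(primeseq:::quantileHigher(x, 1 - 0.3), 7)
  expect_equal(primeseq:::quantileHigher(x, 1 - 0.5), 6)
  expect_equal(primeseq:::quantileHigher(x, 0), 1)
  y <- c(12.5, 3.25, 99.0, 45.5, 45.5, 7.75)
  expect_equal(primeseq:::quantileHigher(y, 1 - 0.34), 45.5)
  expect_equal(primeseq:::quantileHigher(y, 1 - 0.9), 7.75)

  # 100 distinct AUCs at fraction 0.01 -> exactly the top block
  set.seed(12)
  auc <- sample(1000, 100)
  ps <- callPeaksNumeric(blocksFromAuc(auc), fraction = 0.01,
                         mode = "relaxed")
  expect_equal(peakRanges(ps)$auc, max(auc))

  # fraction 1 keeps everything
  ps_all <- callPeaksNumeric(blocksFromAuc(auc), fraction = 1)
  expect_equal(length(ps_all), 100L)

  expect_warning(callPeaksNumeric(blocksFromAuc(numeric(0)), 0.5), "empty")
})

test_that("numeric calling equals the sort-and-slice oracle over 100 seeds", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:30, 1)
    auc <- sample(1:15, n, replace = TRUE)   # ties likely
    f <- runif(1, 0.05, 0.9)
    ps <- callPeaksNumeric(blocksFromAuc(auc), fraction = f, mode = "relaxed")
    kept <- sort(start(peakRanges(ps)))
    oracle <- sort(start(blocksFromAuc(auc))[oracleTopFraction(auc, f)])
    expect_identical(kept, oracle)
  }
})

test_that("numeric calling is monotone in the retained fraction", {
  set.seed(13)
  auc <- runif(200, 1, 50)
  b <- blocksFromAuc(auc)
  prev <- integer(0)
  for (f in c(0.01, 0.05, 0.2, 0.5, 1)) {
    kept <- start(peakRanges(callPeaksNumeric(b, f, mode = "relaxed")))
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("stringent mode additionally gates on max depth", {
  b <- blocksFromAuc(c(100, 90, 80, 10), max_depth = c(1, 9, 8, 2))
  relaxed <- callPeaksNumeric(b, fraction = 0.5, mode = "relaxed")
  stringent <- callPeaksNumeric(b, fraction = 0.5, mode = "stringent")
  expect_equal(sort(peakRanges(relaxed)$auc), c(90, 100))
  # the top-AUC block has the weakest summit and is dropped by the gate
  expect_equal(peakRanges(stringent)$auc, 90)
})

test_that("control-mode thresholding matches the exhaustive scan", {
  t1 <- blocksFromAuc(c(10, 9, 8, 1, 1))
  c1 <- blocksFromAuc(c(2, 1, 1, 1, 1))
  ps <- callPeaksWithControl(t1, c1, mode = "relaxed")
  oracle <- oracleControlThreshold(c(10, 9, 8, 1, 1), c(2, 1, 1, 1, 1))
  expect_equal(aucThreshold(ps), oracle$threshold)
  expect_equal(empiricalFDR(ps), oracle$fdr)

  # identical lists: no separation, FDR 1, QC fail
  same <- c(4, 3, 2, 2)
  expect_warning(
    ps0 <- callPeaksWithControl(blocksFromAuc(same), blocksFromAuc(same)),
    "same separation")
  expect_equal(empiricalFDR(ps0), 1)
  expect_false(qcPass(ps0))

  # perfect separation: FDR 0, QC pass
  ps1 <- callPeaksWithControl(blocksFromAuc(c(50, 40, 30)),
                              blocksFromAuc(c(5, 4)), mode = "relaxed")
  expect_equal(empiricalFDR(ps1), 0)
  expect_true(qcPass(ps1))
  expect_equal(length(ps1), 3L)
})

test_that("control-mode threshold equals the brute-force maximizer on random instances", {
  for (seed in 1:50) {
    set.seed(200 + seed)
    ta <- sample(1:30, sample(5:40, 1), replace = TRUE)
    ca <- sample(1:30, sample(5:40, 1), replace = TRUE)
    ps <- suppressWarnings(
      callPeaksWithControl(blocksFromAuc(ta), blocksFromAuc(ca),
                           mode = "relaxed"))
    oracle <- oracleControlThreshold(ta, ca)
    expect_equal(aucThreshold(ps), oracle$threshold)
    expect_equal(empiricalFDR(ps), oracle$fdr)
  }
})

test_that("QC filtering drops exactly the high-FDR samples", {
  mk <- function(fdr, id) new("PeakSet", peaks = blocksFromAuc(c(5, 4)),
                              mode = "relaxed", thresholdType = "control",
                              numericFraction = NA_real_, aucThreshold = 1,
                              empiricalFDR = fdr, sampleId = id)
  sets <- list(mk(0.09, "a"), mk(0.11, "b"), mk(0.5, "c"), mk(0, "d"),
               callPeaksNumeric(blocksFromAuc(c(9, 2)), 0.5, sampleId = "e"),
               mk(0.1, "f"))
  out <- qcFilterSamples(sets)
  kept <- vapply(out$retained, function(p) p@sampleId, character(1))
  expect_setequal(kept, c("a", "d", "e", "f"))
  expect_setequal(out$excluded$sample_id, c("b", "c"))
  expect_match(out$excluded$reason[1], "FDR")
})

test_that("planted peaks are recovered by numeric 1% calling at high enrichment", {
  # planted count ~ 1% of the block count; fold 8 over background
  recov <- vapply(1:20, function(seed) {
    set.seed(300 + seed)
    lam <- 1
    n_tiles <- 20000
    d <- rpois(n_tiles, lam)
    width_tiles <- 50
    n_peaks <- 45
    starts <- sort(sample(seq(1, n_tiles - width_tiles, by = 400), n_peaks))
    for (s in starts)
      d[s:(s + width_tiles - 1)] <- d[s:(s + width_tiles - 1)] +
        rpois(width_tiles, 8 * lam)
    b <- segmentBlocks(trackFromDepths(d))
    ps <- callPeaksNumeric(b, fraction = 0.01, mode = "relaxed")
    planted <- GRanges("chr1", IRanges((starts - 1) * 10 + 1,
                                       width = width_tiles * 10))
    mean(overlapsAny(planted, peakRanges(ps)))
  }, numeric(1))
  expect_gte(median(recov), 0.9)
})

test_that("planted-peak signal beats matched IgG signal at fold >= 4", {
  set.seed(21)
  params <- simulationParams(backgroundRate = 2, iggRate = 2,
                             enrichmentFold = 4)
  genome <- makeGenome(5, c(chr1 = 200000), seed = 3)
  g <- geneModels(genome)
  peaks <- data.frame(gene_id = g$gene_id, antibody = "H4K8ac",
                      chrom = "chr1", start = g$tss, end = g$tss + 499L,
                      conditions = "ELE", stringsAsFactors = FALSE)
  tr <- simulateCoverage(genome, peaks, "H4K8ac", "ELE", params, seed = 4)
  igg <- simulateCoverage(genome, peaks, "IgG", "ELE", params, seed = 5)
  pk_gr <- GRanges(peaks$chrom, IRanges(peaks$start, peaks$end))
  aucWithin <- function(track, region) {
    hits <- findOverlaps(track, region)
    ov <- pintersect(track[queryHits(hits)], region[subjectHits(hits)])
    sum(width(ov) * track$score[queryHits(hits)])
  }
  for (i in seq_along(pk_gr))
    expect_gt(aucWithin(tr, pk_gr[i]), aucWithin(igg, pk_gr[i]))
})
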