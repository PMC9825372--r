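test_that("median-of-ratios size factors match a hand-computed oracle", {
  # 3 genes x 2 samples: geometric means (2, 6, 4sqrt(2)); per-sample
  # ratios s1: (1/2, 2/3, 1/sqrt2), s2: (2, 3/2, sqrt2); medians by hand
  m <- matrix(c(1, 4, 4, 4, 9, 8), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sf <- medianRatioSizeFactors(m)
  expect_equal(unname(sf), c(median(c(1/2, 2/3, 1/sqrt(2))),
                             median(c(2, 3/2, sqrt(2)))))

  # identical samples give unit factors
  m2 <- matrix(rep(c(5, 9, 2), 3), nrow = 3)
  expect_equal(unname(medianRatioSizeFactors(m2)), rep(1, 3))

  # doubling one sample doubles its factor relative to the others (the
  # geometric-mean reference rescales all factors by a common constant)
  m3 <- cbind(m2, 2 * m2[, 1])
  sf3 <- medianRatioSizeFactors(m3)
  expect_equal(unname(sf3[4] / sf3[1]), 2)
  expect_equal(unname(sf3[2] / sf3[1]), 1)

  expect_error(medianRatioSizeFactors(matrix(c(0, 1, 1, 0), 2)),
               "all-positive")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(600, mu = 100, size = 5), nrow = 100)
  # linear-scale median of ratios vs the reference's exp(median(log ratio)):
  # identical up to median interpolation over even-sized reference sets
  expect_equal(unname(medianRatioSizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("normalization is equivariant: scaling a sample leaves LFCs fixed", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 8, mu = 150, size = 10), nrow = 200)
  rownames(m) <- paste0("g", 1:200)
  design <- data.frame(group = rep(c("A", "B"), each = 4))
  de1 <- nbWaldTest(m, design, c("group", "B", "A"))
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  sf1 <- medianRatioSizeFactors(m)
  sf2 <- medianRatioSizeFactors(m2)
  expect_equal(unname((sf2[3] / sf2[1]) / (sf1[3] / sf1[1])), 5,
               tolerance = 1e-8)
  # rescaling is absorbed by the offset; the NB weights shift slightly at
  # finite counts (the 1/mu variance component shrinks), so the estimates
  # agree closely but not to solver precision
  de2 <- nbWaldTest(m2, design, c("group", "B", "A"),
                    dispersions = rep(0.05, 200))
  de1b <- nbWaldTest(m, design, c("group", "B", "A"),
                     dispersions = rep(0.05, 200))
  expect_gt(cor(de2$log2FoldChange, de1b$log2FoldChange), 0.999)
  expect_lt(max(abs(de2$log2FoldChange - de1b$log2FoldChange)), 0.05)
})

test_that("method-of-moments dispersions floor and recover", {
  # constant gene -> floor
  m <- matrix(7, 1, 10)
  expect_equal(estimateDispersionsMoM(m, sizeFactors = rep(1, 10)), 1e-8)

  # Poisson genes mostly land on the floor
  set.seed(1)
  mp <- matrix(rpois(1000 * 60, lambda = 80), nrow = 1000)
  a <- estimateDispersionsMoM(mp, sizeFactors = rep(1, 60))
  expect_gt(mean(a <= 0.01), 0.9)

  # NB alpha = 0.5 recovered in the median over 2000 genes, n = 50/group
  set.seed(2)
  grp <- factor(rep(c("A", "B"), each = 50))
  mn <- matrix(rnbinom(2000 * 100, mu = 100, size = 2), nrow = 2000)
  ah <- estimateDispersionsMoM(mn, grp, sizeFactors = rep(1, 100))
  expect_gt(median(ah), 0.35)
  expect_lt(median(ah), 0.65)
})

test_that("Wald estimates are unbiased and degenerate genes yield NA", {
  set.seed(3)
  n <- 10
  mu <- 100
  m <- cbind(matrix(rnbinom(1000 * n, mu = mu, size = 10), ncol = n),
             matrix(rnbinom(1000 * n, mu = 2 * mu, size = 10), ncol = n))
  rownames(m) <- paste0("g", 1:1000)
  design <- data.frame(group = rep(c("ref", "test"), each = n))
  de <- nbWaldTest(m, design, c("group", "test", "ref"),
                   sizeFactors = rep(1, 2 * n))
  expect_gt(mean(de$log2FoldChange, na.rm = TRUE), 0.9)
  expect_lt(mean(de$log2FoldChange, na.rm = TRUE), 1.1)

  m[1, ] <- 0L
  de0 <- nbWaldTest(m, design, c("group", "test", "ref"),
                    sizeFactors = rep(1, 2 * n))
  expect_true(is.na(de0$pvalue[1]))
  expect_true(is.na(de0$padj[1]))   # excluded from the BH batch
})

test_that("Wald log fold changes track the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  n <- 8
  m <- matrix(rnbinom(300 * 2 * n, mu = 200, size = 8), ncol = 2 * n)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  cond <- factor(rep(c("A", "B"), each = n))
  m[, cond == "B"] <- m[, cond == "B"] +
    matrix(rpois(300 * n, 60), ncol = n)
  de <- nbWaldTest(m, data.frame(group = cond), c("group", "B", "A"))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, S4Vectors::DataFrame(cond = cond),
                                        ~ cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("cond", "B", "A"))
  ok <- !is.na(de$log2FoldChange) & !is.na(ref$log2FoldChange)
  expect_gt(cor(de$log2FoldChange[ok], ref$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(de$log2FoldChange[ok] - ref$log2FoldChange[ok])), 0.05)
})

test_that("LRT nesting is judged by column space, degenerate cases included", {
  set.seed(4)
  m <- matrix(rnbinom(50 * 12, mu = 100, size = 10), nrow = 50)
  rownames(m) <- paste0("g", 1:50)
  design <- data.frame(a = rep(c("x", "y"), 6), b = rep(c("u", "v"), each = 6))
  expect_error(nbLRT(m, design, ~ a, ~ a + b), "not nested")
  # full = reduced: stat 0, p 1 for every gene (nested identity)
  expect_warning(res <- nbLRT(m, design, ~ a, ~ a), "equivalent")
  expect_true(all(res$stat[!is.na(res$stat)] == 0))
  expect_true(all(res$pvalue[!is.na(res$pvalue)] == 1))
  # a reduced model that spans a subspace without sharing column names
  design$x <- rep(c(-1, 0, 1), 4)
  res2 <- nbLRT(m, design, ~ a + x, ~ I(2 * x))
  expect_equal(S4Vectors::metadata(res2)$df, 1)
  # with a 2x2 factorial, dropping a main effect but keeping the
  # interaction still spans the saturated cell space: df 0
  expect_warning(res3 <- nbLRT(m, design, ~ a + b + a:b, ~ a + a:b),
                 "equivalent")
  expect_equal(S4Vectors::metadata(res3)$df, 0)
})

test_that("LRT recovers a planted exercise effect over hemisphere", {
  set.seed(5)
  design <- data.frame(hemisphere = rep(c("L", "R"), 12),
                       exercise = rep(c("ELE", "SED"), each = 12))
  n_genes <- 300
  mu <- matrix(100, n_genes, 24)
  eff <- sample(n_genes, 60)
  mu[eff, design$exercise == "ELE"] <- 250
  m <- matrix(rnbinom(n_genes * 24, mu = mu, size = 10), nrow = n_genes)
  rownames(m) <- paste0("g", seq_len(n_genes))
  full <- ~ hemisphere + exercise + hemisphere:exercise
  lrt_ex <- nbLRT(m, design, full, ~ hemisphere)     # tests exercise terms
  lrt_hem <- nbLRT(m, design, full, ~ exercise)      # tests hemisphere terms
  n_ex <- sum(lrt_ex$pvalue < 0.05, na.rm = TRUE)
  n_hem <- sum(lrt_hem$pvalue < 0.05, na.rm = TRUE)
  expect_gt(n_ex, n_hem)
  expect_gt(n_ex, 40)
})

test_that("per-gene two-way ANOVA matches the closed-form balanced oracle", {
  # hand-computed 2x2 with 2 replicates on the log2 scale:
  # cells (10,12), (20,18), (11,13), (27,25) -> F = 16, 121, 9 with df (1,4)
  v <- c(10, 12, 20, 18, 11, 13, 27, 25)
  counts <- matrix(as.integer(round(2^v - 1)), nrow = 1)
  rownames(counts) <- "g1"
  design <- data.frame(
    hemisphere = c("L", "L", "L", "L", "R", "R", "R", "R"),
    exercise = c("ELE", "ELE", "SED", "SED", "ELE", "ELE", "SED", "SED"))
  res <- perGeneTwoWayAnova(counts, design, sizeFactors = rep(1, 8))
  expect_equal(unname(unlist(res[1, 1:3])), c(16, 121, 9), tolerance = 1e-6)
  expect_equal(unname(unlist(res[1, 4:6])),
               pf(c(16, 121, 9), 1, 4, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("per-gene two-way ANOVA agrees with stats::aov gene by gene", {
  set.seed(6)
  design <- data.frame(hemisphere = rep(c("L", "R"), each = 6),
                       exercise = rep(rep(c("ELE", "SED"), each = 3), 2))
  m <- matrix(rnbinom(20 * 12, mu = 150, size = 5), nrow = 20)
  rownames(m) <- paste0("g", 1:20)
  res <- perGeneTwoWayAnova(m, design, sizeFactors = rep(1, 12))
  for (g in c(1, 7, 20)) {
    y <- log2(m[g, ] + 1)
    a <- summary(aov(y ~ hemisphere * exercise, data = design))[[1]]
    expect_equal(unname(unlist(res[g, 4:6])),
                 a[["Pr(>F)"]][1:3], tolerance = 1e-8)
  }
  expect_error(perGeneTwoWayAnova(m, data.frame(
    hemisphere = rep("L", 12), exercise = design$exercise)), "empty cell")
})

test_that("ANOVA on a constant gene returns NA by convention", {
  design <- data.frame(hemisphere = rep(c("L", "R"), each = 4),
                       exercise = rep(c("ELE", "SED"), 4))
  m <- matrix(7L, 1, 8, dimnames = list("g1", NULL))
  res <- perGeneTwoWayAnova(m, design, sizeFactors = rep(1, 8))
  expect_true(all(is.na(unlist(res[1, 4:6]))))
})

test_that("BH adjustment follows the step-up rule and handles NAs", {
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  p <- c(0.01, NA, 0.04)
  out <- adjustBH(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in p-rank
  set.seed(8)
  p <- runif(100)
  expect_true(all(diff(adjustBH(p)[order(p)]) >= -1e-12))
})

test_that("DEG calling applies strict thresholds with the log2(1.3) default", {
  expect_equal(round(log2(1.3), 4), 0.3785)
  de <- S4Vectors::DataFrame(
    log2FoldChange = c(0.3785, 0.5, -0.5, 0.4, -0.2),
    pvalue = c(0.001, 0.04, 0.04, 0.05, 0.01),
    padj = rep(0.2, 5),
    row.names = paste0("g", 1:5))
  sets <- callDegs(de)
  # boundary gene at exactly the cutoff is not called (strict >)
  expect_false("g1" %in% degUp(sets))
  # boundary p exactly at 0.05 is not called (strict <)
  expect_false("g4" %in% degUp(sets))
  expect_identical(degUp(sets), "g2")
  expect_identical(degDown(sets), "g3")
  expect_length(intersect(degUp(sets), degDown(sets)), 0)
  expect_warning(callDegs(de, lfcCut = 0.3875), "0.3785")
  # padj gating is available
  sets2 <- callDegs(de, use = "padj")
  expect_length(degUp(sets2), 0)
})
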