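test_that("mark dynamics are set differences and intersection", {
  pres <- list(H4K8ac.ELE = c("a", "b"), H4K8ac.SED = c("b", "c"))
  dyn <- markDynamics(pres, "H4K8ac")
  expect_identical(dyn@new, "a")
  expect_identical(dyn@lost, "c")
  expect_identical(dyn@shared, "b")

  same <- list(H4K8ac.ELE = c("x", "y"), H4K8ac.SED = c("y", "x"))
  dyn2 <- markDynamics(same, "H4K8ac")
  expect_length(dyn2@new, 0)
  expect_length(dyn2@lost, 0)
  expect_setequal(dyn2@shared, c("x", "y"))

  expect_error(markDynamics(list(H4K8ac.ELE = "a"), "H4K8ac"), "SED")

  # randomized sets match a brute-force membership test
  for (seed in 1:10) {
    set.seed(seed)
    universe <- paste0("g", 1:1000)
    ele <- sample(universe, sample(0:500, 1))
    sed <- sample(universe, sample(0:500, 1))
    dyn <- markDynamics(list(H4K8ac.ELE = ele, H4K8ac.SED = sed), "H4K8ac")
    for (g in sample(universe, 50)) {
      in_e <- g %in% ele; in_s <- g %in% sed
      expect_equal(g %in% dyn@new, in_e && !in_s)
      expect_equal(g %in% dyn@lost, !in_e && in_s)
      expect_equal(g %in% dyn@shared, in_e && in_s)
    }
  }
})

test_that("dynamics-DEG overlaps count shared genes and co-occurrence", {
  dyn_h4 <- new("MarkDynamics", antibody = "H4K8ac",
                new = c("a", "b", "c"), lost = character(0),
                shared = character(0))
  dyn_h3 <- new("MarkDynamics", antibody = "H3K27me3",
                new = c("b", "z"), lost = character(0), shared = character(0))
  degs <- degSets(up = c("b", "c", "d"))
  ov <- intersectDynamicsDegs(list(dyn_h4, dyn_h3), degs)
  row <- ov$table[ov$table$antibody == "H4K8ac" & ov$table$dynamic == "new" &
                  ov$table$direction == "up", ]
  expect_equal(row$count, 2L)
  expect_equal(row$genes, "b,c")
  # "of those, N also had ..." style co-occurrence
  co <- ov$cooccurrence
  both <- co[grepl("H4K8ac.new.up", co$cell_a) &
             grepl("H3K27me3.new.up", co$cell_b), ]
  expect_equal(both$count, 1L)
  expect_equal(both$genes, "b")

  empty <- intersectDynamicsDegs(list(dyn_h4), degSets())
  expect_true(all(empty$table$count == 0))
})

test_that("cGAME classification matches the exhaustive 16-pattern oracle", {
  for (dir in c("up", "down")) {
    for (code in 0:15) {
      inEA <- bitwAnd(code, 1) > 0
      inE3 <- bitwAnd(code, 2) > 0
      inS3 <- bitwAnd(code, 4) > 0
      inS10 <- bitwAnd(code, 8) > 0
      gene <- "g"
      mk <- function(present) {
        if (dir == "up") degSets(up = if (present) gene else character(0))
        else degSets(down = if (present) gene else character(0))
      }
      cl <- classifyGame(list(ELE_alone = mk(inEA), ELE_3min = mk(inE3),
                              SED_3min = mk(inS3), SED_10min = mk(inS10)))
      expected <- oracleGameClass(inEA, inE3, inS3, inS10)
      for (cls in c("cGAME", "cGAMES", "cGAMS"))
        expect_equal(gene %in% gameClass(cl, cls, dir), cls %in% expected,
                     info = sprintf("pattern %d class %s dir %s", code, cls,
                                    dir))
    }
  }
  expect_error(classifyGame(list(ELE_3min = degSets())), "missing group")
})

test_that("priming fractions reproduce the worked percentage examples", {
  mkgenes <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))
  cgames <- mkgenes(145, "s")
  cgame <- mkgenes(256, "e")
  cl <- new("GameClassification",
            up = list(cGAME = cgame, cGAMES = cgames, cGAMS = character(0)),
            down = list(cGAME = character(0), cGAMES = character(0),
                        cGAMS = character(0)),
            groups = c("ELE_alone", "ELE_3min", "SED_3min", "SED_10min"))
  dyn <- list(
    H4K8ac = new("MarkDynamics", antibody = "H4K8ac",
                 new = c(cgames[1:58], cgame[1:76]), lost = character(0),
                 shared = character(0)),
    H3K27me3 = emptyDynamics("H3K27me3"))
  rep <- primingFractions(cl, dyn)
  s <- primingSummary(rep)
  # 58 of 145 -> 40%; 76 of 256 -> 29.7% displayed as 30%
  expect_equal(s$percent[s$class == "cGAMES" & s$direction == "up"], 40)
  expect_equal(s$n_primed[s$class == "cGAMES" & s$direction == "up"], 58L)
  expect_equal(s$percent[s$class == "cGAME" & s$direction == "up"], 30)
  expect_equal(s$fraction[s$class == "cGAME" & s$direction == "up"], 76 / 256)
  # empty class -> NA fraction, count 0
  expect_true(is.na(s$fraction[s$class == "cGAMS" & s$direction == "up"]))
  expect_equal(s$n_primed[s$class == "cGAMS" & s$direction == "up"], 0L)
  # no overlap -> 0%
  dyn0 <- list(H4K8ac = emptyDynamics("H4K8ac"),
               H3K27me3 = emptyDynamics("H3K27me3"))
  s0 <- primingSummary(primingFractions(cl, dyn0))
  expect_equal(s0$percent[s0$class == "cGAMES" & s0$direction == "up"], 0)
})

test_that("display rounding is half-up, not banker's", {
  expect_equal(primeseq:::roundHalfUp(29.5), 30)
  expect_equal(primeseq:::roundHalfUp(30.5), 31)
  expect_equal(primeseq:::roundHalfUp(100 * 76 / 256), 30)
  expect_equal(primeseq:::roundHalfUp(100 * 58 / 145), 40)
})

test_that("priming counts never exceed class sizes", {
  set.seed(41)
  genes <- paste0("g", 1:200)
  shuf <- sample(genes)
  cl <- new("GameClassification",
            up = list(cGAME = shuf[1:50], cGAMES = shuf[51:80],
                      cGAMS = character(0)),
            down = list(cGAME = shuf[81:120], cGAMES = character(0),
                        cGAMS = shuf[121:130]),
            groups = c("ELE_alone", "ELE_3min", "SED_3min", "SED_10min"))
  dyn <- list(
    H4K8ac = new("MarkDynamics", antibody = "H4K8ac",
                 new = sample(genes, 80), lost = sample(setdiff(
                   genes, character(0)), 0), shared = character(0)),
    H3K27me3 = new("MarkDynamics", antibody = "H3K27me3",
                   new = sample(genes, 20), lost = character(0),
                   shared = character(0)))
  s <- primingSummary(primingFractions(cl, dyn))
  expect_true(all(s$n_primed <= s$n_total))
  expect_true(all(s$n_primed <= s$n_mark_gain + s$n_mark_loss))
  ok <- !is.na(s$fraction)
  expect_true(all(s$fraction[ok] >= 0 & s$fraction[ok] <= 1))
})

test_that("z-scores and sign concordance follow the hand computation", {
  m <- matrix(c(1, 0, 1), 1,
              dimnames = list("g1", c("ELE_3min", "SED_3min", "SED_10min")))
  zc <- zscoreConcordance(m, "g1")
  expect_equal(unname(zc$zscores[1, ]), c(0.5773503, -1.1547005, 0.5773503),
               tolerance = 1e-6)
  expect_equal(zc$concordance, 1)

  # constant row excluded
  m2 <- rbind(m, g2 = c(2, 2, 2))
  zc2 <- zscoreConcordance(m2, c("g1", "g2"))
  expect_equal(nrow(zc2$zscores), 1L)
  expect_equal(zc2$n_excluded, 1L)

  # planted: every primed gene moves with the sedentary-threshold direction
  # (comparable magnitude in both threshold groups, so both z-scores sit on
  # the same side of the row mean)
  set.seed(42)
  n <- 50
  e3 <- runif(n, 0.5, 2)
  lfc <- cbind(ELE_3min = e3, SED_3min = rnorm(n, 0, 0.05),
               SED_10min = e3 * runif(n, 0.8, 1.25))
  rownames(lfc) <- paste0("g", 1:n)
  zc3 <- zscoreConcordance(lfc, rownames(lfc))
  expect_equal(zc3$concordance, 1)

  # all-constant input -> concordance NA
  m3 <- matrix(1, 2, 3, dimnames = list(c("a", "b"),
                                        colnames(m)))
  expect_true(is.na(zscoreConcordance(m3, c("a", "b"))$concordance))
})
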