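# Synthetic paired study generator: random genomes, NB count matrices with
# planted condition-specific log fold changes, and sparse coverage tracks
# with planted condition-specific peaks linked to the planted DEGs (the
# priming structure).  Every generator is deterministic for a fixed seed,
# and every downstream stage can be scored against the returned truth.

#' Simulation parameters
#'
#' Defaults describe the emulated study: NB counts with log-normal
#' baseline means and dispersions, planted |log2FC| at least 0.2 above the
#' calling threshold, an unbalanced n = 3 ELE vs n = 2 SED two-group
#' design, and very sparse CUT&RUN-like coverage (background 0.002 expected
#' reads per 10-bp tile, i.e. 0.2 reads/kb) with strong planted enrichment.
#'
#' @param nGenes Number of genes.
#' @param nPerGroup Samples per group for [simulateCounts()]; a named
#'   vector is honored per group level.
#' @param baselineMeanlog,baselineSdlog Log-normal baseline mean counts.
#' @param dispersionMeanlog,dispersionSdlog Log-normal per-gene NB
#'   dispersions.
#' @param dispersionFixed Fixed dispersion overriding the log-normal draw
#'   (e.g. ~0 for the Poisson limit).
#' @param degFraction Fraction of genes planted as DEGs.
#' @param lfcMin,lfcMax Planted |log2FC| range; the default floor is
#'   log2(1.3) + 0.2, keeping planted effects clear of the call threshold.
#' @param libSizeSdlog Log-normal spread of per-sample library size factors.
#' @param tileWidth Coverage tile width in bp.
#' @param backgroundRate Expected background reads per tile.
#' @param iggRate Expected reads per tile for IgG tracks.
#' @param enrichmentFold Planted peak rate as a multiple of the background
#'   rate (of the unit tile rate when the background is zero).
#' @param peakWidthMeanlog,peakWidthSdlog Log-normal planted peak widths (bp).
#' @return A list of class "SimulationParams".
#' @export
simulationParams <- function(nGenes = 1000,
                             nPerGroup = c(ELE = 3, SED = 2),
                             baselineMeanlog = log(200), baselineSdlog = 1,
                             dispersionMeanlog = log(0.05),
                             dispersionSdlog = 0.5,
                             dispersionFixed = NULL,
                             degFraction = 0.1,
                             lfcMin = log2(1.3) + 0.2, lfcMax = 2,
                             libSizeSdlog = 0.15,
                             tileWidth = 10,
                             backgroundRate = 0.002,
                             iggRate = 0.002,
                             enrichmentFold = 2500,
                             peakWidthMeanlog = log(500),
                             peakWidthSdlog = 0.25) {
  p <- as.list(environment())
  stopifnot(nGenes >= 0, all(unlist(nPerGroup) > 0), degFraction >= 0,
            degFraction <= 1, lfcMin > 0, lfcMax >= lfcMin, tileWidth >= 1,
            backgroundRate >= 0, iggRate >= 0, enrichmentFold > 0)
  class(p) <- "SimulationParams"
  p
}

#' Generate a random gene annotation
#'
#' Non-overlapping genes with 2-10 exons each, all pairwise gaps at least
#' `minGap` bp, distributed over the supplied chromosomes proportionally to
#' their lengths.  Deterministic for a fixed seed.
#'
#' @param nGenes Number of genes.
#' @param chromSizes Named chromosome lengths in bp.
#' @param seed Random seed.
#' @param minGap Minimum inter-gene gap (default 10 kb).
#' @param geneWidthRange Gene body width range in bp.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
makeGenome <- function(nGenes, chromSizes, seed = 1, minGap = 10000,
                       geneWidthRange = c(1000, 5000)) {
  set.seed(seed)
  chroms <- names(chromSizes)
  if (nGenes == 0) {
    g <- GRanges(seqinfo = Seqinfo(chroms,
                                   seqlengths = as.integer(chromSizes)))
    g$gene_id <- character(0)
    return(GenomeAnnotation(g))
  }
  # apportion genes to chromosomes by length
  share <- chromSizes / sum(chromSizes)
  n_c <- floor(nGenes * share)
  rem <- nGenes - sum(n_c)
  if (rem > 0) {
    o <- order(nGenes * share - n_c, decreasing = TRUE)
    n_c[o[seq_len(rem)]] <- n_c[o[seq_len(rem)]] + 1
  }
  all_genes <- list()
  for (ci in seq_along(chroms)) {
    nc <- n_c[ci]
    if (nc == 0) next
    size <- chromSizes[ci]
    w <- as.integer(round(runif(nc, geneWidthRange[1], geneWidthRange[2])))
    slack <- size - sum(w) - (nc + 1) * minGap
    if (slack < 0)
      stop("cannot place ", nc, " genes on '", chroms[ci],
           "' with gaps >= ", minGap, " bp (capacity error)")
    cuts <- sort(runif(nc + 1))
    extra <- floor(cuts / sum(cuts) * slack)
    starts <- cumsum(c(minGap + extra[1] + 1,
                       head(w, -1) + minGap + extra[-1][seq_len(nc - 1)]))
    strand <- sample(c("+", "-"), nc, replace = TRUE)
    all_genes[[ci]] <- data.frame(
      chrom = chroms[ci], start = starts, end = starts + w - 1L,
      strand = strand, stringsAsFactors = FALSE)
  }
  gd <- do.call(rbind, all_genes)
  gd$gene_id <- sprintf("gene_%04d", seq_len(nrow(gd)))
  genes <- GRanges(gd$chrom, IRanges(gd$start, gd$end), strand = gd$strand,
                   gene_id = gd$gene_id,
                   seqinfo = Seqinfo(chroms,
                                     seqlengths = as.integer(chromSizes)))
  # exon structure: k exons, exon at each gene end, alternating segments
  exon_list <- lapply(seq_along(genes), function(i) {
    s <- start(genes)[i]; e <- end(genes)[i]
    k <- sample(2:10, 1)
    n_seg <- 2 * k - 1
    cutpts <- sort(sample(seq(s + 1L, e - 1L), n_seg - 1))
    bounds <- c(s, cutpts, e + 1L)
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1] - 1L
    is_exon <- seq_len(n_seg) %% 2 == 1
    cbind(seg_start[is_exon], seg_end[is_exon])
  })
  n_ex <- vapply(exon_list, nrow, integer(1))
  flat <- do.call(rbind, exon_list)
  exon_gr <- GRanges(rep(seqnames(genes), n_ex),
                     IRanges(flat[, 1], flat[, 2]),
                     strand = rep(strand(genes), n_ex),
                     seqinfo = seqinfo(genes))
  exons <- split(exon_gr, factor(rep(genes$gene_id, n_ex),
                                 levels = genes$gene_id))
  GenomeAnnotation(genes, exons = exons)
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Counts ~ NB(mean = s_j * mu_g * 2^lfc(g, group_j), dispersion alpha_g).
#' Planted DEGs (a `degFraction` of genes, against the reference level)
#' get |log2FC| drawn from [lfcMin, lfcMax] with random sign; alternatively
#' a full genes x groups `lfcMatrix` can be supplied (reference column
#' implied zero).  Every group needs at least 2 samples.
#'
#' @param genome A \linkS4class{GenomeAnnotation} (or a vector of gene ids).
#' @param design data.frame with a `group` column (plus any extra columns);
#'   when NULL a two-group ELE/SED design is built from
#'   `params$nPerGroup`.
#' @param params A [simulationParams()] list.
#' @param seed Random seed.
#' @param lfcMatrix Optional genes x groups matrix of planted log2 fold
#'   changes (columns = non-reference group levels).
#' @param refLevel Reference group (default the first level).
#' @return list: `se` (SummarizedExperiment with `counts` and the design as
#'   colData), `truth` (data.frame with per-gene baseline mean, dispersion
#'   and planted lfc per non-reference group).
#' @export
simulateCounts <- function(genome, design = NULL, params = simulationParams(),
                           seed = 1, lfcMatrix = NULL, refLevel = NULL) {
  set.seed(seed)
  gene_ids <- if (is(genome, "GenomeAnnotation"))
    geneModels(genome)$gene_id else as.character(genome)
  n <- length(gene_ids)
  if (is.null(design)) {
    np <- params$nPerGroup
    design <- data.frame(
      sample_id = unlist(lapply(names(np), function(g)
        paste0(g, "_", seq_len(np[[g]])))),
      group = rep(names(np), unlist(np)), stringsAsFactors = FALSE)
    rownames(design) <- design$sample_id
  }
  grp <- as.factor(design$group)
  if (any(table(grp) < 2))
    stop("every group needs at least 2 samples (design error)")
  if (is.null(refLevel)) refLevel <- levels(grp)[1]
  others <- setdiff(levels(grp), refLevel)
  mu <- rlnorm(n, params$baselineMeanlog, params$baselineSdlog)
  alpha <- if (!is.null(params$dispersionFixed))
    rep(params$dispersionFixed, n)
  else rlnorm(n, params$dispersionMeanlog, params$dispersionSdlog)
  if (is.null(lfcMatrix)) {
    lfcMatrix <- matrix(0, n, length(others),
                        dimnames = list(gene_ids, others))
    n_deg <- round(params$degFraction * n)
    if (n_deg > 0 && length(others)) {
      idx <- sample(n, n_deg)
      for (g in others)
        lfcMatrix[idx, g] <- sample(c(-1, 1), n_deg, replace = TRUE) *
          runif(n_deg, params$lfcMin, params$lfcMax)
    }
  } else {
    lfcMatrix <- lfcMatrix[gene_ids, , drop = FALSE]
  }
  sf <- rlnorm(nrow(design), 0, params$libSizeSdlog)
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(gene_ids, rownames(design)))
  for (j in seq_len(nrow(design))) {
    g <- as.character(grp[j])
    lfc_j <- if (g == refLevel) 0 else lfcMatrix[, g]
    mean_j <- sf[j] * mu * 2^lfc_j
    counts[, j] <- rnbinom(n, size = 1 / alpha, mu = mean_j)
  }
  truth <- data.frame(gene_id = gene_ids, baseline_mean = mu,
                      dispersion = alpha, stringsAsFactors = FALSE)
  for (g in colnames(lfcMatrix)) truth[[paste0("lfc_", g)]] <- lfcMatrix[, g]
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = S4Vectors::DataFrame(design))
  list(se = se, truth = truth)
}

#' Simulate a sparse coverage track
#'
#' Background depth ~ Poisson(backgroundRate) per tile (iggRate for IgG);
#' tiles inside planted peaks whose condition set includes `condition` draw
#' depth ~ Poisson(enrichmentFold * backgroundRate) instead (the unit tile
#' rate stands in for a zero background), so fold = 1 reproduces the
#' background exactly.  IgG tracks are background only.  The result is
#' run-length encoded, zero runs retained.
#'
#' @param genome A \linkS4class{GenomeAnnotation} (supplies chromosome
#'   sizes).
#' @param peaks data.frame of planted peaks: chrom, start, end, antibody,
#'   conditions (comma-separated condition set).  May be empty.
#' @param antibody Track antibody ("H4K8ac", "H3K27me3" or "IgG").
#' @param condition Track condition ("ELE" or "SED").
#' @param params A [simulationParams()] list.
#' @param seed Random seed.
#' @return GRanges coverage with a `score` column (depth per tile).
#' @export
simulateCoverage <- function(genome, peaks, antibody, condition,
                             params = simulationParams(), seed = 1) {
  set.seed(seed)
  sizes <- chromSizes(genome)
  tw <- params$tileWidth
  rate <- if (antibody == "IgG") params$iggRate else params$backgroundRate
  peak_rate <- params$enrichmentFold *
    (if (params$backgroundRate > 0) params$backgroundRate else 1)
  use_peaks <- if (antibody != "IgG" && nrow(peaks)) {
    sel <- peaks$antibody == antibody &
      vapply(strsplit(peaks$conditions, ","), function(cs)
        condition %in% cs, logical(1))
    peaks[sel, , drop = FALSE]
  } else peaks[0, , drop = FALSE]
  if (nrow(use_peaks)) {
    bad <- !(use_peaks$chrom %in% names(sizes)) |
      use_peaks$end > sizes[use_peaks$chrom] | use_peaks$start < 1
    if (any(bad)) stop("planted peak outside chromosome bounds")
  }
  out <- list()
  for (chrom in names(sizes)) {
    n_tiles <- ceiling(sizes[[chrom]] / tw)
    depth <- rpois(n_tiles, rate)
    pk <- use_peaks[use_peaks$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      t0 <- (pk$start[i] - 1L) %/% tw + 1L
      t1 <- (pk$end[i] - 1L) %/% tw + 1L
      depth[t0:t1] <- rpois(t1 - t0 + 1L, peak_rate)
    }
    r <- rle(depth)
    ends <- cumsum(r$lengths) * tw
    ends[length(ends)] <- min(ends[length(ends)], sizes[[chrom]])
    starts <- c(1, head(cumsum(r$lengths), -1) * tw + 1)
    out[[chrom]] <- GRanges(chrom, IRanges(starts, ends), score = r$values,
                            seqinfo = Seqinfo(names(sizes),
                                              as.integer(sizes)))
  }
  sort(do.call(c, unname(out)))
}

.FIXTURE_GROUPS <- c("baseline", "ELE_alone", "ELE_3min", "SED_3min",
                     "SED_10min")

#' Generate a complete synthetic priming study
#'
#' Builds a genome, a five-group count matrix (baseline, ELE-alone,
#' ELE + 3 min, SED + 3 min, SED + 10 min learning) with planted
#' cGAME/cGAMES/cGAMS class structure, and H4K8ac/H3K27me3/IgG coverage
#' tracks for the ELE and SED conditions with planted gained/lost/shared
#' promoter peaks tied to the planted classes.  Planted priming fractions
#' default to the emulated study's printed values: 40% of cGAMES-up and
#' 30% of cGAME-up genes gain H4K8ac; ~6% of the down-classes gain
#' H3K27me3.
#'
#' In the noise-free setting the NB dispersion drops to its floor, the
#' sequencing depth scales a hundredfold (the noise -> 0 limit of the count
#' model), and coverage background vanishes, so downstream recovery of the
#' planted structure is exact.
#'
#' @param seed Random seed.
#' @param nGenes Number of genes (default 1000).
#' @param nPerGroup Mice per behavioral group (default 6).
#' @param params A [simulationParams()] list for the noise model.
#' @param classSizes Named list with `up` and `down` integer vectors
#'   (cGAME, cGAMES, cGAMS planted class sizes).
#' @param primingFractionUp Planted fraction of cGAMES-up/cGAME-up genes
#'   given a new H4K8ac peak (length 2: cGAMES, cGAME).
#' @param primingFractionDown Same for new H3K27me3 at the down classes.
#' @param noiseFree Use the exact-recovery limit described above.
#' @return list: `genome`, `counts` (SummarizedExperiment), `tracks`
#'   (named list of coverage GRanges, "antibody.condition"), `truth`
#'   (list: `genes` data.frame with intended_class/direction/mark status,
#'   `peaks` planted-peak data.frame, `lfc` genes x groups matrix,
#'   `primingFractions` the planted fractions), `params`.
#' @export
makeFixtureStudy <- function(seed = 1, nGenes = 1000, nPerGroup = 6,
                             params = simulationParams(nGenes = nGenes),
                             classSizes = list(
                               up = c(cGAME = 100, cGAMES = 60, cGAMS = 40),
                               down = c(cGAME = 120, cGAMES = 80, cGAMS = 40)),
                             primingFractionUp = c(cGAMES = 0.40, cGAME = 0.30),
                             primingFractionDown = c(cGAMES = 0.063,
                                                     cGAME = 0.064),
                             noiseFree = FALSE) {
  set.seed(seed)
  if (noiseFree) {
    params$dispersionFixed <- 1e-8
    params$baselineMeanlog <- params$baselineMeanlog + log(100)
    params$backgroundRate <- 0
    params$iggRate <- 0
    params$enrichmentFold <- 10
  }
  # genome sized to hold the genes with 10 kb gaps
  per_gene <- 5000 + 10000
  total <- ceiling(nGenes * per_gene * 1.1) + 40000
  chromSizes <- c(chr1 = ceiling(total * 0.55), chr2 = ceiling(total * 0.45))
  genome <- makeGenome(nGenes, chromSizes, seed = seed + 1)
  gene_ids <- geneModels(genome)$gene_id

  # ---- plant classes and extra DEG patterns -------------------------------
  need <- sum(unlist(classSizes)) + 60
  if (need > nGenes) stop("class sizes exceed the gene count")
  shuffled <- sample(gene_ids)
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- shuffled[seq_len(k)]
    shuffled <<- shuffled[-seq_len(k)]
    out
  }
  genes <- data.frame(gene_id = gene_ids, intended_class = "none",
                      direction = "none", stringsAsFactors = FALSE)
  rownames(genes) <- gene_ids
  for (dir in c("up", "down")) for (cls in names(classSizes[[dir]])) {
    ids <- take(classSizes[[dir]][[cls]])
    genes[ids, "intended_class"] <- cls
    genes[ids, "direction"] <- dir
  }
  ele_alone_only <- take(30)   # responds to exercise alone
  sed3_only <- take(30)        # responds to the subthreshold stimulus
  genes[ele_alone_only, "direction"] <- "up"
  genes[sed3_only, "direction"] <- "up"
  genes[ele_alone_only, "intended_class"] <- "none"
  genes[sed3_only, "intended_class"] <- "none"

  groups <- setdiff(.FIXTURE_GROUPS, "baseline")
  lfc <- matrix(0, nGenes, length(groups),
                dimnames = list(gene_ids, groups))
  draw <- function(k, dir) (if (dir == "up") 1 else -1) *
    runif(k, params$lfcMin, params$lfcMax)
  for (dir in c("up", "down")) {
    sel <- function(cls) genes$gene_id[genes$intended_class == cls &
                                       genes$direction == dir]
    g <- sel("cGAMES")
    lfc[g, "ELE_3min"] <- draw(length(g), dir)
    lfc[g, "SED_10min"] <- draw(length(g), dir)
    g <- sel("cGAME")
    lfc[g, "ELE_3min"] <- draw(length(g), dir)
    g <- sel("cGAMS")
    lfc[g, "SED_10min"] <- draw(length(g), dir)
  }
  lfc[ele_alone_only, "ELE_alone"] <- draw(length(ele_alone_only), "up")
  lfc[sed3_only, "SED_3min"] <- draw(length(sed3_only), "up")

  # ---- plant mark dynamics ------------------------------------------------
  genes$h4k8ac <- "absent"
  genes$h3k27me3 <- "absent"
  plant_frac <- function(pool, frac) {
    k <- round(frac * length(pool))
    if (k > 0) sample(pool, k) else character(0)
  }
  cgames_up <- genes$gene_id[genes$intended_class == "cGAMES" &
                             genes$direction == "up"]
  cgame_up <- genes$gene_id[genes$intended_class == "cGAME" &
                            genes$direction == "up"]
  cgames_dn <- genes$gene_id[genes$intended_class == "cGAMES" &
                             genes$direction == "down"]
  cgame_dn <- genes$gene_id[genes$intended_class == "cGAME" &
                            genes$direction == "down"]
  new_h4 <- c(plant_frac(cgames_up, primingFractionUp[["cGAMES"]]),
              plant_frac(cgame_up, primingFractionUp[["cGAME"]]))
  new_h3 <- c(plant_frac(cgames_dn, primingFractionDown[["cGAMES"]]),
              plant_frac(cgame_dn, primingFractionDown[["cGAME"]]))
  genes[new_h4, "h4k8ac"] <- "new"
  genes[new_h3, "h3k27me3"] <- "new"
  # marks not tied to expression (most peaks, as in real chromatin data)
  pool <- genes$gene_id[genes$h4k8ac == "absent" & genes$intended_class == "none"]
  genes[sample(pool, min(40, length(pool))), "h4k8ac"] <- "new"
  pool <- genes$gene_id[genes$h4k8ac == "absent"]
  genes[sample(pool, min(300, length(pool))), "h4k8ac"] <- "shared"
  pool <- genes$gene_id[genes$h4k8ac == "absent"]
  genes[sample(pool, min(15, length(pool))), "h4k8ac"] <- "lost"
  pool <- genes$gene_id[genes$h3k27me3 == "absent" & genes$intended_class == "none"]
  genes[sample(pool, min(30, length(pool))), "h3k27me3"] <- "new"
  pool <- genes$gene_id[genes$h3k27me3 == "absent"]
  genes[sample(pool, min(150, length(pool))), "h3k27me3"] <- "shared"
  pool <- genes$gene_id[genes$h3k27me3 == "absent" & genes$intended_class == "none"]
  genes[sample(pool, min(15, length(pool))), "h3k27me3"] <- "lost"

  # ---- planted peaks at the TSS of marked genes ---------------------------
  gm <- geneModels(genome)
  tss <- setNames(gm$tss, gm$gene_id)
  chrom_of <- setNames(as.character(seqnames(gm)), gm$gene_id)
  peak_rows <- list()
  for (ab in c("H4K8ac", "H3K27me3")) {
    col <- if (ab == "H4K8ac") "h4k8ac" else "h3k27me3"
    marked <- genes$gene_id[genes[[col]] != "absent"]
    if (!length(marked)) next
    w <- pmax(50, round(rlnorm(length(marked), params$peakWidthMeanlog,
                               params$peakWidthSdlog)))
    status <- genes[marked, col]
    conditions <- c(new = "ELE", lost = "SED", shared = "ELE,SED")[status]
    start <- pmax(1, tss[marked] - w %/% 2)
    sz <- chromSizes[chrom_of[marked]]
    end <- pmin(sz, start + w - 1)
    peak_rows[[ab]] <- data.frame(
      gene_id = marked, antibody = ab, chrom = chrom_of[marked],
      start = as.integer(start), end = as.integer(end),
      conditions = unname(conditions), stringsAsFactors = FALSE)
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(gene_id = character(0), antibody = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               conditions = character(0))
  rownames(peaks) <- NULL

  # ---- counts -------------------------------------------------------------
  design <- data.frame(
    sample_id = unlist(lapply(.FIXTURE_GROUPS, function(g)
      paste0(g, "_", seq_len(nPerGroup)))),
    group = rep(.FIXTURE_GROUPS, each = nPerGroup),
    stringsAsFactors = FALSE)
  rownames(design) <- design$sample_id
  sim <- simulateCounts(genome, design, params, seed = seed + 2,
                        lfcMatrix = lfc, refLevel = "baseline")

  # ---- coverage tracks ----------------------------------------------------
  tracks <- list()
  k <- 0
  for (ab in c("H4K8ac", "H3K27me3", "IgG")) for (cond in c("ELE", "SED")) {
    k <- k + 1
    tracks[[paste(ab, cond, sep = ".")]] <-
      simulateCoverage(genome, peaks, ab, cond, params, seed = seed + 10 + k)
  }

  list(genome = genome, counts = sim$se, tracks = tracks,
       truth = list(genes = genes, peaks = peaks, lfc = lfc,
                    countTruth = sim$truth,
                    primingFractions = list(up = primingFractionUp,
                                            down = primingFractionDown)),
       params = params, groups = .FIXTURE_GROUPS)
}

#' Score recovered classes against planted truth
#'
#' Micro-averaged precision, recall and F1 of class membership over the six
#' (class, direction) cells, plus the recovered priming fraction per up
#' class.
#'
#' @param truth The `truth` element of [makeFixtureStudy()].
#' @param classification A \linkS4class{GameClassification}.
#' @param report Optional \linkS4class{PrimingReport} for recovered
#'   priming fractions.
#' @return list: precision, recall, f1, per_class (data.frame), and (when
#'   report given) priming (data.frame of planted vs recovered fraction).
#' @export
scoreRecovery <- function(truth, classification, report = NULL) {
  g <- truth$genes
  tp <- fp <- fn <- 0
  per <- list()
  for (dir in c("up", "down")) for (cls in c("cGAME", "cGAMES", "cGAMS")) {
    planted <- g$gene_id[g$intended_class == cls & g$direction == dir]
    found <- gameClass(classification, cls, dir)
    tpi <- length(intersect(planted, found))
    tp <- tp + tpi
    fp <- fp + length(setdiff(found, planted))
    fn <- fn + length(setdiff(planted, found))
    per[[paste(cls, dir)]] <- data.frame(
      class = cls, direction = dir, planted = length(planted),
      recovered = length(found), correct = tpi, stringsAsFactors = FALSE)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(precision = precision, recall = recall, f1 = f1,
              per_class = do.call(rbind, per))
  if (!is.null(report)) {
    s <- primingSummary(report)
    planted_frac <- c(cGAMES = unname(truth$primingFractions$up["cGAMES"]),
                      cGAME = unname(truth$primingFractions$up["cGAME"]))
    rec <- s[s$direction == "up" & s$class %in% names(planted_frac), ]
    out$priming <- data.frame(
      class = rec$class,
      planted = as.numeric(planted_frac[rec$class]),
      recovered = rec$fraction, stringsAsFactors = FALSE)
  }
  out
}
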