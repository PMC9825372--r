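# Isolation-method / hemisphere comparability statistics: fixed-width
# coverage binning with CPM normalization, Spearman concordance with the
# study's significance rule (rho > 0.5 and p < 2.2e-16), and gene-length
# bias summaries with a permutation comparison between two analyses.

#' Bin a coverage track along one chromosome
#'
#' Each bin's raw value is the depth-weighted overlap with the bin
#' (conserving the track's total signal exactly); normalized values are
#' counts-per-million of the chromosome's total signal.  Zero total signal
#' yields all-zero bins with a warning.
#'
#' @param track GRanges coverage with a `score` column.
#' @param chrom Chromosome to bin.
#' @param binSize Bin width in bp (default 100, the study's setting).
#' @param chromLength Length of the chromosome; taken from seqlengths when
#'   NULL, else the last covered position.
#' @return data.frame: bin start (1-based), raw, cpm.
#' @export
binCoverage <- function(track, chrom, binSize = 100, chromLength = NULL) {
  if (binSize < 1) stop("binSize must be >= 1")
  tr <- track[as.character(seqnames(track)) == chrom]
  if (!length(tr)) stop("chromosome '", chrom, "' absent from track")
  if (is.null(chromLength)) {
    chromLength <- seqlengths(track)[chrom]
    if (is.na(chromLength)) chromLength <- max(end(tr))
  }
  n_bins <- ceiling(chromLength / binSize)
  raw <- numeric(n_bins)
  pos <- tr[tr$score > 0]
  if (length(pos)) {
    bin_lo <- (start(pos) - 1L) %/% binSize
    bin_hi <- (end(pos) - 1L) %/% binSize
    simple <- bin_lo == bin_hi
    if (any(simple)) {
      v <- tapply(width(pos)[simple] * pos$score[simple], bin_lo[simple], sum)
      idx <- as.integer(names(v)) + 1L
      raw[idx] <- raw[idx] + as.numeric(v)
    }
    for (i in which(!simple)) {     # intervals spanning bin boundaries
      s <- start(pos)[i]; e <- end(pos)[i]; d <- pos$score[i]
      bins <- (bin_lo[i]):(bin_hi[i])
      lo <- pmax(s, bins * binSize + 1L)
      hi <- pmin(e, (bins + 1L) * binSize)
      raw[bins + 1L] <- raw[bins + 1L] + (hi - lo + 1L) * d
    }
  }
  total <- sum(raw)
  if (total == 0) {
    warning("zero total signal on '", chrom, "'; CPM left at zero")
    cpm <- raw
  } else cpm <- raw / total * 1e6
  data.frame(bin_start = seq_len(n_bins) * binSize - binSize + 1L,
             raw = raw, cpm = cpm)
}

#' Spearman concordance with the study's significance rule
#'
#' Rank correlation with average ranks for ties; p from the large-sample t
#' approximation.  `passes_rule` is TRUE when rho > 0.5 and p < 2.2e-16
#' (the conventional numeric-underflow reporting bound); `p_label` renders
#' underflowed p-values as "< 2.2e-16".  Zero variance in either vector
#' gives rho NA.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return list: rho, p, p_label, n, passes_rule.
#' @export
spearmanConcordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, p_label = NA_character_,
                n = length(x), passes_rule = FALSE))
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  list(rho = rho, p = p,
       p_label = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3),
       n = length(x),
       passes_rule = isTRUE(rho > 0.5 && p < 2.2e-16))
}

#' Binned-coverage concordance between two tracks
#'
#' Bins both tracks on a shared chromosome, pairs bins by index, drops bins
#' with zero signal in both tracks (pure ties; retain with
#' `keepEmptyBins = TRUE`), and applies [spearmanConcordance()].
#'
#' @param a,b GRanges coverage tracks.
#' @param chrom Shared chromosome.
#' @param binSize Bin width in bp (default 100).
#' @param keepEmptyBins Keep bins empty in both tracks (default FALSE).
#' @return list as from [spearmanConcordance()], plus n_bins_used.
#' @export
compareTracks <- function(a, b, chrom, binSize = 100,
                          keepEmptyBins = FALSE) {
  la <- max(end(a[as.character(seqnames(a)) == chrom]), 0)
  lb <- max(end(b[as.character(seqnames(b)) == chrom]), 0)
  len <- max(la, lb,
             suppressWarnings(seqlengths(a)[chrom]),
             suppressWarnings(seqlengths(b)[chrom]), na.rm = TRUE)
  ba <- binCoverage(a, chrom, binSize, chromLength = len)
  bb <- binCoverage(b, chrom, binSize, chromLength = len)
  keep <- if (keepEmptyBins) rep(TRUE, nrow(ba)) else
    ba$raw > 0 | bb$raw > 0
  res <- spearmanConcordance(ba$cpm[keep], bb$cpm[keep])
  res$n_bins_used <- sum(keep)
  res
}

#' Gene-length bias summary of a differential-expression result
#'
#' Spearman correlation of log2 fold change with gene length, plus mean
#' LFC per length decile, quantifying the length-vs-fold-change
#' distribution comparison as statistics.
#'
#' @param de DataFrame from [nbWaldTest()] (rownames = gene ids).
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param label Label attached to the summary.
#' @return list: label, rho, p, n, decile_table (decile, mean_length,
#'   mean_lfc).
#' @export
lengthBiasSummary <- function(de, annotation, label = "analysis") {
  g <- geneModels(annotation)
  len <- setNames(width(g), g$gene_id)
  genes <- intersect(rownames(de), names(len))
  lfc <- de[genes, "log2FoldChange"]
  lg <- len[genes]
  ok <- is.finite(lfc)
  lfc <- lfc[ok]; lg <- lg[ok]
  sc <- spearmanConcordance(as.numeric(lg), lfc)
  dec <- cut(rank(lg, ties.method = "first"),
             breaks = quantile(rank(lg, ties.method = "first"),
                               probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    decile = 1:10,
    mean_length = as.numeric(tapply(lg, dec, mean)),
    mean_lfc = as.numeric(tapply(lfc, dec, mean)))
  list(label = label, rho = sc$rho, p = sc$p, n = length(lfc),
       decile_table = tab)
}

#' Permutation comparison of gene-length bias between two analyses
#'
#' Observed statistic: difference of the two Spearman correlations of LFC
#' with gene length.  Null distribution: per-gene swaps of the two
#' analyses' LFC labels.  This permutation test is an added statistic of
#' this package (the source comparison it quantifies was visual).
#'
#' @param de1,de2 DataFrames from [nbWaldTest()] over a shared gene set.
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param nPerm Number of label permutations (default 10000).
#' @param seed Seed for the permutations.
#' @return list: rho1, rho2, observed_diff, p_perm, n_perm.
#' @export
lengthBiasComparison <- function(de1, de2, annotation, nPerm = 10000,
                                 seed = 1) {
  g <- geneModels(annotation)
  len <- setNames(width(g), g$gene_id)
  genes <- Reduce(intersect, list(rownames(de1), rownames(de2), names(len)))
  l1 <- de1[genes, "log2FoldChange"]
  l2 <- de2[genes, "log2FoldChange"]
  ok <- is.finite(l1) & is.finite(l2)
  l1 <- l1[ok]; l2 <- l2[ok]
  rl <- rank(len[genes][ok])
  rho_of <- function(v) suppressWarnings(cor(rl, rank(v)))
  rho1 <- rho_of(l1)
  rho2 <- rho_of(l2)
  obs <- rho1 - rho2
  n <- length(l1)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    swap <- runif(n) < 0.5
    a1 <- ifelse(swap, l2, l1)
    a2 <- ifelse(swap, l1, l2)
    if (abs(rho_of(a1) - rho_of(a2)) >= abs(obs) - 1e-12) exceed <- exceed + 1L
  }
  list(rho1 = rho1, rho2 = rho2, observed_diff = obs,
       p_perm = (1 + exceed) / (nPerm + 1), n_perm = nPerm)
}
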