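# Peak-to-gene annotation with genomic-feature priority:
# Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream > DistalIntergenic.
# A peak is assigned the first category whose feature it overlaps by >= 1 bp;
# the gene supplying the winning feature is attached, with ties broken by
# smallest |distance to TSS| then lexicographic gene id.  Distal intergenic
# peaks are assigned the gene with the nearest TSS.

.CATEGORIES <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron",
                 "Downstream", "DistalIntergenic")

# Feature GRanges per category, each carrying gene_id.  The minimal
# annotation has no CDS, so UTRs are proxied by the first/last 10% of the
# first/last exon (strand-oriented); a gene whose model carries explicit
# `utr5`/`utr3` ranges in its metadata would be honored upstream.
annotationFeatures <- function(annotation, tssWindow = 3000,
                               downstreamWindow = 3000) {
  g <- geneModels(annotation)
  ex <- exonsByGene(annotation)
  tss_gr <- GRanges(seqnames(g), IRanges(g$tss, g$tss), strand = strand(g),
                    gene_id = g$gene_id)
  prom <- GRanges(seqnames(g),
                  IRanges(pmax(1L, g$tss - tssWindow), g$tss + tssWindow),
                  gene_id = g$gene_id)
  ex <- ex[as.character(g$gene_id)]
  exon_flat <- unlist(ex, use.names = FALSE)
  exon_gr <- granges(exon_flat)
  exon_gr$gene_id <- rep(as.character(g$gene_id), elementNROWS(ex))
  # genomically first/last exon per gene (exons are sorted within genes)
  len <- elementNROWS(ex)
  last_idx <- cumsum(len)
  first_idx <- last_idx - len + 1L
  plus <- as.character(strand(g)) == "+"
  utr <- function(which) {
    anchor5 <- which == "5"
    # the anchoring exon: 5' end of the transcript for the 5'UTR proxy,
    # 3' end for the 3'UTR proxy, swapped on minus-strand genes
    use_first <- if (anchor5) plus else !plus
    idx <- ifelse(use_first, first_idx, last_idx)
    es <- start(exon_flat)[idx]
    ee <- end(exon_flat)[idx]
    w <- pmax(1L, as.integer(floor((ee - es + 1L) * 0.1)))
    # the UTR proxy hugs the outer edge of that exon
    outer_left <- (anchor5 & plus) | (!anchor5 & !plus)
    out <- GRanges(seqnames(g),
                   IRanges(ifelse(outer_left, es, ee - w + 1L),
                           ifelse(outer_left, es + w - 1L, ee)),
                   gene_id = g$gene_id)
    seqlengths(out) <- seqlengths(g)
    out
  }
  gb <- granges(g)
  names(gb) <- g$gene_id
  introns <- psetdiff(gb, ex)
  intron_flat <- unlist(introns, use.names = FALSE)
  intron_gr <- granges(intron_flat)
  intron_gr$gene_id <- rep(as.character(g$gene_id), elementNROWS(introns))
  names(intron_gr) <- NULL
  down <- flank(granges(g), downstreamWindow, start = FALSE)
  down <- trim(down)
  down$gene_id <- g$gene_id
  feats <- list(Promoter = prom, "5'UTR" = utr("5"), "3'UTR" = utr("3"),
                Exon = exon_gr, Intron = intron_gr, Downstream = down)
  lapply(feats, function(f) { strand(f) <- "*"; f })
}

# Signed distance from a peak to a TSS: 0 when the peak covers the TSS;
# otherwise the gap from the nearest peak edge, negative when the peak lies
# upstream of the TSS in gene orientation.
signedTssDistance <- function(pk_start, pk_end, tss, geneStrand) {
  d <- ifelse(tss >= pk_start & tss <= pk_end, 0,
              ifelse(tss > pk_end, pk_end - tss, pk_start - tss))
  # d is negative when peak is left of tss; flip for minus-strand genes
  ifelse(geneStrand == "-", -d, d)
}

#' Annotate peaks with genomic-feature categories and genes
#'
#' Each peak is assigned exactly one category by priority (Promoter,
#' 5'UTR, 3'UTR, Exon, Intron, Downstream, DistalIntergenic) and exactly
#' one gene: the gene supplying the winning feature, ties broken by
#' smallest |distance to TSS| then lexicographic gene id.  The promoter is
#' the symmetric window around the TSS; distal intergenic peaks get the
#' nearest-TSS gene.  Overlap means >= 1 bp intersection.
#'
#' @param peaks A \linkS4class{PeakSet} or a GRanges of peaks.
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param tssWindow Promoter half-width in bp (default 3000).
#' @param downstreamWindow Downstream window past the gene 3' end (default
#'   3000).
#' @return data.frame: chrom, start, end, auc, category, gene_id,
#'   distance_to_tss.
#' @export
annotatePeaks <- function(peaks, annotation, tssWindow = 3000,
                          downstreamWindow = 3000) {
  pk <- if (is(peaks, "PeakSet")) peakRanges(peaks) else peaks
  g <- geneModels(annotation)
  if (length(pk) &&
      !all(as.character(seqnames(pk)) %in% names(chromSizes(annotation))))
    stop("peak on a chromosome absent from the annotation")
  feats <- annotationFeatures(annotation, tssWindow, downstreamWindow)
  n <- length(pk)
  category <- rep("DistalIntergenic", n)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  tss <- setNames(g$tss, g$gene_id)
  strands <- setNames(as.character(strand(g)), g$gene_id)
  chrom_g <- setNames(as.character(seqnames(g)), g$gene_id)
  unassigned <- rep(TRUE, n)
  pk_nostrand <- granges(pk)
  strand(pk_nostrand) <- "*"
  for (cat in names(feats)) {
    if (!any(unassigned)) break
    f <- feats[[cat]]
    hits <- findOverlaps(pk_nostrand[unassigned], f, ignore.strand = TRUE)
    if (!length(hits)) next
    idx_un <- which(unassigned)
    qh <- idx_un[queryHits(hits)]
    gid <- f$gene_id[subjectHits(hits)]
    d <- signedTssDistance(start(pk)[qh], end(pk)[qh], tss[gid],
                           strands[gid])
    # per peak: smallest |distance|, then lexicographic gene id
    o <- order(qh, abs(d), gid)
    firsts <- !duplicated(qh[o])
    sel <- o[firsts]
    category[qh[sel]] <- cat
    gene[qh[sel]] <- gid[sel]
    dist[qh[sel]] <- d[sel]
    unassigned[qh[sel]] <- FALSE
  }
  if (any(unassigned)) {
    idx <- which(unassigned)
    for (i in idx) {
      same_chrom <- chrom_g == as.character(seqnames(pk))[i]
      cand <- names(tss)[same_chrom]
      if (!length(cand)) cand <- names(tss)
      d <- signedTssDistance(start(pk)[i], end(pk)[i], tss[cand],
                             strands[cand])
      o <- order(abs(d), cand)
      gene[i] <- cand[o[1]]
      dist[i] <- d[o[1]]
    }
  }
  data.frame(chrom = as.character(seqnames(pk)), start = start(pk),
             end = end(pk), auc = if (!is.null(pk$auc)) pk$auc else NA_real_,
             category = factor(category, levels = .CATEGORIES),
             gene_id = gene, distance_to_tss = dist,
             stringsAsFactors = FALSE)
}

#' Genomic-region distribution of annotated peaks
#'
#' @param annotated data.frame from [annotatePeaks()].
#' @return data.frame with count and fraction per category (all seven
#'   categories listed; fractions sum to 1).
#' @export
regionDistribution <- function(annotated) {
  if (!nrow(annotated)) stop("no annotated peaks; distribution undefined")
  counts <- table(factor(annotated$category, levels = .CATEGORIES))
  data.frame(category = .CATEGORIES, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotated),
             stringsAsFactors = FALSE)
}

#' Gene-level peak presence per antibody and condition
#'
#' A gene is present for an (antibody, condition) pair iff at least one
#' peak of that pair annotates to it, in any category.
#'
#' @param annotatedList Named list of data.frames from [annotatePeaks()];
#'   names are "antibody.condition" labels (e.g. "H4K8ac.ELE").
#' @return Named list of unique gene-id vectors.
#' @export
genePeakPresence <- function(annotatedList) {
  lapply(annotatedList, function(a) sort(unique(a$gene_id)))
}
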