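#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames seqlevels seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats rnbinom rpois rlnorm runif cor.test pchisq pnorm
#'   model.matrix p.adjust setNames pf lm.fit dnbinom
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# GenomeAnnotation: one transcript model per gene over a fixed set of
# chromosomes.  Gene bodies live in a GRanges (with a `gene_id` column and a
# precomputed `tss` column); exon structure is a GRangesList named by gene id.
# Chromosome sizes are carried as seqlengths on both slots.
# ---------------------------------------------------------------------------

#' GenomeAnnotation: gene models plus chromosome sizes
#'
#' Container for a gene-level annotation: one transcript model per gene
#' (the longest, if the source had several), exon structure, and chromosome
#' sizes.  Coordinates are 1-based closed GRanges internally; conversion
#' to/from 0-based half-open text formats (BED, bedGraph) happens only at
#' I/O boundaries.
#'
#' @slot genes GRanges of gene bodies with metadata columns \code{gene_id}
#'   and \code{tss} (the transcription start site: \code{start} on \code{+}
#'   genes, \code{end} on \code{-} genes).
#' @slot exons GRangesList of exons, named by \code{gene_id}, each sorted and
#'   non-overlapping within a gene.
#'
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (is.null(g$gene_id)) return("genes must carry a 'gene_id' column")
  if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene_id")
  if (length(g)) {
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    sl <- seqlengths(g)
    if (any(is.na(sl))) msg <- c(msg, "all chromosomes must have a known size")
    else if (any(end(g) > sl[as.character(seqnames(g))] | start(g) < 1))
      msg <- c(msg, "gene coordinates outside chromosome bounds")
    if (!identical(sort(names(object@exons)), sort(as.character(g$gene_id))))
      msg <- c(msg, "exons must be named by gene_id, one entry per gene")
    # exons contained in the gene body, sorted, disjoint
    ex <- object@exons[as.character(g$gene_id)]
    n_ex <- lengths(ex)
    if (any(n_ex == 0)) msg <- c(msg, "every gene needs at least one exon")
    rng <- unlist(range(ex), use.names = FALSE)
    if (length(rng) == length(g) &&
        (any(start(rng) < start(g)) || any(end(rng) > end(g))))
      msg <- c(msg, "exon outside gene body")
    if (any(sum(width(reduce(ex))) != sum(width(ex))))
      msg <- c(msg, "exons overlap within a gene")
    tss_exp <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    if (!identical(as.integer(g$tss), as.integer(tss_exp)))
      msg <- c(msg, "tss inconsistent with strand rule")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes GRanges with `gene_id` metadata column; seqlengths must be set
#'   (or supply `chromSizes`).  A `tss` column is computed if absent.
#' @param exons GRangesList named by gene id; defaults to single-exon models
#'   spanning each gene body.
#' @param chromSizes optional named vector of chromosome lengths (bp).
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genes, exons = NULL, chromSizes = NULL) {
  if (!is.null(chromSizes)) {
    # out-of-bound ranges surface as a validity error, not a GRanges warning
    genes <- suppressWarnings(
      GRanges(seqnames(genes), ranges(genes), strand = strand(genes),
              gene_id = genes$gene_id,
              seqinfo = Seqinfo(names(chromSizes),
                                seqlengths = as.integer(chromSizes))))
  }
  genes$tss <- ifelse(as.character(strand(genes)) == "+",
                      start(genes), end(genes))
  if (is.null(exons)) {
    exons <- split(granges(genes), genes$gene_id)
  }
  exons <- sort(exons[as.character(genes$gene_id)])
  seqlengths(exons) <- seqlengths(genes)
  new("GenomeAnnotation", genes = genes, exons = exons)
}

#' @describeIn GenomeAnnotation Gene bodies as a GRanges.
#' @param x,object A GenomeAnnotation.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @export
setMethod("geneModels", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation Exons grouped by gene.
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))
#' @export
setMethod("exonsByGene", "GenomeAnnotation", function(x) x@exons)

#' @describeIn GenomeAnnotation Named chromosome lengths (bp).
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @export
setMethod("chromSizes", "GenomeAnnotation", function(x) seqlengths(x@genes))

#' @describeIn GenomeAnnotation TSS positions, named by gene id.
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))
#' @export
setMethod("tssPositions", "GenomeAnnotation", function(x)
  setNames(x@genes$tss, x@genes$gene_id))

setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genes), "genes on",
      length(seqlengths(object@genes)), "chromosome(s)\n")
  if (length(object@genes))
    cat("  gene length range:", paste(range(width(object@genes)),
        collapse = "-"), "bp\n")
})

# ---------------------------------------------------------------------------
# PeakSet: called signal blocks plus the thresholding metadata that produced
# them (SEACR-style sparse enrichment calling).
# ---------------------------------------------------------------------------

#' PeakSet: called sparse-enrichment peaks
#'
#' Signal blocks retained by AUC thresholding, with the calling metadata.
#' The `peaks` GRanges carries `auc` (total depth x length of the block) and
#' `max_depth` columns.
#'
#' @slot peaks GRanges with `auc` and `max_depth` metadata columns.
#' @slot mode "stringent" (AUC and max-depth double gate) or "relaxed"
#'   (AUC only).
#' @slot thresholdType "numeric" (top-fraction) or "control" (IgG scan).
#' @slot numericFraction fraction used in numeric mode (NA otherwise).
#' @slot aucThreshold the AUC threshold actually applied.
#' @slot empiricalFDR control blocks over threshold / target blocks over
#'   threshold (NA in numeric mode).
#' @slot sampleId identifier of the originating sample.
#' @export
setClass("PeakSet",
  representation(peaks = "GRanges", mode = "character",
                 thresholdType = "character", numericFraction = "numeric",
                 aucThreshold = "numeric", empiricalFDR = "numeric",
                 sampleId = "character"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (!object@mode %in% c("stringent", "relaxed"))
    msg <- c(msg, "mode must be 'stringent' or 'relaxed'")
  if (!object@thresholdType %in% c("numeric", "control"))
    msg <- c(msg, "thresholdType must be 'numeric' or 'control'")
  p <- object@peaks
  if (length(p)) {
    if (is.null(p$auc) || is.null(p$max_depth))
      msg <- c(msg, "peaks need 'auc' and 'max_depth' columns")
    else if (!is.na(object@aucThreshold) && any(p$auc < object@aucThreshold))
      msg <- c(msg, "peak below the AUC threshold")
    if (!isDisjoint(p)) msg <- c(msg, "peaks must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PeakSet Retained peaks as a GRanges.
#' @param x,object A PeakSet.
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @describeIn PeakSet The applied AUC threshold.
#' @export
setGeneric("aucThreshold", function(x) standardGeneric("aucThreshold"))
#' @export
setMethod("aucThreshold", "PeakSet", function(x) x@aucThreshold)

#' @describeIn PeakSet Empirical FDR from IgG-control thresholding.
#' @export
setGeneric("empiricalFDR", function(x) standardGeneric("empiricalFDR"))
#' @export
setMethod("empiricalFDR", "PeakSet", function(x) x@empiricalFDR)

#' @describeIn PeakSet TRUE unless control-mode empirical FDR exceeds 0.1.
#' @param threshold QC cutoff on the empirical FDR.
#' @export
setGeneric("qcPass", function(x, threshold = 0.1) standardGeneric("qcPass"))
#' @export
setMethod("qcPass", "PeakSet", function(x, threshold = 0.1) {
  if (x@thresholdType != "control" || is.na(x@empiricalFDR)) return(TRUE)
  x@empiricalFDR <= threshold
})

setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s': %d peaks (%s, %s threshold %.4g",
              object@sampleId, length(object@peaks), object@mode,
              object@thresholdType, object@aucThreshold))
  if (object@thresholdType == "control")
    cat(sprintf(", empirical FDR %.3g", object@empiricalFDR))
  cat(")\n")
})

# ---------------------------------------------------------------------------
# DEResult: per-gene differential-expression table (a DataFrame subclass in
# the DESeqResults mold).
# ---------------------------------------------------------------------------

#' DEResult: per-gene differential-expression results
#'
#' A DataFrame with columns baseMean (mean of normalized counts),
#' log2FoldChange, lfcSE (both log2 scale), stat (Wald z or LRT
#' chi-squared), pvalue and padj (BH over the non-NA p-values).  The test
#' type is stored in \code{metadata(x)$test}.  Genes that were all-zero or
#' did not converge carry NA statistics and are excluded from the BH batch.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue", "padj")
  if (!all(need %in% colnames(object)))
    return(paste("missing column(s):",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  p <- object$pvalue; q <- object$padj
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  ok <- !is.na(p) & !is.na(q)
  if (any(q[ok] < p[ok] - 1e-12))
    return("padj must be >= pvalue component-wise")
  TRUE
})

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult (%s test): %d genes, %d with p < 0.05, %d NA\n",
              S4Vectors::metadata(object)$test %||% "?", nrow(object),
              sum(object$pvalue < 0.05, na.rm = TRUE),
              sum(is.na(object$pvalue))))
  callNextMethod()
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# DEGSets: thresholded up/down gene sets for one contrast.
# ---------------------------------------------------------------------------

#' DEGSets: called differentially expressed gene sets
#'
#' Up- and down-regulated gene ids for one contrast under explicit
#' thresholds.  The default calling rule is strict: |log2FC| > lfcCut and
#' p < pCut.
#'
#' @slot up,down character vectors of gene ids (disjoint).
#' @slot contrast label of the comparison.
#' @slot lfcCut,pCut thresholds used.
#' @export
setClass("DEGSets",
  representation(up = "character", down = "character", contrast = "character",
                 lfcCut = "numeric", pCut = "numeric"))

setValidity("DEGSets", function(object) {
  if (length(intersect(object@up, object@down)))
    "up and down sets must be disjoint" else TRUE
})

#' @describeIn DEGSets Upregulated gene ids.
#' @param x,object A DEGSets.
#' @export
setGeneric("degUp", function(x) standardGeneric("degUp"))
#' @export
setMethod("degUp", "DEGSets", function(x) x@up)

#' @describeIn DEGSets Downregulated gene ids.
#' @export
setGeneric("degDown", function(x) standardGeneric("degDown"))
#' @export
setMethod("degDown", "DEGSets", function(x) x@down)

setMethod("show", "DEGSets", function(object) {
  cat(sprintf("DEGSets '%s': %d up / %d down (|log2FC| > %.4f, p < %g)\n",
              object@contrast, length(object@up), length(object@down),
              object@lfcCut, object@pCut))
})

# ---------------------------------------------------------------------------
# MarkDynamics: gene-level gain/loss/persistence of one histone mark
# between ELE and sedentary conditions.
# ---------------------------------------------------------------------------

#' MarkDynamics: gained, lost and shared mark presence per gene
#'
#' Gene-level dynamics of one antibody's peaks between exercised (ELE) and
#' sedentary (SED) conditions: `new` = present only after ELE, `lost` =
#' present only in SED, `shared` = present in both.
#'
#' @slot antibody mark name (e.g. "H4K8ac").
#' @slot new,lost,shared disjoint character vectors of gene ids.
#' @export
setClass("MarkDynamics",
  representation(antibody = "character", new = "character",
                 lost = "character", shared = "character"))

setValidity("MarkDynamics", function(object) {
  sets <- list(object@new, object@lost, object@shared)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      return("new, lost and shared must be pairwise disjoint")
  TRUE
})

setMethod("show", "MarkDynamics", function(object) {
  cat(sprintf("MarkDynamics [%s]: %d new / %d lost / %d shared genes\n",
              object@antibody, length(object@new), length(object@lost),
              length(object@shared)))
})

# ---------------------------------------------------------------------------
# GameClassification: cGAME / cGAMES / cGAMS gene sets per direction.
# ---------------------------------------------------------------------------

#' GameClassification: candidate memory-gene classes
#'
#' Set-algebra classification of genes over the four behavioral groups'
#' DEG sets (all relative to the no-exercise/no-learning baseline):
#' \itemize{
#'   \item cGAMES: significant in both threshold-learning groups
#'     (ELE + 3 min and SED + 10 min);
#'   \item cGAME: significant in ELE + 3 min but in no other group;
#'   \item cGAMS: significant in SED + 10 min but in no other group.
#' }
#' Directions (up/down) are classified independently.
#'
#' @slot up,down named lists with elements `cGAME`, `cGAMES`, `cGAMS`
#'   (character vectors of gene ids).
#' @slot groups the group labels used.
#' @export
setClass("GameClassification",
  representation(up = "list", down = "list", groups = "character"))

setValidity("GameClassification", function(object) {
  for (dir in list(object@up, object@down)) {
    if (!all(c("cGAME", "cGAMES", "cGAMS") %in% names(dir)))
      return("each direction needs cGAME, cGAMES and cGAMS elements")
    if (length(intersect(dir$cGAME, dir$cGAMES)) ||
        length(intersect(dir$cGAME, dir$cGAMS)))
      return("cGAME must be disjoint from cGAMES and cGAMS within a direction")
  }
  TRUE
})

#' @describeIn GameClassification Extract one class.
#' @param x,object A GameClassification.
#' @param class One of "cGAME", "cGAMES", "cGAMS".
#' @param direction "up" or "down".
#' @export
setGeneric("gameClass", function(x, class, direction = "up")
  standardGeneric("gameClass"))
#' @export
setMethod("gameClass", "GameClassification", function(x, class,
                                                      direction = "up") {
  direction <- match.arg(direction, c("up", "down"))
  class <- match.arg(class, c("cGAME", "cGAMES", "cGAMS"))
  slot(x, direction)[[class]]
})

setMethod("show", "GameClassification", function(object) {
  cat("GameClassification (vs baseline):\n")
  for (d in c("up", "down")) {
    s <- slot(object, d)
    cat(sprintf("  %-4s cGAME: %d  cGAMES: %d  cGAMS: %d\n", d,
                length(s$cGAME), length(s$cGAMES), length(s$cGAMS)))
  }
})

# ---------------------------------------------------------------------------
# PrimingReport: mark-dynamics fractions per class, plus z-score concordance.
# ---------------------------------------------------------------------------

#' PrimingReport: priming fractions and z-score concordance
#'
#' Per class and direction: how many genes carry an ELE-induced permissive
#' change (new H4K8ac or lost H3K27me3; for down-classes, new H3K27me3 or
#' lost H4K8ac), with exact fractions and display percentages
#' (round-half-up).  Also carries the per-gene z-score matrix of primed
#' genes across learning groups and the sign-concordance fraction between
#' the two threshold-learning groups.
#'
#' @slot summary data.frame with one row per (class, direction).
#' @slot zscores genes x groups z-score matrix for primed genes.
#' @slot concordance fraction of primed genes whose ELE+3min and SED+10min
#'   z-scores share a sign (NA when undefined).
#' @export
setClass("PrimingReport",
  representation(summary = "data.frame", zscores = "matrix",
                 concordance = "numeric"))

setValidity("PrimingReport", function(object) {
  s <- object@summary
  ok <- is.na(s$fraction) | (s$fraction >= 0 & s$fraction <= 1)
  if (!all(ok)) return("fractions must lie in [0, 1]")
  if (any(s$n_primed > s$n_total)) return("primed count exceeds class size")
  TRUE
})

#' @describeIn PrimingReport Per-class summary table.
#' @param x,object A PrimingReport.
#' @export
setGeneric("primingSummary", function(x) standardGeneric("primingSummary"))
#' @export
setMethod("primingSummary", "PrimingReport", function(x) x@summary)

setMethod("show", "PrimingReport", function(object) {
  cat("PrimingReport\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %-4s: %d/%d primed (%s%%)\n", s$class[i],
                s$direction[i], s$n_primed[i], s$n_total[i],
                ifelse(is.na(s$percent[i]), "NA", s$percent[i])))
  cat(sprintf("  z-score concordance (ELE+3min vs SED+10min): %s\n",
              ifelse(is.na(object@concordance), "NA",
                     sprintf("%.3f", object@concordance))))
})
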