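# End-to-end orchestration: differential expression per behavioral group,
# peak calling per track (IgG control by default), QC, annotation, mark
# dynamics, cGAME/cGAMES/cGAMS classification, priming fractions and
# z-score concordance.  Deterministic given its inputs; stage failures
# propagate with the stage name.

#' Run the full priming pipeline
#'
#' Stages: per-group NB Wald tests against the baseline -> DEG calling ->
#' signal-block segmentation -> peak calling (IgG control when a matching
#' "IgG.<condition>" track exists, else numeric top-fraction) -> QC filter
#' -> annotation -> gene-level presence -> mark dynamics -> classification
#' -> priming fractions and z-score concordance.  Every threshold used is
#' recorded in the returned `settings`.
#'
#' @param counts SummarizedExperiment with a `counts` assay and a `group`
#'   column in colData (levels must include `baselineGroup` and the four
#'   behavioral groups).
#' @param tracks Named list of coverage GRanges, names "antibody.condition"
#'   (e.g. "H4K8ac.ELE", "IgG.SED").
#' @param genome A \linkS4class{GenomeAnnotation}.
#' @param baselineGroup Reference group label (default "baseline").
#' @param lfcCut,pCut,useP DEG thresholds passed to [callDegs()].
#' @param peakMode "stringent" or "relaxed".
#' @param fraction Numeric-mode retained fraction (used when no IgG track
#'   matches a condition).
#' @param fdrThreshold Sample-level empirical-FDR QC cutoff.
#' @param tssWindow,downstreamWindow Annotation windows (bp).
#' @param outDir Optional directory; when given, result tables are written
#'   there (overlap_table.tsv, game_classes.tsv, priming_summary.tsv,
#'   zscore_matrix.tsv).
#' @return list: de (per-group DataFrames), degs (per-group DEGSets),
#'   peaks (PeakSets), qc (exclusion report), annotated (data.frames),
#'   presence, dynamics, classification, report (PrimingReport), overlaps,
#'   settings.
#' @export
runPrimingPipeline <- function(counts, tracks, genome,
                               baselineGroup = "baseline",
                               lfcCut = log2(1.3), pCut = 0.05,
                               useP = c("pvalue", "padj"),
                               peakMode = c("stringent", "relaxed"),
                               fraction = 0.01, fdrThreshold = 0.1,
                               tssWindow = 3000, downstreamWindow = 3000,
                               outDir = NULL) {
  useP <- match.arg(useP)
  peakMode <- match.arg(peakMode)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  design <- as.data.frame(colData(counts))
  groups <- setdiff(unique(design$group), baselineGroup)
  de <- list(); degs <- list()
  for (g in groups) {
    de[[g]] <- stage(paste0("de:", g),
      nbWaldTest(counts, design, contrast = c("group", g, baselineGroup)))
    degs[[g]] <- callDegs(de[[g]], lfcCut = lfcCut, pCut = pCut, use = useP,
                          contrast = paste(g, "vs", baselineGroup))
  }

  target_names <- grep("^IgG\\.", names(tracks), invert = TRUE, value = TRUE)
  peaksets <- list()
  for (nm in target_names) {
    cond <- sub("^[^.]+\\.", "", nm)
    blocks <- stage(paste0("segment:", nm), segmentBlocks(tracks[[nm]]))
    igg_nm <- paste0("IgG.", cond)
    peaksets[[nm]] <- stage(paste0("callpeaks:", nm), suppressWarnings({
      if (igg_nm %in% names(tracks)) {
        igg_blocks <- segmentBlocks(tracks[[igg_nm]])
        callPeaksWithControl(blocks, igg_blocks, mode = peakMode,
                             sampleId = nm)
      } else {
        callPeaksNumeric(blocks, fraction = fraction, mode = peakMode,
                         sampleId = nm)
      }
    }))
  }
  qc <- qcFilterSamples(peaksets, threshold = fdrThreshold)

  annotated <- lapply(qc$retained, function(ps)
    stage(paste0("annotate:", ps@sampleId),
          annotatePeaks(ps, genome, tssWindow = tssWindow,
                        downstreamWindow = downstreamWindow)))
  presence <- genePeakPresence(annotated)

  dynamics <- list()
  for (ab in unique(sub("\\..*$", "", names(presence)))) {
    ele <- paste0(ab, ".ELE"); sed <- paste0(ab, ".SED")
    pres <- presence
    if (!ele %in% names(pres)) pres[[ele]] <- character(0)
    if (!sed %in% names(pres)) pres[[sed]] <- character(0)
    dynamics[[ab]] <- markDynamics(pres, ab)
  }
  for (ab in c("H4K8ac", "H3K27me3"))
    if (is.null(dynamics[[ab]]))
      dynamics[[ab]] <- new("MarkDynamics", antibody = ab,
                            new = character(0), lost = character(0),
                            shared = character(0))

  classification <- stage("classify", classifyGame(degs))
  lfc_groups <- intersect(c("ELE_3min", "SED_3min", "SED_10min"), groups)
  lfcMatrix <- do.call(cbind, lapply(lfc_groups, function(g)
    de[[g]]$log2FoldChange))
  dimnames(lfcMatrix) <- list(rownames(de[[lfc_groups[1]]]), lfc_groups)
  report <- stage("priming",
    primingFractions(classification, dynamics, lfcMatrix = lfcMatrix))

  overlaps <- if ("ELE_alone" %in% names(degs))
    intersectDynamicsDegs(dynamics, degs$ELE_alone) else NULL

  settings <- list(lfcCut = lfcCut, pCut = pCut, useP = useP,
                   peakMode = peakMode, fraction = fraction,
                   fdrThreshold = fdrThreshold, tssWindow = tssWindow,
                   downstreamWindow = downstreamWindow,
                   baselineGroup = baselineGroup)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(overlaps))
      write.table(overlaps$table, file.path(outDir, "overlap_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    cls_rows <- do.call(rbind, lapply(c("up", "down"), function(d)
      do.call(rbind, lapply(c("cGAME", "cGAMES", "cGAMS"), function(cl)
        data.frame(class = cl, direction = d,
                   gene_id = gameClass(classification, cl, d),
                   stringsAsFactors = FALSE)))))
    write.table(cls_rows, file.path(outDir, "game_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(primingSummary(report),
                file.path(outDir, "priming_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(report@zscores))
      write.table(data.frame(gene_id = rownames(report@zscores),
                             report@zscores, check.names = FALSE),
                  file.path(outDir, "zscore_matrix.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(de = de, degs = degs, peaks = peaksets, qc = qc,
       annotated = annotated, presence = presence, dynamics = dynamics,
       classification = classification, report = report,
       overlaps = overlaps, settings = settings)
}
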