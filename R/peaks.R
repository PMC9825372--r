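# Sparse-enrichment peak calling from coverage tracks: maximal
# strictly-positive signal blocks scored by AUC (depth x length), then
# either top-fraction numeric thresholding or an IgG-control threshold scan
# with empirical FDR, in the SEACR mold.

#' Segment a coverage track into signal blocks
#'
#' Maximal runs of strictly positive depth; blocks separated by any
#' zero-depth gap are never merged.  Each block carries `auc` (sum of depth
#' times interval length) and `max_depth`.
#'
#' @param track GRanges coverage with a `score` depth column (e.g. from
#'   [readBedGraph()] or [simulateCoverage()]).
#' @return GRanges of blocks with `auc` and `max_depth` columns.
#' @export
segmentBlocks <- function(track) {
  track <- canonicalizeCoverage(track)
  pos <- track[track$score > 0]
  if (!length(pos)) {
    out <- GRanges()
    out$auc <- numeric(0)
    out$max_depth <- numeric(0)
    return(out)
  }
  blocks <- reduce(pos, min.gapwidth = 1L)
  hits <- findOverlaps(pos, blocks)
  w <- width(pos) * pos$score
  auc <- as.numeric(tapply(w, subjectHits(hits), sum))
  mx <- as.numeric(tapply(pos$score, subjectHits(hits), max))
  blocks$auc <- auc
  blocks$max_depth <- mx
  blocks
}

# Empirical quantile with "higher" interpolation: the smallest order
# statistic at or above position (n-1)*p.  Deterministic and conservative:
# the kept fraction never exceeds the requested one except through ties.
quantileHigher <- function(x, p) {
  s <- sort(x)
  s[min(length(s), ceiling((length(s) - 1) * p) + 1L)]
}

newPeakSet <- function(peaks, mode, thresholdType, numericFraction = NA_real_,
                       aucThreshold = NA_real_, empiricalFDR = NA_real_,
                       sampleId = "sample") {
  new("PeakSet", peaks = sort(peaks, ignore.strand = TRUE), mode = mode,
      thresholdType = thresholdType, numericFraction = numericFraction,
      aucThreshold = aucThreshold, empiricalFDR = empiricalFDR,
      sampleId = sampleId)
}

#' Numeric (top-fraction) peak calling
#'
#' Keeps blocks whose AUC reaches the empirical (1 - fraction) quantile of
#' block AUCs ("higher" interpolation; ties at the threshold are all kept).
#' Stringent mode additionally requires max depth at or above the same
#' quantile of block max depths; relaxed mode gates on AUC alone.
#'
#' @param blocks GRanges from [segmentBlocks()].
#' @param fraction Retained fraction in (0, 1]; the study setting is 0.01.
#' @param mode "stringent" (default) or "relaxed".
#' @param sampleId Label carried into the PeakSet.
#' @return A \linkS4class{PeakSet}.
#' @export
callPeaksNumeric <- function(blocks, fraction = 0.01,
                             mode = c("stringent", "relaxed"),
                             sampleId = "sample") {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (!length(blocks)) {
    warning("no signal blocks; returning an empty PeakSet")
    return(newPeakSet(blocks, mode, "numeric", numericFraction = fraction,
                      sampleId = sampleId))
  }
  thr <- quantileHigher(blocks$auc, 1 - fraction)
  keep <- blocks$auc >= thr
  if (mode == "stringent") {
    thr_max <- quantileHigher(blocks$max_depth, 1 - fraction)
    keep <- keep & blocks$max_depth >= thr_max
  }
  newPeakSet(blocks[keep], mode, "numeric", numericFraction = fraction,
             aucThreshold = thr, sampleId = sampleId)
}

#' IgG-control peak calling with empirical FDR
#'
#' Scans candidate AUC thresholds (the union of target and control block
#' AUCs) and keeps the one maximizing the difference between the fraction
#' of target blocks and the fraction of control blocks at or above it
#' (smallest such threshold on ties, with a warning).  The empirical FDR is
#' the count of control blocks over threshold divided by the count of
#' target blocks over threshold; samples with FDR > 0.1 fail QC.
#'
#' An empty control block list (degenerate input) keeps every target block
#' at FDR 0 with a warning.
#'
#' @param targetBlocks,controlBlocks GRanges from [segmentBlocks()].
#' @param mode "stringent" additionally gates max depth at the max-depth
#'   quantile matching the kept AUC fraction; "relaxed" gates AUC only.
#' @param sampleId Label carried into the PeakSet.
#' @return A \linkS4class{PeakSet} with `empiricalFDR` set.
#' @export
callPeaksWithControl <- function(targetBlocks, controlBlocks,
                                 mode = c("stringent", "relaxed"),
                                 sampleId = "sample") {
  mode <- match.arg(mode)
  if (!length(targetBlocks)) {
    warning("no target signal blocks; returning an empty PeakSet")
    return(newPeakSet(targetBlocks, mode, "control", sampleId = sampleId))
  }
  if (!length(controlBlocks)) {
    warning("control track has no signal blocks; keeping all target blocks")
    return(newPeakSet(targetBlocks, mode, "control",
                      aucThreshold = min(targetBlocks$auc),
                      empiricalFDR = 0, sampleId = sampleId))
  }
  ta <- targetBlocks$auc
  ca <- controlBlocks$auc
  cand <- sort(unique(c(ta, ca)))
  # fraction at or above each candidate threshold
  nt <- length(ta); nc <- length(ca)
  # #(x >= t) = n - #(x < t); findInterval(left.open) counts elements < t
  ft <- 1 - (findInterval(cand, sort(ta), left.open = TRUE) / nt)
  fc <- 1 - (findInterval(cand, sort(ca), left.open = TRUE) / nc)
  diff <- ft - fc
  best <- max(diff)
  # ties at the maximum are resolved toward the smallest threshold; a small
  # tolerance keeps mathematically equal differences tied under FP rounding
  at_best <- which(diff > best - 1e-9)
  if (length(at_best) == length(cand))
    warning("all candidate thresholds give the same separation; ",
            "using the smallest")
  thr <- cand[at_best[1]]
  keep <- ta >= thr
  fdr <- sum(ca >= thr) / sum(keep)
  kept <- targetBlocks[keep]
  if (mode == "stringent" && length(kept)) {
    frac_kept <- sum(keep) / nt
    thr_max <- quantileHigher(targetBlocks$max_depth, 1 - frac_kept)
    kept <- kept[kept$max_depth >= thr_max]
  }
  newPeakSet(kept, mode, "control", aucThreshold = thr,
             empiricalFDR = fdr, sampleId = sampleId)
}

#' QC-filter a list of PeakSets by empirical FDR
#'
#' Control-mode sets with empirical FDR above the threshold are dropped
#' (the study's rule: FDR > 0.1 is too high for called peaks).  Numeric
#' mode sets carry no FDR and are always retained.
#'
#' @param peaksets List of \linkS4class{PeakSet} objects.
#' @param threshold Empirical-FDR cutoff (default 0.1).
#' @return List with `retained` (PeakSets) and `excluded` (data.frame of
#'   sample id, FDR, reason).
#' @export
qcFilterSamples <- function(peaksets, threshold = 0.1) {
  pass <- vapply(peaksets, qcPass, logical(1), threshold = threshold)
  excl <- data.frame(
    sample_id = vapply(peaksets[!pass], function(p) p@sampleId, character(1)),
    empirical_fdr = vapply(peaksets[!pass], empiricalFDR, numeric(1)),
    reason = rep(sprintf("empirical FDR > %g", threshold), sum(!pass)),
    stringsAsFactors = FALSE)
  list(retained = peaksets[pass], excluded = excl)
}
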