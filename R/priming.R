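# The core inference: gene-level mark dynamics between ELE and sedentary
# conditions, their overlap with DEG sets, the cGAME/cGAMES/cGAMS
# classification across behavioral groups, priming fractions, and the
# z-score concordance of primed genes across learning groups.

#' Gene-level mark dynamics between conditions
#'
#' Set algebra on gene-level peak presence: `new` = ELE only, `lost` = SED
#' only, `shared` = both.
#'
#' @param presence Named list of gene-id vectors (from
#'   [genePeakPresence()]); must contain entries for both conditions of
#'   this antibody.
#' @param antibody Mark name, e.g. "H4K8ac".
#' @param eleLabel,sedLabel Names of the ELE and SED presence entries
#'   (default `paste(antibody, c("ELE", "SED"), sep = ".")`).
#' @return A \linkS4class{MarkDynamics}.
#' @export
markDynamics <- function(presence, antibody,
                         eleLabel = paste(antibody, "ELE", sep = "."),
                         sedLabel = paste(antibody, "SED", sep = ".")) {
  if (!all(c(eleLabel, sedLabel) %in% names(presence)))
    stop("presence must contain entries '", eleLabel, "' and '", sedLabel, "'")
  ele <- unique(presence[[eleLabel]])
  sed <- unique(presence[[sedLabel]])
  new("MarkDynamics", antibody = antibody,
      new = sort(setdiff(ele, sed)),
      lost = sort(setdiff(sed, ele)),
      shared = sort(intersect(ele, sed)))
}

#' Overlap of mark dynamics with DEG sets
#'
#' All antibody x {new, lost, shared} x {up, down} intersections, plus
#' co-occurrence counts (genes appearing in two or more cells), supporting
#' statements like "93 upregulated genes had new H4K8ac peaks, of which 14
#' also had new H3K27me3".
#'
#' @param dynamics List of \linkS4class{MarkDynamics}, one per antibody.
#' @param degs A \linkS4class{DEGSets}.
#' @return list with `table` (data.frame: antibody, dynamic, direction,
#'   count, genes) and `cooccurrence` (data.frame of gene pairs of cells).
#' @export
intersectDynamicsDegs <- function(dynamics, degs) {
  rows <- list()
  cells <- list()
  for (dyn in dynamics) {
    for (what in c("new", "lost", "shared")) {
      genes_dyn <- slot(dyn, what)
      for (dir in c("up", "down")) {
        genes_deg <- if (dir == "up") degUp(degs) else degDown(degs)
        ov <- sort(intersect(genes_dyn, genes_deg))
        key <- paste(dyn@antibody, what, dir, sep = ".")
        rows[[key]] <- data.frame(
          antibody = dyn@antibody, dynamic = what, direction = dir,
          count = length(ov), genes = paste(ov, collapse = ","),
          stringsAsFactors = FALSE)
        cells[[key]] <- ov
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # genes present in >= 2 cells (within one direction across antibodies)
  co <- list()
  keys <- names(cells)
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (j <= i) next
    both <- intersect(cells[[i]], cells[[j]])
    if (length(both))
      co[[paste(keys[i], keys[j], sep = " & ")]] <- data.frame(
        cell_a = keys[i], cell_b = keys[j], count = length(both),
        genes = paste(both, collapse = ","), stringsAsFactors = FALSE)
  }
  co <- if (length(co)) do.call(rbind, co) else
    data.frame(cell_a = character(0), cell_b = character(0),
               count = integer(0), genes = character(0))
  rownames(co) <- NULL
  list(table = tab, cooccurrence = co)
}

.GAME_GROUPS <- c("ELE_alone", "ELE_3min", "SED_3min", "SED_10min")

#' Classify candidate memory genes (cGAME / cGAMES / cGAMS)
#'
#' Given per-group DEG sets (each group vs the no-exercise/no-learning
#' baseline), per direction d:
#' \itemize{
#'   \item cGAMES_d = deg(ELE_3min, d) intersect deg(SED_10min, d)
#'   \item cGAME_d = deg(ELE_3min, d) minus the union of the other three
#'     groups' sets
#'   \item cGAMS_d = deg(SED_10min, d) minus the union of the other three
#' }
#' ELE-alone counts as an "other group" for the exclusions.  Genes are
#' classified independently per direction.
#'
#' @param degByGroup Named list of \linkS4class{DEGSets}; names must
#'   include "ELE_alone", "ELE_3min", "SED_3min", "SED_10min".
#' @return A \linkS4class{GameClassification}.
#' @export
classifyGame <- function(degByGroup) {
  missing <- setdiff(.GAME_GROUPS, names(degByGroup))
  if (length(missing))
    stop("missing group(s): ", paste(missing, collapse = ", "))
  classify <- function(dir) {
    s <- lapply(degByGroup[.GAME_GROUPS], function(d)
      if (dir == "up") degUp(d) else degDown(d))
    cgames <- intersect(s$ELE_3min, s$SED_10min)
    cgame <- setdiff(s$ELE_3min,
                     Reduce(union, s[c("ELE_alone", "SED_3min", "SED_10min")]))
    cgams <- setdiff(s$SED_10min,
                     Reduce(union, s[c("ELE_alone", "SED_3min", "ELE_3min")]))
    list(cGAME = sort(cgame), cGAMES = sort(cgames), cGAMS = sort(cgams))
  }
  new("GameClassification", up = classify("up"), down = classify("down"),
      groups = .GAME_GROUPS)
}

# Display rounding: round half away from zero (so 58/145 -> 40%, and
# 76/256 = 29.7% -> 30%), not banker's rounding.
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Priming fractions per class
#'
#' For up-classes, a gene counts as primed when it has new H4K8ac or lost
#' H3K27me3 after ELE; for down-classes, new H3K27me3 or lost H4K8ac.
#' Component counts are reported alongside the union.  Percentages use
#' round-half-up for display; exact fractions are retained.  An empty class
#' reports fraction NA with count 0.
#'
#' @param classification A \linkS4class{GameClassification}.
#' @param dynamics Named list of \linkS4class{MarkDynamics} with entries
#'   "H4K8ac" and "H3K27me3".
#' @param lfcMatrix Optional genes x groups log2FC matrix (columns
#'   ELE_3min, SED_3min, SED_10min) for the z-score concordance of primed
#'   genes; omit to skip.
#' @return A \linkS4class{PrimingReport}.
#' @export
primingFractions <- function(classification, dynamics, lfcMatrix = NULL) {
  h4 <- dynamics[["H4K8ac"]]
  h3 <- dynamics[["H3K27me3"]]
  if (is.null(h4) || is.null(h3))
    stop("dynamics must contain 'H4K8ac' and 'H3K27me3' entries")
  permissive <- union(h4@new, h3@lost)   # gained activation potential
  repressive <- union(h3@new, h4@lost)   # gained repression
  rows <- list()
  primed_genes <- character(0)
  for (dir in c("up", "down")) {
    marks <- if (dir == "up") permissive else repressive
    comp1 <- if (dir == "up") h4@new else h3@new
    comp2 <- if (dir == "up") h3@lost else h4@lost
    for (cls in c("cGAME", "cGAMES", "cGAMS")) {
      genes <- gameClass(classification, cls, dir)
      hit <- intersect(genes, marks)
      if (cls %in% c("cGAME", "cGAMES")) primed_genes <- union(primed_genes, hit)
      n <- length(genes)
      frac <- if (n == 0) NA_real_ else length(hit) / n
      rows[[paste(cls, dir)]] <- data.frame(
        class = cls, direction = dir, n_total = n, n_primed = length(hit),
        n_mark_gain = length(intersect(genes, comp1)),
        n_mark_loss = length(intersect(genes, comp2)),
        fraction = frac,
        percent = if (is.na(frac)) NA_real_ else roundHalfUp(100 * frac),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  z <- matrix(numeric(0), 0, 0)
  conc <- NA_real_
  if (!is.null(lfcMatrix) && length(primed_genes)) {
    zc <- zscoreConcordance(lfcMatrix, primed_genes)
    z <- zc$zscores
    conc <- zc$concordance
  }
  new("PrimingReport", summary = summary, zscores = z, concordance = conc)
}

#' Z-scores of primed genes across learning groups, with sign concordance
#'
#' Per gene, z = (LFC - row mean) / row sd across the groups (default the
#' three learning groups, all relative to the untrained/unexercised
#' baseline).  Genes with zero row sd are excluded and counted.  The
#' concordance is the fraction of primed genes whose ELE_3min and SED_10min
#' z-scores share a sign.
#'
#' @param lfcMatrix genes x groups numeric matrix with columns including
#'   "ELE_3min" and "SED_10min" (rownames = gene ids).
#' @param primedGenes Gene ids to evaluate (rows absent from the matrix are
#'   dropped).
#' @return list: `zscores` (matrix), `concordance` (fraction or NA),
#'   `n_excluded` (zero-sd genes).
#' @export
zscoreConcordance <- function(lfcMatrix, primedGenes) {
  genes <- intersect(primedGenes, rownames(lfcMatrix))
  m <- lfcMatrix[genes, , drop = FALSE]
  m <- m[complete.cases(m), , drop = FALSE]
  if (!nrow(m) || ncol(m) < 2)
    return(list(zscores = matrix(numeric(0), 0, 0), concordance = NA_real_,
                n_excluded = 0L))
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  keep <- sdv > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  conc <- NA_real_
  if (nrow(z) && all(c("ELE_3min", "SED_10min") %in% colnames(z)))
    conc <- mean(sign(z[, "ELE_3min"]) == sign(z[, "SED_10min"]))
  list(zscores = z, concordance = conc, n_excluded = sum(!keep))
}
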