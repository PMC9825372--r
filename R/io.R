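# Readers and writers for the plain-text formats the pipeline consumes:
# tab-separated count and design tables, 4-column bedGraph coverage, BED12 or
# minimal GTF gene annotations, and BED6 peak output.  All genomic text
# formats are converted to 1-based GRanges on read; 0-based conventions
# exist only in the files themselves.

.exerciseLevels  <- c("ELE", "SED")
.learningLevels  <- c("none", "3min", "10min")
.hemiLevels      <- c("L", "R", "both")
.isolationLevels <- c("simultaneous", "separate")
.assayLevels     <- c("RNA", "CUTRUN")
.antibodyLevels  <- c("H4K8ac", "H3K27me3", "IgG")

#' Read a sample design table
#'
#' Tab-separated table keyed by \code{sample_id} with the study factors:
#' \code{exercise} (ELE/SED), \code{learning} (none/3min/10min),
#' \code{hemisphere} (L/R/both), \code{isolation} (simultaneous/separate),
#' \code{assay} (RNA/CUTRUN) and \code{antibody} (H4K8ac/H3K27me3/IgG, or NA
#' for RNA samples).  Factor values outside these closed vocabularies are
#' rejected; \code{antibody} must be NA exactly for RNA samples.
#'
#' @param path Path to the design table.
#' @return data.frame with factor columns, rownames = sample ids.
#' @export
readDesignTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), quote = "")
  if (!"sample_id" %in% names(d)) stop("design table needs a 'sample_id' column")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design table")
  rownames(d) <- d$sample_id
  validateDesign(d)
  d
}

validateDesign <- function(d) {
  chk <- function(col, levels, allowNA = FALSE) {
    if (!col %in% names(d)) return(invisible())
    v <- d[[col]]
    bad <- !(v %in% levels | (allowNA & is.na(v)))
    if (any(bad))
      stop(sprintf("design column '%s' has values outside {%s}: %s", col,
                   paste(levels, collapse = ", "),
                   paste(unique(v[bad]), collapse = ", ")))
  }
  chk("exercise", .exerciseLevels)
  chk("learning", .learningLevels)
  chk("hemisphere", .hemiLevels)
  chk("isolation", .isolationLevels)
  chk("assay", .assayLevels)
  chk("antibody", .antibodyLevels, allowNA = TRUE)
  if (all(c("assay", "antibody") %in% names(d))) {
    if (any(d$assay == "RNA" & !is.na(d$antibody)))
      stop("RNA samples must have antibody = NA")
    if (any(d$assay == "CUTRUN" & is.na(d$antibody)))
      stop("CUTRUN samples must have an antibody")
  }
  invisible(d)
}

#' Read a gene-level count table
#'
#' First column gene ids, remaining columns one per sample; the body must be
#' non-negative integers.  If a design table is supplied the sample columns
#' are matched against it (all count columns must be known samples) and the
#' design is attached as \code{colData}.
#'
#' @param path Path to the tab-separated count table.
#' @param design Optional design data.frame from [readDesignTable()].
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay.
#' @export
readCountTable <- function(path, design = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
  if (ncol(tab) < 2) stop("count table needs a gene-id column plus samples")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  if (anyDuplicated(names(body))) stop("duplicate sample id in count table")
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count at (%s, %s): '%s'",
                   gene_ids[bad[1]], names(body)[j], body[bad[1], j]))
    body[[j]] <- as.integer(v)
  }
  counts <- as.matrix(body)
  rownames(counts) <- gene_ids
  cd <- NULL
  if (!is.null(design)) {
    missing <- setdiff(colnames(counts), rownames(design))
    if (length(missing))
      stop("count columns absent from design table: ",
           paste(missing, collapse = ", "))
    cd <- S4Vectors::DataFrame(design[colnames(counts), , drop = FALSE])
  }
  if (is.null(cd))
    SummarizedExperiment(assays = list(counts = counts))
  else
    SummarizedExperiment(assays = list(counts = counts), colData = cd)
}

#' Write a count table
#'
#' Canonical form: a `gene_id` header for the first column, tab separation,
#' no quoting.  Round-trips with [readCountTable()].
#'
#' @param se SummarizedExperiment with a `counts` assay (or a plain matrix).
#' @param path Output path.
#' @export
writeCountTable <- function(se, path) {
  m <- if (is.matrix(se)) se else assay(se, "counts")
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph coverage track
#'
#' Input intervals are 0-based half-open; the result is a sorted 1-based
#' GRanges with a `score` depth column.  Adjacent intervals with equal depth
#' are merged; zero-depth intervals are retained.  Overlapping intervals
#' within a chromosome are an error, as are empty intervals.
#'
#' @param path Path to the bedGraph file.
#' @param chromSizes Optional named chromosome lengths to set as seqlengths.
#' @return GRanges with a numeric `score` column.
#' @export
readBedGraph <- function(path, chromSizes = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  canonicalizeCoverage(gr, chromSizes = chromSizes)
}

# Shared validation/normal-form step for coverage tracks, whether read from
# disk or simulated in memory.
canonicalizeCoverage <- function(gr, chromSizes = NULL) {
  if (any(width(gr) < 1)) stop("coverage interval with end <= start")
  if (any(gr$score < 0)) stop("negative coverage depth")
  gr <- sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
  if (!isDisjoint(gr)) stop("overlapping coverage intervals within a chromosome")
  # merge runs that are adjacent (no gap) and of equal depth
  if (length(gr) > 1) {
    same <- as.character(seqnames(gr))[-1] ==
              as.character(seqnames(gr))[-length(gr)] &
            start(gr)[-1] == end(gr)[-length(gr)] + 1L &
            gr$score[-1] == gr$score[-length(gr)]
    grp <- cumsum(c(TRUE, !same))
    if (anyDuplicated(grp)) {
      first <- !duplicated(grp)
      out <- gr[first]
      end(out) <- end(gr)[!duplicated(grp, fromLast = TRUE)]
      gr <- out
    }
  }
  if (!is.null(chromSizes)) {
    seqlengths(gr) <- chromSizes[seqlevels(gr)]
    if (any(end(gr) > seqlengths(gr)[as.character(seqnames(gr))]))
      stop("coverage interval beyond chromosome end")
  }
  strand(gr) <- "*"
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param gr GRanges with a `score` column.
#' @param path Output path.
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read chromosome sizes
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(d[[2]]), d[[1]])
}

#' Read a gene annotation (BED12 or minimal GTF)
#'
#' One record per gene.  For GTF input, `gene` and `exon` features are used
#' (attributes must carry `gene_id`); when a gene id has several transcripts
#' the longest transcript model is kept.  For BED12 the block structure
#' provides the exons.  TSS is computed by strand: `start` for `+` genes,
#' `end` for `-` genes.
#'
#' @param path Path to the annotation file.
#' @param chromSizes Named chromosome lengths; required for BED12 input and
#'   any GTF lacking sequence lengths.  When NULL, sizes are inferred as the
#'   maximum annotated coordinate per chromosome.
#' @param format "auto" (by extension), "gtf" or "bed".
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readGeneAnnotation <- function(path, chromSizes = NULL, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      stop("unknown strand symbol in annotation (must be '+' or '-')")
    ex <- gr[gr$type == "exon"]
    gn <- gr[gr$type == "gene"]
    if (!length(gn)) { # derive gene bodies from exon extents
      gn <- unlist(range(split(ex, ex$gene_id)))
      gn$gene_id <- names(gn)
      names(gn) <- NULL
    }
    if (anyDuplicated(gn$gene_id)) {
      # several transcript models: keep the longest per gene
      o <- order(gn$gene_id, -width(gn))
      gn <- gn[o][!duplicated(gn$gene_id[o])]
    }
    exons <- split(granges(ex), ex$gene_id)[as.character(gn$gene_id)]
    bad <- which(start(unlist(range(exons))) < start(gn) |
                 end(unlist(range(exons))) > end(gn))
    if (length(bad))
      stop("exon outside gene body for gene ", gn$gene_id[bad[1]])
    genes <- granges(gn)
    genes$gene_id <- as.character(gn$gene_id)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      stop("unknown strand symbol in annotation (must be '+' or '-')")
    genes <- granges(gr)
    genes$gene_id <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr))
    exons <- if (!is.null(gr$blocks)) {
      b <- rtracklayer::blocks(gr)
      names(b) <- genes$gene_id
      b
    } else NULL
  }
  if (is.null(chromSizes)) {
    sq <- seqlengths(genes)
    if (any(is.na(sq))) {
      mx <- tapply(end(genes), as.character(seqnames(genes)), max)
      chromSizes <- setNames(as.integer(mx), names(mx))
    } else chromSizes <- sq
  }
  GenomeAnnotation(genes, exons = exons, chromSizes = chromSizes)
}

#' Write a minimal GTF for a GenomeAnnotation
#'
#' Emits `gene` and `exon` features with `gene_id` attributes; round-trips
#' through [readGeneAnnotation()].
#'
#' @param annotation A GenomeAnnotation.
#' @param path Output path.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  g <- geneModels(annotation)
  ex <- unlist(exonsByGene(annotation))
  gene_lines <- sprintf("%s\tprimeseq\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                        as.character(seqnames(g)), start(g), end(g),
                        as.character(strand(g)), g$gene_id)
  st <- as.character(strand(g))[match(names(ex), g$gene_id)]
  exon_lines <- sprintf("%s\tprimeseq\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                        as.character(seqnames(ex)), start(ex), end(ex),
                        st, names(ex))
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' Write called peaks as BED6
#'
#' Six columns: chrom, 0-based start, end, name, AUC score, ".".  Peaks are
#' sorted by coordinate; an empty PeakSet produces a file holding only the
#' header comment.
#'
#' @param peaks A \linkS4class{PeakSet}.
#' @param path Output path.
#' @export
writePeaksBed <- function(peaks, path) {
  p <- sort(peakRanges(peaks), ignore.strand = TRUE)
  lines <- "# primeseq peaks: chrom start end name auc ."
  if (length(p))
    lines <- c(lines,
               sprintf("%s\t%d\t%d\tpeak_%d\t%s\t.",
                       as.character(seqnames(p)), start(p) - 1L, end(p),
                       seq_along(p), format(p$auc, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks written by [writePeaksBed()]
#'
#' @param path Path to the BED6 file.
#' @return GRanges with `name` and `auc` columns (1-based coordinates).
#' @export
readPeaksBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    gr <- GRanges()
    gr$name <- character(0)
    gr$auc <- numeric(0)
    return(gr)
  }
  d <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]),
          name = d[[4]], auc = as.numeric(d[[5]]))
}
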