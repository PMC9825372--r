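# Small in-code fixtures shared across test files.

library(GenomicRanges)
library(SummarizedExperiment)

# A coverage GRanges from a depth-per-tile vector (tile width in bp).
trackFromDepths <- function(depths, tile = 10, chrom = "chr1",
                            chromLength = length(depths) * tile) {
  r <- rle(depths)
  ends <- cumsum(r$lengths) * tile
  starts <- c(1, head(cumsum(r$lengths), -1) * tile + 1)
  gr <- GRanges(chrom, IRanges(starts, pmin(ends, chromLength)),
                score = r$values)
  seqlengths(gr) <- setNames(chromLength, chrom)
  gr
}

# Signal blocks directly from AUC values (positions made non-overlapping).
blocksFromAuc <- function(auc, max_depth = pmax(1, round(auc / 10)),
                          chrom = "chr1") {
  n <- length(auc)
  if (n == 0) {
    gr <- GRanges()
    gr$auc <- numeric(0)
    gr$max_depth <- numeric(0)
    return(gr)
  }
  GRanges(chrom, IRanges(seq_len(n) * 1000, width = 100),
          auc = auc, max_depth = max_depth)
}

# A tiny deterministic annotation: two genes on chr1 (one per strand), one
# gene on chr2.
tinyAnnotation <- function() {
  genes <- GRanges(c("chr1", "chr1", "chr2"),
                   IRanges(c(10001, 40001, 5001), c(14000, 46000, 9000)),
                   strand = c("+", "-", "+"),
                   gene_id = c("gA", "gB", "gC"))
  exons <- GRangesList(
    gA = GRanges("chr1", IRanges(c(10001, 12001), c(10800, 14000)), "+"),
    gB = GRanges("chr1", IRanges(c(40001, 43001, 45001), c(41000, 43800, 46000)), "-"),
    gC = GRanges("chr2", IRanges(c(5001, 8001), c(6000, 9000)), "+"))
  GenomeAnnotation(genes, exons = exons,
                   chromSizes = c(chr1 = 100000, chr2 = 50000))
}

# Count table + design written to temp files; returns the two paths.
writeTinyCountFiles <- function(dir = tempfile()) {
  dir.create(dir)
  counts_path <- file.path(dir, "counts.tsv")
  design_path <- file.path(dir, "design.tsv")
  writeLines(c("gene_id\ts1\ts2",
               "g1\t3\t0",
               "g2\t1\t5"), counts_path)
  writeLines(c(paste("sample_id", "exercise", "learning", "hemisphere",
                     "isolation", "assay", "antibody", sep = "\t"),
               paste("s1", "ELE", "none", "both", "simultaneous", "RNA",
                     "NA", sep = "\t"),
               paste("s2", "SED", "none", "both", "simultaneous", "RNA",
                     "NA", sep = "\t")), design_path)
  list(counts = counts_path, design = design_path)
}

emptyDynamics <- function(ab) new("MarkDynamics", antibody = ab,
                                  new = character(0), lost = character(0),
                                  shared = character(0))

degSets <- function(up = character(0), down = character(0), label = "x")
  new("DEGSets", up = up, down = down, contrast = label,
      lfcCut = log2(1.3), pCut = 0.05)
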