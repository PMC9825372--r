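# Independent brute-force oracles.  These deliberately re-derive results
# from first principles (plain loops over plain vectors) so that the fast
# implementations can be checked against them on random instances.

# Top-fraction selection: take the m largest values, m = n - ceil((n-1)(1-f)),
# then extend to every tie of the smallest value taken.
oracleTopFraction <- function(auc, fraction) {
  n <- length(auc)
  m <- n - ceiling((n - 1) * (1 - fraction))
  m <- max(1L, min(n, m))
  s <- sort(auc, decreasing = TRUE)
  cut <- s[m]
  which(auc >= cut)
}

# Control-mode threshold: exhaustive scan over every candidate value.
oracleControlThreshold <- function(target, control) {
  cand <- sort(unique(c(target, control)))
  best <- -Inf; best_t <- NA
  for (t in cand) {
    d <- mean(target >= t) - mean(control >= t)
    if (d > best + 1e-9) { best <- d; best_t <- t }
  }
  list(threshold = best_t,
       fdr = sum(control >= best_t) / sum(target >= best_t))
}

# Quadratic peak-annotation scan: per peak, walk the priority list and all
# genes, using only plain integer arithmetic.
oracleAnnotate <- function(peaks_df, genes_df, exons_list,
                           tssWindow = 3000, downstreamWindow = 3000) {
  # peaks_df: chrom,start,end ; genes_df: gene_id,chrom,start,end,strand,tss
  sdist <- function(ps, pe, tss, strand) {
    d <- if (tss >= ps && tss <= pe) 0 else if (tss > pe) pe - tss else ps - tss
    if (strand == "-") -d else d
  }
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  featuresOf <- function(g, cat) {
    ex <- exons_list[[g$gene_id]]            # matrix start,end rows sorted
    first <- ex[1, ]; last <- ex[nrow(ex), ]
    plus <- g$strand == "+"
    u <- function(anchor5) {
      use_first <- if (anchor5) plus else !plus
      e <- if (use_first) first else last
      w <- max(1, floor((e[2] - e[1] + 1) * 0.1))
      outer_left <- (anchor5 && plus) || (!anchor5 && !plus)
      if (outer_left) c(e[1], e[1] + w - 1) else c(e[2] - w + 1, e[2])
    }
    switch(cat,
      Promoter = matrix(c(max(1, g$tss - tssWindow), g$tss + tssWindow), 1),
      `5'UTR` = matrix(u(TRUE), 1),
      `3'UTR` = matrix(u(FALSE), 1),
      Exon = ex,
      Intron = {
        if (nrow(ex) < 2) matrix(numeric(0), 0, 2) else
          cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
      },
      Downstream = if (plus)
        matrix(c(g$end + 1, g$end + downstreamWindow), 1)
      else matrix(c(max(1, g$start - downstreamWindow), g$start - 1), 1))
  }
  cats <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron", "Downstream")
  out <- data.frame(category = character(nrow(peaks_df)),
                    gene_id = character(nrow(peaks_df)),
                    distance_to_tss = numeric(nrow(peaks_df)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks_df))) {
    p <- peaks_df[i, ]
    assigned <- FALSE
    for (cat in cats) {
      hits <- character(0); dists <- numeric(0)
      for (j in seq_len(nrow(genes_df))) {
        g <- genes_df[j, ]
        if (g$chrom != p$chrom) next
        f <- featuresOf(g, cat)
        hit <- FALSE
        for (r in seq_len(nrow(f)))
          if (f[r, 1] <= f[r, 2] &&
              overlaps(p$start, p$end, f[r, 1], f[r, 2])) hit <- TRUE
        if (hit) {
          hits <- c(hits, g$gene_id)
          dists <- c(dists, sdist(p$start, p$end, g$tss, g$strand))
        }
      }
      if (length(hits)) {
        o <- order(abs(dists), hits)
        out$category[i] <- cat
        out$gene_id[i] <- hits[o[1]]
        out$distance_to_tss[i] <- dists[o[1]]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      same <- genes_df[genes_df$chrom == p$chrom, , drop = FALSE]
      if (!nrow(same)) same <- genes_df
      dists <- vapply(seq_len(nrow(same)), function(j)
        sdist(p$start, p$end, same$tss[j], same$strand[j]), numeric(1))
      o <- order(abs(dists), same$gene_id)
      out$category[i] <- "DistalIntergenic"
      out$gene_id[i] <- same$gene_id[o[1]]
      out$distance_to_tss[i] <- dists[o[1]]
    }
  }
  out
}

# The verbal cGAME/cGAMES/cGAMS rule applied to a single membership pattern
# (logical in ELE_alone, ELE_3min, SED_3min, SED_10min).
oracleGameClass <- function(inEA, inE3, inS3, inS10) {
  out <- character(0)
  if (inE3 && inS10) out <- c(out, "cGAMES")
  if (inE3 && !inEA && !inS3 && !inS10) out <- c(out, "cGAME")
  if (inS10 && !inEA && !inS3 && !inE3) out <- c(out, "cGAMS")
  out
}

# Random gene annotation for oracle comparisons: nGenes over one or two
# chromosomes, exon matrices returned alongside.
randomAnnotationInstance <- function(nGenes, seed) {
  set.seed(seed)
  genome <- makeGenome(nGenes, c(chr1 = 3e6, chr2 = 2e6), seed = seed)
  g <- geneModels(genome)
  genes_df <- data.frame(gene_id = g$gene_id,
                         chrom = as.character(seqnames(g)),
                         start = start(g), end = end(g),
                         strand = as.character(strand(g)), tss = g$tss,
                         stringsAsFactors = FALSE)
  ex <- exonsByGene(genome)
  exons_list <- lapply(setNames(names(ex), names(ex)), function(id)
    cbind(start(ex[[id]]), end(ex[[id]])))
  list(genome = genome, genes_df = genes_df, exons_list = exons_list)
}
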