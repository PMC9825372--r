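# Negative binomial differential expression: median-of-ratios size factors,
# method-of-moments dispersions, per-gene NB log-link GLMs fit by IRLS for
# Wald and likelihood-ratio tests, per-gene two-way ANOVA, BH adjustment,
# and the study's DEG-calling criterion (|log2FC| > log2(1.3), p < 0.05).
#
# Deliberately simpler than DESeq2: no dispersion shrinkage toward a fitted
# trend, no outlier machinery.  Every estimator here is property-tested
# (type-I error, bias, null uniformity) rather than matched numerically to
# another package.

.ALPHA_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the pseudo-reference is the per-gene geometric
#' mean across samples (genes with any zero are excluded); each sample's
#' factor is the median of its counts over the reference.
#'
#' @param counts Integer matrix, genes x samples, or a SummarizedExperiment
#'   with a `counts` assay.
#' @return Positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  m <- countsMatrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop("no gene has all-positive counts; size factors undefined ",
         "(consider a pseudo-reference fallback)")
  lg <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, median)
  setNames(sf, colnames(m))
}

countsMatrix <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  storage.mode(counts) <- "double"
  counts
}

#' Method-of-moments per-gene dispersions
#'
#' Counts are normalized by the size factors, group means removed (pooled
#' within-group centering over the design's grouping factor(s)), then
#' alpha_g = max(floor, (var - mean) / mean^2).  Underdispersed or constant
#' genes land on the floor (1e-8).
#'
#' @param counts Count matrix or SummarizedExperiment.
#' @param group Factor (or interaction of factors) defining the groups; a
#'   single group is allowed.
#' @param sizeFactors Per-sample size factors.
#' @return Numeric vector of dispersions, one per gene.
#' @export
estimateDispersionsMoM <- function(counts, group = NULL, sizeFactors = NULL) {
  m <- countsMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(m)
  norm <- sweep(m, 2, sizeFactors, "/")
  if (is.null(group)) group <- factor(rep(1, ncol(m)))
  group <- droplevels(as.factor(group))
  if (max(table(group)) < 2)
    stop("dispersion estimation needs >= 2 samples in some group")
  mu <- rowMeans(norm)
  # pooled within-group variance of normalized counts
  centered <- norm
  for (lv in levels(group)) {
    j <- which(group == lv)
    centered[, j] <- norm[, j, drop = FALSE] -
      rowMeans(norm[, j, drop = FALSE])
  }
  df <- ncol(m) - nlevels(group)
  v <- rowSums(centered^2) / df
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- .ALPHA_FLOOR
  pmax(alpha, .ALPHA_FLOOR)
}

# --- NB GLM with log link, fixed dispersion, fit by IRLS ------------------
# Returns beta, standard errors, log-likelihood and a convergence flag.
# offset = log(size factor).  Weights w = mu / (1 + alpha * mu).
nbGlmFit <- function(y, X, offset, alpha, maxit = 50L, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- tryCatch(qr.solve(X, eta - offset), error = function(e) NULL)
  if (is.null(beta)) beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    upd <- tryCatch(solve(XtWX, crossprod(X, w * z)), error = function(e) NULL)
    if (is.null(upd)) break
    beta <- drop(upd)
    eta <- drop(X %*% beta) + offset
    # guard against divergence (e.g. complete separation toward zero)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev <- -2 * sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  se <- rep(NA_real_, ncol(X))
  if (!is.null(XtWX)) {
    w <- mu / (1 + alpha * mu)
    XtWX <- crossprod(X, X * w)
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  list(beta = beta, se = se,
       loglik = sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)),
       converged = converged)
}

deResultFrame <- function(gene_ids, baseMean, log2FoldChange, lfcSE, stat,
                          pvalue, test) {
  res <- new("DEResult", S4Vectors::DataFrame(
    baseMean = baseMean, log2FoldChange = log2FoldChange, lfcSE = lfcSE,
    stat = stat, pvalue = pvalue, padj = adjustBH(pvalue),
    row.names = gene_ids))
  S4Vectors::metadata(res)$test <- test
  res
}

#' Per-gene negative binomial Wald test
#'
#' Fits, per gene, an NB log-link GLM of counts on a two-level factor with
#' log size factors as offsets, and tests the factor coefficient with a
#' Wald z statistic.  Genes that are all-zero or fail to converge get
#' p = NA and are excluded from the BH batch.
#'
#' @param counts Count matrix or SummarizedExperiment.
#' @param design data.frame of sample covariates (or the colData of the
#'   SummarizedExperiment when NULL).
#' @param contrast c(factorName, testLevel, referenceLevel), e.g.
#'   c("exercise", "ELE", "SED").
#' @param sizeFactors,dispersions Optional precomputed values; estimated
#'   from the data when NULL.
#' @return DataFrame with baseMean, log2FoldChange, lfcSE, stat, pvalue,
#'   padj; rownames are gene ids.
#' @export
nbWaldTest <- function(counts, design = NULL, contrast, sizeFactors = NULL,
                       dispersions = NULL) {
  m <- countsMatrix(counts)
  if (is.null(design) && is(counts, "SummarizedExperiment"))
    design <- as.data.frame(colData(counts))
  if (length(contrast) != 3)
    stop("contrast must be c(factor, testLevel, refLevel)")
  fac <- design[[contrast[1]]]
  if (is.null(fac)) stop("factor '", contrast[1], "' not in design")
  keep_s <- fac %in% contrast[2:3]
  m <- m[, keep_s, drop = FALSE]
  fac <- factor(fac[keep_s], levels = c(contrast[3], contrast[2]))
  if (nlevels(droplevels(fac)) != 2)
    stop("both contrast levels must be present in the design")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(m)
  else sizeFactors <- sizeFactors[keep_s]
  if (is.null(dispersions))
    dispersions <- estimateDispersionsMoM(m, fac, sizeFactors)
  X <- cbind(1, as.numeric(fac == contrast[2]))
  offset <- log(sizeFactors)
  n_genes <- nrow(m)
  lfc <- se <- stat <- p <- rep(NA_real_, n_genes)
  baseMean <- rowMeans(sweep(m, 2, sizeFactors, "/"))
  for (g in seq_len(n_genes)) {
    y <- m[g, ]
    if (all(y == 0)) next
    fit <- nbGlmFit(y, X, offset, dispersions[g])
    if (!fit$converged || !is.finite(fit$se[2]) || fit$se[2] <= 0) next
    lfc[g] <- fit$beta[2] / log(2)
    se[g] <- fit$se[2] / log(2)
    stat[g] <- fit$beta[2] / fit$se[2]
    p[g] <- 2 * pnorm(-abs(stat[g]))
  }
  deResultFrame(rownames(m), baseMean, lfc, se, stat, p, "wald")
}

#' Per-gene negative binomial likelihood-ratio test
#'
#' Fits full and reduced NB GLMs per gene (same dispersion, estimated under
#' the full model's grouping) and compares twice the log-likelihood
#' difference to a chi-squared with df = difference in parameters.  The
#' reduced model terms must nest within the full model.
#'
#' @param counts Count matrix or SummarizedExperiment.
#' @param design data.frame of sample covariates.
#' @param full,reduced One-sided model formulas, e.g.
#'   \code{~ hemisphere + exercise + hemisphere:exercise} and
#'   \code{~ hemisphere} (or \code{~ exercise + exercise:hemisphere} to
#'   test a main effect while keeping the interaction).  Nesting is checked
#'   on the column spaces; identical models give stat 0, p 1, with a
#'   warning.
#' @param sizeFactors,dispersions Optional precomputed values.
#' @return DataFrame as for [nbWaldTest()]; `log2FoldChange` is the last
#'   full-model coefficient (log2 scale), reported for reference.
#' @export
nbLRT <- function(counts, design = NULL, full, reduced, sizeFactors = NULL,
                  dispersions = NULL) {
  m <- countsMatrix(counts)
  if (is.null(design) && is(counts, "SummarizedExperiment"))
    design <- as.data.frame(colData(counts))
  Xf <- model.matrix(full, design)
  Xr <- model.matrix(reduced, design)
  # nesting is a column-space property, not a column-name one (formulas like
  # ~ exercise + exercise:hemisphere span a subspace of the full
  # ~ hemisphere * exercise design without sharing term names)
  qf <- qr(Xf)
  qr_r <- qr(Xr)
  if (qr(cbind(Xf, Xr))$rank > qf$rank)
    stop("reduced model is not nested in the full model")
  df <- qf$rank - qr_r$rank
  if (df == 0)
    warning("full and reduced models are equivalent; stat = 0, p = 1")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(m)
  if (is.null(dispersions)) {
    grp <- interaction(design[, all.vars(full), drop = FALSE], drop = TRUE)
    dispersions <- estimateDispersionsMoM(m, grp, sizeFactors)
  }
  offset <- log(sizeFactors)
  n_genes <- nrow(m)
  lfc <- se <- stat <- p <- rep(NA_real_, n_genes)
  baseMean <- rowMeans(sweep(m, 2, sizeFactors, "/"))
  for (g in seq_len(n_genes)) {
    y <- m[g, ]
    if (all(y == 0)) next
    ff <- nbGlmFit(y, Xf, offset, dispersions[g])
    fr <- nbGlmFit(y, Xr, offset, dispersions[g])
    if (!ff$converged || !fr$converged) next
    stat[g] <- if (df == 0) 0 else max(0, 2 * (ff$loglik - fr$loglik))
    p[g] <- if (df == 0) 1 else pchisq(stat[g], df = df, lower.tail = FALSE)
    k <- ncol(Xf)
    lfc[g] <- ff$beta[k] / log(2)
    se[g] <- ff$se[k] / log(2)
  }
  res <- deResultFrame(rownames(m), baseMean, lfc, se, stat, p, "lrt")
  S4Vectors::metadata(res)$df <- df
  res
}

#' Per-gene two-way ANOVA on log-transformed normalized counts
#'
#' Ordinary least squares of log2(normalized count + 1) on two crossed
#' factors with interaction, classic sequential F tests per gene.  All four
#' factor combinations must be represented.  Genes with constant response
#' get NA p-values by convention (zero residual variance).
#'
#' @param counts Count matrix or SummarizedExperiment.
#' @param design data.frame of sample covariates.
#' @param factors Length-2 character vector naming the factors
#'   (default hemisphere, exercise).
#' @param sizeFactors Optional size factors.
#' @return data.frame with one row per gene: p-values for each main effect
#'   and the interaction.
#' @export
perGeneTwoWayAnova <- function(counts, design = NULL,
                               factors = c("hemisphere", "exercise"),
                               sizeFactors = NULL) {
  m <- countsMatrix(counts)
  if (is.null(design) && is(counts, "SummarizedExperiment"))
    design <- as.data.frame(colData(counts))
  f1 <- droplevels(as.factor(design[[factors[1]]]))
  f2 <- droplevels(as.factor(design[[factors[2]]]))
  if (nlevels(f1) < 2 || nlevels(f2) < 2 || any(table(f1, f2) == 0))
    stop("empty cell in the two-way design")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(m)
  logn <- log2(sweep(m, 2, sizeFactors, "/") + 1)
  X <- model.matrix(~ f1 * f2)
  # sequential (type I) sums of squares via nested projections; balanced
  # designs make type I and type III identical
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  n <- ncol(m)
  df_res <- n - ncol(X)
  out <- data.frame(row.names = rownames(m))
  terms <- c(factors[1], factors[2], "interaction")
  p_mat <- matrix(NA_real_, nrow(m), 3,
                  dimnames = list(rownames(m), terms))
  F_mat <- p_mat
  for (g in seq_len(nrow(m))) {
    y <- logn[g, ]
    fit <- lm.fit(X, y)
    rss_full <- sum(fit$residuals^2)
    ss <- df <- numeric(3)
    rss_prev <- sum((y - mean(y))^2)
    for (k in 1:3) {
      Xk <- X[, asgn <= k, drop = FALSE]
      rk <- sum(lm.fit(Xk, y)$residuals^2)
      ss[k] <- rss_prev - rk
      df[k] <- sum(asgn == k)
      rss_prev <- rk
    }
    if (rss_full > 1e-12 && df_res > 0) {
      ms_res <- rss_full / df_res
      F_mat[g, ] <- (ss / df) / ms_res
      p_mat[g, ] <- pf(F_mat[g, ], df, df_res, lower.tail = FALSE)
    }
  }
  data.frame(F_mat, p_mat, check.names = FALSE,
             row.names = rownames(m)) |>
    setNames(c(paste0("F_", terms), paste0("p_", terms)))
}

#' Benjamini-Hochberg adjustment with NA handling
#'
#' Standard step-up BH on the non-NA p-values; NAs (non-converged or
#' all-zero genes) are excluded from the batch, not assigned p = 1, and
#' reinserted as NA.
#'
#' @param p Numeric vector of p-values in [0, 1], NAs allowed.
#' @return Adjusted p-values, same length and order.
#' @export
adjustBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' Strict thresholds: up = log2FC > lfcCut and p < pCut; down = log2FC <
#' -lfcCut and p < pCut.  The default cutoff log2(1.3) = 0.3785 encodes the
#' ">30% expression change" criterion; raw p gates the call by default
#' (adjusted p available via `use = "padj"`).
#'
#' @param de Result of [nbWaldTest()] or [nbLRT()] (needs log2FoldChange
#'   plus the chosen p column).
#' @param lfcCut Absolute log2 fold-change cutoff (default log2(1.3)).
#' @param pCut P-value cutoff (default 0.05).
#' @param use "pvalue" (default) or "padj".
#' @param contrast Label for the resulting sets.
#' @return A \linkS4class{DEGSets}.
#' @export
callDegs <- function(de, lfcCut = log2(1.3), pCut = 0.05,
                     use = c("pvalue", "padj"), contrast = "contrast") {
  use <- match.arg(use)
  if (isTRUE(all.equal(lfcCut, 0.3875, tolerance = 1e-9)))
    warning("lfcCut = 0.3875 looks like a transcription of log2(1.3) = ",
            "0.3785; proceeding with 0.3875 as given")
  lfc <- de$log2FoldChange
  p <- de[[use]]
  ids <- rownames(de)
  ok <- !is.na(lfc) & !is.na(p)
  up <- ids[ok & lfc > lfcCut & p < pCut]
  down <- ids[ok & lfc < -lfcCut & p < pCut]
  new("DEGSets", up = up, down = down, contrast = contrast,
      lfcCut = lfcCut, pCut = pCut)
}
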