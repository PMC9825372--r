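# primeseq

Paired translatome–epigenome analysis of exercise-primed gene expression.

## The problem

Early-life exercise (ELE) in mice improves hippocampal memory: after three
weeks of voluntary wheel running, a 3-minute object-location training session
— normally too short to form a long-term memory — becomes sufficient. One
candidate mechanism is epigenetic *priming*: exercise deposits permissive
histone marks (e.g. H4K8ac) or removes repressive ones (H3K27me3) at
plasticity genes, without changing their expression, so that a later learning
stimulus can transcribe them efficiently.

Testing this requires joining two sparse, noisy data types from the same
neurons: translating-ribosome mRNA counts (TRAP-seq) across behavioral
groups, and antibody-directed chromatin coverage (CUT&RUN) for H4K8ac,
H3K27me3 and an IgG background control. `primeseq` implements that joint
analysis as a tested, reusable pipeline, plus a synthetic-data generator that
plants known differential expression, peaks and priming structure so every
stage can be validated against ground truth.

## What it computes

- **Differential expression** — per-gene negative binomial GLMs
  (median-of-ratios size factors `s_j`, method-of-moments dispersions
  `alpha_g`, IRLS fits of `K_gj ~ NB(s_j mu_g 2^{x_j' beta_g}, alpha_g)`),
  Wald z and likelihood-ratio chi-squared tests, per-gene two-way ANOVA, BH
  adjustment. A gene is called differentially expressed when
  `|log2FC| > log2(1.3) = 0.3785` and `p < 0.05`.
- **Peak calling** — maximal runs of positive coverage scored by AUC
  (depth × length, the SEACR statistic), retained either above the top-1%
  AUC quantile or above the threshold maximizing separation from the IgG
  track, with a per-sample empirical FDR (`#control blocks ≥ t / #target
  blocks ≥ t`; samples with FDR > 0.1 fail QC).
- **Annotation** — each peak gets one genomic category by priority
  (Promoter ±3 kb of TSS, 5'UTR, 3'UTR, Exon, Intron, Downstream ≤3 kb,
  DistalIntergenic) and one gene (nearest TSS on ties).
- **Priming integration** — gene-level mark dynamics (`new`/`lost`/`shared`
  between ELE and sedentary), overlap with DEG sets, and the candidate
  memory-gene classes over four behavioral groups, all relative to an
  untrained sedentary baseline:
  `cGAMES = deg(ELE+3min) ∩ deg(SED+10min)`,
  `cGAME = deg(ELE+3min) \ (others)`, `cGAMS = deg(SED+10min) \ (others)`;
  then the fraction of each class carrying a permissive change (new H4K8ac
  or lost H3K27me3 for upregulated classes) and a z-score sign-concordance
  across learning groups.
- **Comparability statistics** — 100-bp binned-coverage Spearman
  correlations between tracks (isolation-method and hemisphere concordance;
  significance rule rho > 0.5, p < 2.2e-16) and gene-length-bias summaries
  with a permutation comparison.

## Worked example

```r
library(primeseq)
fx  <- makeFixtureStudy(seed = 42)   # synthetic study with planted truth
res <- runPrimingPipeline(fx$counts, fx$tracks, fx$genome)

res$degs$ELE_3min
#> DEGSets 'ELE_3min vs baseline': 177 up / 203 down (|log2FC| > 0.3785, p < 0.05)
res$peaks$`H4K8ac.ELE`
#> PeakSet 'H4K8ac.ELE': 526 peaks (stringent, control threshold 30, empirical FDR 0)
res$classification
#> GameClassification (vs baseline):
#>   up   cGAME: 97  cGAMES: 69  cGAMS: 47
#>   down cGAME: 112  cGAMES: 81  cGAMS: 42
res$report
#> PrimingReport
#>   cGAME  up  : 28/97 primed (29%)
#>   cGAMES up  : 26/69 primed (38%)
#>   ...
#>   z-score concordance (ELE+3min vs SED+10min): 0.357

scoreRecovery(fx$truth, res$classification, res$report)$f1
#> [1] 0.905
```

Reading: of the genes upregulated only after exercise-enabled learning
(cGAME), 29% carried a new H4K8ac peak or lost H3K27me3 after exercise alone
— candidates primed by exercise for later transcription. The fixture planted
30% and 40% priming at the cGAME/cGAMES up-classes; the pipeline recovers
the classes at F1 ≈ 0.9 and the fractions within a few points under the
default noise model (exactly, under the noise-free setting).

Real data enter through `readCountTable()`/`readDesignTable()` (TSV),
`readBedGraph()` (UCSC bedGraph) and `readGeneAnnotation()` (BED12 or
minimal GTF); results leave as TSV/BED via `writePeaksBed()` and the
pipeline's `outDir` argument.

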