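---
title: "Comparing duodenal transcriptomes across malnutrition cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing duodenal transcriptomes across malnutrition cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteroDEG)
```

## The problem

Environmental enteric dysfunction — chronic, usually asymptomatic
small-intestinal inflammation in disadvantaged environments — is studied by
contrasting duodenal gene expression in children with non-responsive
stunting, children hospitalised with severe acute malnutrition (SAM), and
adults from the same community. The raw material is a bulk RNA-seq FPKM
matrix (transcripts × biopsies) and a table assigning each biopsy to a
cohort. `enteroDEG` packages the comparative analysis of such a design as
composable, individually tested functions; it deliberately starts *after*
read alignment and FPKM quantification, which belong to sequencing-facility
pipelines, and it does not attempt literature-mining theme discovery, for
which proprietary tools exist — gene sets are supplied by the user in GMT
format instead.

## Preprocessing

FPKM values are quantile-normalized across samples: every column is mapped
onto the common reference distribution formed by averaging the k-th order
statistics across samples, which equalizes sample distributions while
preserving within-sample ranks. Ties need a convention: all members of a
tie group receive the mean of the reference values spanned by the group's
rank range. This is deterministic, keeps a constant column constant at the
reference mean, and reduces to plain sort-average-reassign on tie-free
data (where it coincides with `limma::normalizeQuantiles`). The reference
distribution and tie policy are recorded in a normalization report so a
run's convention is always inspectable.

Where a symmetric scale is needed (PCA, fold-change displays) the package
uses log₂(FPKM + 1); the pseudocount of 1 keeps zero at zero and is
invertible.

## The two differential-expression procedures

**Ratio tails.** For cohorts (a, b) the per-gene statistic is
log₂((m̄ₐ + ε)/(m̄ᵦ + ε)) on cohort means, with ε = 0.01. "Outside the 95%
confidence limits of the ratio" is operationalized as empirical rank
selection: with n rankable genes, exactly k = ⌊n · α/2⌋ genes per tail at
α = 0.05. The empirical reading — rather than a parametric
mean ± 1.96·SD band — is forced by arithmetic: a transcriptome of 20,120
genes repeatedly yields ~503 calls per tail, which is exactly 2.5% of the
genes and is what rank selection guarantees for any continuous ratio
distribution; a parametric band would not. Genes whose means are zero in
*both* cohorts have no usable ratio and are excluded before ranking
(plausibly why slightly smaller counts such as 501 or 502 arise in real
data); genes zero on one side stay rankable thanks to ε. Ties in the
ranking are broken by gene identifier so results are platform-independent.

**Trimming.** Tail calls are then filtered on expression level: the
default `mode = "any"` keeps a call when either cohort mean is ≥ 1 FPKM
(the convention that matches trimmed supplementary gene lists phrased as
"either FPKM value greater than 1"), while `mode = "both"` requires both
(the convention of scatter and dot-plot displays). Both conventions are
genuinely in use, so both are implemented and the choice is explicit in
every call; trimming never alters tail flags, only a `trimmed_out` marker,
so the selection and the filter remain separately auditable.

**Strict filter.** The second procedure tests individual samples rather
than means: a gene passes when |log₂ FC| > log₂ 2.5 and the two-sided
Mann-Whitney p across samples is < 10⁻⁶. The Mann-Whitney implementation
is exact (full enumeration of the rank distribution) for tie-free groups
of up to 8 + 8 and otherwise uses the normal approximation with tie and
continuity corrections. With the study's cohort sizes (27–37 per group)
the 10⁻⁶ threshold is attainable (complete separation gives p ≈ 10⁻¹¹);
users should note that for groups below ~13 + 13 it is not, and the filter
then passes nothing. A Bonferroni-adjusted p (min(1, p·m), m = genes
tested) is reported alongside the raw p because with m ≈ 20,000 the raw
10⁻⁶ cut corresponds to a family-wise bound of about 0.02; the pass flag
is driven by the raw threshold, and both columns are in the output so
either convention can be audited.

## Panels, enrichment, ordination

Three built-in panels cover the functional domains most affected in
enteropathy: solute carriers (prefix SLC), xenobiotic-metabolizing enzymes
(prefixes CYP, UGT, GST, SULT, ADH, ALDH, FMO, NAT, EPHX — a heuristic,
since no canonical list exists; any GMT can override it), and the 21
digestive / brush-border enzyme genes shipped with their printed cohort
mean FPKM as a frozen, checksum-guarded fixture. Panel reports apply the
display rule of the corresponding dot plots: a gene is display-eligible
when its ratio lies in a selected tail *and* both cohort means exceed
1 FPKM.

Over-representation of a query gene list in user-supplied sets uses the
upper-tail hypergeometric test against a universe that defaults to all
matrix rows (all mapped transcripts); restricting to expressed genes is a
caller choice, since no universe definition is canonical. q-values are
Benjamini-Hochberg. Theme summaries are the median log₂ ratio of a set's
genes per comparison — the quantity behind theme heatmaps; sign carries
direction, and colour mapping is left to the caller.

PCA runs on gene-centred log₂(FPKM + 1) without variance scaling —
after quantile normalization all samples already share one scale, and
scaling per gene would up-weight near-zero genes — preceded by a filter
keeping genes with within-cohort median FPKM ≥ 1 in at least one cohort.
Components carry a deterministic sign convention (largest-magnitude
loading positive). Cohort ellipses are covariance-coverage ellipses: the
member mean, semi-axes √(χ²₂(0.95)·λᵢ) from the eigenvalues of the 2-D
score covariance, rotation from the eigenvectors. A standard-error
(mean-uncertainty) ellipse would be ~√n smaller; coverage ellipses are
implemented because the display's purpose is cohort spread, and the choice
is labelled in the output. Degenerate (zero-variance) cohorts are flagged
rather than erroring.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of the three-cohort
study, not its biology: 20,120 genes; cohorts of 30 (stunting), 27 (SAM)
and 37 (adult) samples; per-gene baseline log₂ level b ~ N(3, 2.5) with 10%
of genes forced to a near-zero baseline (2⁻⁶ FPKM); per-gene noise
sd ~ U(0.25, 0.6) log₂; planted log₂ effects |δ| ~ N(1.8, 0.5) on 2.5% of
genes per direction for stunting and 4% per direction for SAM, half of the
stunting effects recurring in SAM with the same sign (the shared
enteropathy signature); HIV status generated at the observed 0/33%/32%
rates but carrying no expression effect by default. The model is
log-normal rather than count-based because the pipeline's input is
continuous FPKM and all its statistics operate on FPKM. Defaults were
chosen once so that cohort-mean Spearman correlations across genes match
the observed 0.94–0.96 range (they land near 0.98) and most genes are
expressed in adults; noise has no published dispersion summary to
calibrate against, so the range is a field-typical choice.

What passing tests on this generator do show: the selection, trimming and
testing machinery recovers planted mean-shift effects at the study's
sample sizes with high sensitivity and precision, and stays specific under
the null. What they cannot show: robustness to library-depth artefacts,
batch structure, compositional effects, or count noise at low expression —
none of which the log-normal model produces.

## Numerical and design choices

* Ratio pseudocount ε = 0.01 — small against the 1-FPKM trim threshold,
  keeps one-sided-zero genes rankable; both-zero genes are excluded
  outright.
* Tail ties broken by gene id; quantile-normalization ties averaged over
  the rank range; both choices exist for cross-platform determinism.
* `tail_select` with k = 0 (tiny n or α) warns and selects nothing rather
  than failing, so degenerate configurations complete with empty tables.
* Exact-vs-approximate Mann-Whitney switch at 8 + 8: exact enumeration is
  cheap there and the normal approximation is already within 0.02 absolute
  p at that size.
* The end-to-end `reproduce()` writes every table as TSV plus a manifest
  of MD5 content hashes, so determinism can be asserted by comparing
  manifests without parsing outputs.
* Test and validation problem sizes: oracle suites run at n ≤ 1,000
  (tail selection), 8 + 8 (rank-test enumeration), N ≤ 12 (urn
  enumeration); recovery checks use the full 20,120 × 94 generator at 3–5
  seeds — sizes at which the whole suite completes in a couple of minutes
  on a laptop.

## Limitations

The ratio procedure tests cohort *means* only; a fixed fraction of genes
is always called, so calls are claims of extremity relative to the
transcriptome, not hypothesis-test rejections. The strict filter's raw
10⁻⁶ threshold is conservative and sample-size-limited, as noted above.
Prefix-based panels are heuristics. The generator plants effects relative
to the adult baseline; contrasts between the two child cohorts inherit
truth as the difference of the planted deltas.
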