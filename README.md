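# enteroDEG

Tools for comparing bulk duodenal transcriptomes across three cohorts —
children with non-responsive stunting, children with severe acute
malnutrition (SAM), and adults from the same community — the setting in
which environmental enteric dysfunction is studied. The package starts from
a gene-by-sample FPKM matrix and a cohort design table and provides the
whole comparative workflow as tested, reusable functions, together with a
calibrated synthetic-data generator so every step can be validated against
planted ground truth.

## What it computes

Starting from quantile-normalized FPKM (every sample is forced onto the
mean-of-order-statistics reference distribution, ties averaged), the
package implements two complementary differential-expression procedures on
cohort means:

1. **Ratio / 95%-confidence-limit calling.** For a pair of cohorts (a, b)
   and per-gene means m̄ₐ, m̄ᵦ, the statistic is the ratio
   r = (m̄ₐ + ε)/(m̄ᵦ + ε) with pseudocount ε = 0.01. Genes are called in
   the empirical tails of the log₂ r distribution: with n rankable genes and
   tail mass α = 0.05, exactly k = ⌊n·α/2⌋ genes per tail
   (20,120 transcripts → 503 per tail). Called genes are then *trimmed* by
   requiring a group-mean FPKM ≥ 1 in either (default) or both cohorts.
2. **Strict filter.** A gene passes when |log₂ FC| > log₂ 2.5 **and** the
   two-sided Mann-Whitney p across the individual samples is < 10⁻⁶
   (exact for tie-free groups up to 8 + 8, otherwise normal approximation
   with tie and continuity corrections; Bonferroni-adjusted p reported
   alongside).

Around these sit: curated functional panels (solute carriers, xenobiotic
enzymes, brush-border digestive enzymes — the latter shipped with its
printed reference means), hypergeometric over-representation with
Benjamini-Hochberg q-values and theme-median summaries, PCA of samples on
gene-centred log₂(FPKM+1) with χ²-quantile cohort confidence ellipses, and
a log-normal synthetic generator that plants cohort effects and records
them as truth for sensitivity/precision checks.

## Worked example

```r
library(enteroDEG)

# synthetic three-cohort study: 20,120 genes, cohorts of 30/27/37 samples
sim <- generate_dataset(synth_params(seed = 42))
qn  <- quantile_normalize(sim$matrix)
gm  <- group_means(qn$matrix, sim$design)

rec <- compute_ratio_records(gm, "SAM", "adult")
rec <- trim_deg(tail_select(rec, alpha = 0.05))
up  <- deg_list(rec, "up"); dn <- deg_list(rec, "down")
cat("selected up:", up$n_selected, " after trim:", up$n_after_trim, "\n")
cat("selected down:", dn$n_selected, " after trim:", dn$n_after_trim, "\n")
```

```
selected up: 503  after trim: 492
selected down: 503  after trim: 461
```

503 genes per tail is ⌊20,120 × 0.025⌋ — the tail rule selects a fixed
fraction; trimming then discards calls whose means sit below 1 FPKM in both
cohorts. Recovery against the generator's planted truth:

```r
tt     <- truth_table(sim$truth, "SAM", min_abs_log2 = 2)
sel_up <- rec$gene_id[rec$tail == "upper" & !rec$trimmed_out]
cat("planted up genes recovered:", sum(tt$up %in% sel_up), "of", length(tt$up), "\n")
```

```
planted up genes recovered: 275 of 278
```

The packaged digestive-enzyme reference means work directly as group
summaries; lactase (LCT) shows the expected child/adult contrast:

```r
fx <- table2_fixture()
r  <- compute_ratio_records(fx, "stunting", "adult")
head(r[order(-r$ratio), c("gene_id", "num_mean", "den_mean", "ratio")], 3)
```

```
 gene_id num_mean den_mean     ratio
     LCT    363.1     14.0 25.917916
   PRSS2    267.9     87.2  3.072010
   PRSS1      0.2      0.1  1.909091
```

An end-to-end run (simulate → normalize → all three pairwise contrasts,
both directions → panels → PCA) with a content-hash manifest:

```r
reproduce(run_config(seed = 42), out_dir = "run42")
```

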