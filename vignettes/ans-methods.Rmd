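---
title: "Adjusted Neighborhood Scoring: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusted Neighborhood Scoring: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansscore)
```

## The scoring model

Let $X \in \mathbb{R}_{\ge 0}^{n \times p}$ be a preprocessed (normalized,
log-transformed) expression matrix over $n$ cells and $p$ genes, and
$S = \{s_1, \dots, s_m\}$ a gene signature. Control-based (Tirosh-style)
scoring assigns every signature gene $s$ a control gene set $C_s$ of
expression-matched background genes and scores cell $j$ as

$$\mathrm{score}_j \;=\; \frac{1}{m} \sum_{s \in S}
  \Big( X_{j,s} - \tfrac{1}{|C_s|} \textstyle\sum_{k \in C_s} X_{j,k} \Big).$$

Subtracting a matched background mean removes cell-level technical effects:
adding any constant to all genes of a cell shifts the signature term and the
control term equally, leaving the score unchanged (a property the test
suite asserts).

Everything that distinguishes the methods in this package is *how $C_s$ is
chosen*:

* **`seurat` / `scanpy_bins`** — genes are sorted by their average
  expression $\bar g$ over all cells and cut into `n_bins` (default 25)
  equally sized expression bins; $C_s$ is a random sample of
  `control_size` (default $c = 100$) non-signature genes from $s$'s bin
  (`seurat` draws per signature gene, `scanpy_bins` draws one pooled set
  per bin). Random, hence seeded.
* **`seurat_ag`** — all non-signature genes of $s$'s bin; ignores $c$.
* **`seurat_lvg`** — the $c$ in-bin genes with the smallest dispersion
  (see below).
* **`ans`** (Adjusted Neighborhood Scoring) — the contiguous window of $c$
  genes in the signature-free sorted mean profile $\tilde g$ whose average
  mean expression is closest to $\bar g_s$:
  $$C_s = \arg\min_{C_k} \Big| \bar g_s - \tfrac{1}{c}
    \textstyle\sum_{\bar g_l \in C_k} \bar g_l \Big|,
    \qquad C_k = \{\tilde g_k, \dots, \tilde g_{k+c-1}\}.$$
  Because the mean-expression distribution is long-tailed, the top
  expression bin spans a huge mean range and bin-based control selection
  is badly biased there; a per-gene neighborhood window removes that bias
  and is fully deterministic.

Signature genes ranked within the top $\lfloor c/2 \rfloor$ genes by mean
expression cannot receive a centered window, so `ans` excludes them before
scoring and reports them. If that empties the signature, the error message
recommends shrinking the control set or extending the signature — the two
remedies that actually help.

The two rank-based comparators do not use controls. **UCell** ranks all
genes per cell by decreasing expression (averaged ties), clamps ranks
beyond `max_rank` (default 1500) to `max_rank + 1`, and maps the
Mann–Whitney statistic $U$ of the signature ranks to
$1 - U/(m \cdot \mathrm{max\_rank}) \in [0,1]$; a cell's score depends on
that cell alone, so UCell is immune to dataset composition. **JASMINE**
averages two min–max-normalized components: the mean rank of expressed
signature genes among all expressed genes of the cell, and an enrichment
value (odds ratio or likelihood) from the per-cell 2×2
expressed/non-expressed × signature/non-signature table.

## Score-based annotation and its two metrics

With one signature per candidate cell type, each cell is labeled by its
highest-scoring signature (argmax; ties go to the first column and are
logged). Argmax labels survive any strictly increasing transformation
applied jointly to all score columns, but *not* per-column shifts — which
is why score-range comparability across signatures matters, and why it is
quantified by two numbers:

* **information quantity** — mean held-out balanced accuracy of an
  unpenalized multinomial logistic regression predicting the true labels
  from the score matrix, under stratified 10-fold cross-validation
  (seeded, deterministic). This is what the scores *could* deliver if
  scales were allowed to be recalibrated per signature.
* **scale imbalance** — the absolute gap between information quantity and
  the balanced accuracy of plain argmax labeling. Near zero means argmax
  already realizes the information in the scores.

The classifier is multinomial (softmax) rather than one-vs-rest and is fit
unpenalized with a fixed iteration cap; regularization would leak scale
information into the supervised benchmark and make the gap
uninterpretable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `control_size` ($c$) | 100 genes | window / sample size of each control set; also fixes the top-$\lfloor c/2\rfloor$ exclusion zone |
| `n_bins` | 25 | expression bins for the bin-based strategies |
| `max_rank` | 1500 | UCell rank clamp; scores saturate to 0 beyond it |
| `seed` | none | only consumed by the sampled-bin strategies |

Defaults follow the values in routine use in the field's toolkits. The
control size trades bias (small $c$: noisy control means) against the
width of the exclusion zone (large $c$: more signature genes dropped).

## Numerical choices

* Mean profiles use a **stable sort**: genes with tied means keep their
  column order, making every bin assignment and window selection
  deterministic and reproducible bit for bit.
* When $p$ is not divisible by `n_bins`, the extra genes go to the
  **lowest-expression bins** (sizes differ by at most one). Any fixed
  convention would do; this one is documented and stable.
* ANS window ties (two windows at equal distance) resolve to the
  **lower-expression window** (leftmost index). Window means over a sorted
  profile are nondecreasing, so the objective is unimodal; the
  implementation still scans all windows from one cumulative sum, and the
  test suite checks it against exhaustive enumeration on hundreds of
  random instances.
* `seurat_lvg` dispersion is the variance/mean ratio on the expm1
  (de-logged) scale, z-scored within 20 mean-expression bins — the
  statistic of the standard "seurat"-flavor highly-variable-genes routine.
  The raw (non-z-scored) ratio is available via `lvg_raw_dispersion` for
  sensitivity checks, since published descriptions of the least-variable
  strategy do not pin this down.
* JASMINE needs guards for degenerate per-cell 2×2 tables: a cell with no
  expressed signature gene gets enrichment (and rank component) 0; a cell
  whose denominator vanishes with expressed signature genes present gets
  the maximum enrichment observed among well-defined cells. Both choices
  keep scores finite and monotone in the number of expressed signature
  genes, and are logged when triggered. Min–max normalization is applied
  over the whole dataset (not per batch), matching how the method is used
  in practice.
* `bin_sampled` draws an independent control sample **per signature
  gene**, which is what the scoring formula implies; the pooled
  one-draw-per-bin variant used by some implementations is available as
  `pooled_bins = TRUE` (`scanpy_bins` in `score_all`).
* The top-expression exclusion ranks signature genes against **all** genes
  (not only non-signature genes) — the stricter reading, and the one that
  makes the exclusion zone independent of the signature.

## The synthetic data generator

`generate_dataset()` emulates the features of real scRNA-seq data that
signature scoring is actually sensitive to:

* a **long-tailed baseline**: per-gene means are log-normal
  (`baseline_meanlog = 0`, `baseline_sdlog = 1`), which reproduces the
  wide top expression bin that drives control-selection bias;
* **cell types with markers**: each type's marker genes are upregulated
  by `marker_log2fc` (default 2) in that type. Markers are drawn from the
  50th–90th percentile of the baseline — detectable but not ubiquitous,
  as curated marker genes are; markers from the low tail would carry no
  signal and markers from the top tail can have no valid control window;
* **dropout**: values are zeroed so that the overall zero fraction matches
  `dropout_rate`. By default the zeroing probability is logistic in the
  gene's log mean (steepness: half the spread of log means), concentrating
  zeros in weakly expressed genes as droplet protocols do; a uniform
  Bernoulli variant is available. The calibration is a monotone root-find
  on the logistic intercept;
* **multiplicative noise**: per-value log-normal with `noise_sd = 0.5`
  on the log scale, roughly a 50% coefficient of variation;
* **samples and batches**: cells are spread over samples with
  Dirichlet(`composition_alpha = 2`) weights per type, so per-sample
  cell-type composition varies as it does across real specimens — the
  mechanism that makes per-sample control selection unstable. Each batch
  carries a `depth_factor` that multiplies the dropout keep-odds,
  mimicking capture-efficiency differences between sequencing chemistries
  (an effect that survives library-size normalization, unlike a plain
  scaling factor, which normalization would cancel exactly);
* after marker effects, noise and dropout, cells are library-size
  normalized to the median total and log1p-transformed.

The `"high_sparsity"` preset reproduces the hardest regime (about 90%
zeros). What the generator does **not** emulate: count-level sampling
(negative binomial), doublets, ambient RNA, gene–gene correlation beyond
the marker blocks, and continuous state transitions. Tests passing on this
generator therefore demonstrate the methods' contracts and comparative
behavior under composition, dropout and batch structure — not performance
on any particular tissue.

## Benchmark procedures and the problem sizes used

The packaged experiments run at sizes chosen to make their statistical
targets measurable while completing in minutes on a laptop:

* **control-bias scan**: homogeneous data, 1000 cells × 2000 genes; the
  top 8% of genes (160) scored as single-gene signatures; ANS cannot score
  the top 50 (exclusion zone), leaving 110. On homogeneous data the mean
  single-gene score estimates pure control bias; ANS stays within three
  standard errors of zero essentially everywhere while bin-based controls
  show two orders of magnitude larger absolute bias in the top bin.
* **joint vs per-sample scoring**: 6 samples in 2 batch groups
  (capture-odds factor 2), 720 cells × 1200 genes, 20 generator seeds.
  Scoring all samples together yields lower across-sample variance of
  per-sample mean scores than per-sample scoring, and a null calibration
  (no batch shift) keeps the two-sided Mann–Whitney batch test's p-values
  centered.
* **signature-length sweep**: grows ranked marker prefixes until AUCROC
  reaches 1; control-based methods first drop genes in the
  $\lfloor c/2\rfloor$ lowest/highest expression ranks, where no valid
  control set exists.
* **noise robustness**: a pure 100-gene marker signature on 600 cells ×
  2000 genes; genes progressively replaced (nested within run) by genes
  with no class signal (rank-sum adjusted p > 0.01, |log2FC| ≤ 0.5);
  20 runs. ANS keeps AUCROC above 0.9 up to 85% replacement and falls to
  chance at full replacement.
* **marker selection**: class-vs-rest rank-sum tests with tie-corrected
  normal approximation, Benjamini–Hochberg adjustment, log2 fold-changes
  on expm1-scale means with a 1e-9 pseudocount, top genes by z-score.

## Known limitations

* ANS assumes enough non-signature genes to form windows
  ($p - m \ge c$) and refuses to score signatures living entirely in the
  top expression ranks; both conditions produce actionable errors.
* The information-quantity classifier is linear; score sets that are
  informative only through nonlinear combinations would be undervalued.
* JASMINE's min–max normalization makes its scores dataset-dependent by
  construction; per-cell deletion invariance holds for UCell only.
* The generator's independence assumptions make synthetic separation
  tasks easier than transcriptionally similar real cell states; absolute
  accuracies on synthetic data should not be read as field performance.
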