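---
title: "Scoring genetic interactions in two-context pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in two-context pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giscreen)
```

## The problem

A pooled CRISPR/Cas9 dropout screen infects a cell population with a guide
library at low multiplicity, passages the pool, and sequences guide
abundances over time. Guides that knock out fitness genes decline; the
log2 fold change (LFC) of a guide's depth-normalized abundance between an
endpoint and the starting timepoint (T0) is its fitness readout. Running
the *same* library in two genotype contexts — a control background and a
query-mutant background — and contrasting the two fitness profiles yields
genetic-interaction (GI) scores: genes whose loss is differentially
tolerated in the mutant. Negative GI scores flag synthetic sick/lethal
relationships; positive scores flag buffering or suppression.

`giscreen` implements this analysis end to end: count ingestion and guide
filtering, fitness estimation, cross-context normalization, gene-level
testing, screen quality control, and gene-set summarization, plus a
ground-truth simulator used throughout the test suite.

## Pipeline and model

Given a raw count matrix (guides x samples), a sample sheet
(context/timepoint/replicate per sample) and a guide library
(guide-to-gene map), `score_gi_screen()` performs:

1. **Guide filtering.** Guides with a raw T0 count below 30 or above
   10000 in *any* T0 sample of either context are excluded (strict
   inequalities; counts of exactly 30 or 10000 are kept). Low-abundance
   guides carry mostly sampling noise; extreme-abundance guides indicate
   library artifacts. Filtering on T0 rather than all timepoints is
   deliberate: essential-gene guides are *supposed* to fall below the low
   bound by the endpoint, and filtering on later timepoints would remove
   exactly the biology the screen measures. A guide excluded in either
   screen of the pair is excluded from both, so every scored guide has a
   defined differential.

2. **Depth normalization.** Counts plus a pseudocount of 1 are scaled to
   reads per million per sample and log2-transformed. The pseudocount is
   the minimal convention that keeps LFCs defined for guides that drop to
   zero reads; it biases very-low-count LFCs mildly toward zero
   (conservative for dropout estimates).

3. **Fitness (LFC).** Per guide, context and replicate:
   `lfc = log2RPM(endpoint) − log2RPM(T0)`, with the T0 sample matched by
   replicate label. Any sampled timepoint can serve as the endpoint, so
   the analysis can be run along the time course (e.g. day 6, 12, 18).

4. **MA/loess normalization.** Per replicate pair, guide LFCs from the
   two contexts are re-expressed as `M = lfc_mutant − lfc_control` and
   `A = (lfc_mutant + lfc_control) / 2`. A smooth trend `f(A)` is fitted
   and subtracted, giving the normalized mutant LFC
   `lfc_control + (M − f(A))`. This removes abundance-dependent bias
   between the screens (e.g. differential PCR or sampling efficiency along
   the abundance range) that would otherwise masquerade as interaction
   signal. The smoother sorts guides along A into 20 equal-count bins,
   summarizes each bin by its **median** (A, M), and predicts by
   tricube-weighted local linear regression over the nearest
   `ceiling(span * bins)` bin summaries (span 0.3). The median summary is
   a robustness choice: genuine interactors shift both M and A, and a
   mean-based trend visibly chases clusters of true interactors in
   sparsely populated A ranges, subtracting real signal from their
   neighbours; the median ignores an interactor minority within a bin.
   Both `span` and `bins` are exposed; with fewer guides than bins the
   fit falls back to a global median with a warning. Local linear fits
   reproduce constant and linear trends exactly, so the normalization is
   exactly idempotent on such trends; on arbitrary data a binned local
   smoother is not a projection and a second pass changes values by a
   small but nonzero amount.

5. **Replicate averaging and GI scores.** Normalized LFCs are averaged
   over replicates per (guide, context); the guide GI score is the
   mutant-minus-control difference of these means, and the gene GI score
   is the plain mean of its guide scores.

6. **Moderated one-sample t-test.** Per gene, the k guide GI scores are
   tested against zero. With hundreds of genes and only ~3 guides each,
   per-gene variances are unstable, so they are shrunk toward a common
   prior by empirical Bayes: the prior `(d0, s0²)` is estimated by
   matching the mean and variance of `log(s²)` across genes to a log
   scaled-F distribution (digamma/trigamma moment matching, with Newton
   inversion of the trigamma function). The posterior variance is
   `s²_post = (d0·s0² + (k−1)·s²) / (d0 + k − 1)` and
   `t = mean / sqrt(s²_post / k)` on `d0 + k − 1` degrees of freedom.
   At `d0 = 0` this is exactly the classical one-sample t; at `d0 = ∞`
   every gene uses the common variance. If the observed spread of log
   variances does not exceed its pure-sampling component, the estimate is
   `d0 = ∞` — handled, not an error. Genes with one surviving guide keep
   their score but receive no p-value. Two-sided p-values are
   BH-adjusted, and interactors are called at `fdr < 0.2` and
   `|gi_score| > 0.5` (both strict).

7. **Quality control.** `qc_report()` computes (i) Pearson correlations
   of guide-level LFC vectors between all replicate pairs and (ii) the
   essential-gene dropout AUC-ROC: genes ranked by dropout strength
   (negative mean LFC) against a provided essential-gene standard, by the
   rank/Mann-Whitney formula with midranks. Well-executed screens of this
   design show replicate r above 0.9 and AUC above 0.85. Gene-level LFC
   aggregation over guides uses the mean (configurable to median).

8. **Gene-set summaries.** `term_zscores()` computes, per gene set,
   `z = (x̄ − μ) / (σ / √n)` with `x̄` the mean GI of the term's member
   genes, `μ` and `σ` the mean and **sample** standard deviation (n−1
   denominator; the population/sample choice is not standardized in this
   statistic, and the sample SD is the conservative pick) of GI scores
   across all scored library genes, and `n` the member count. Two-tailed
   normal p-values are BH-adjusted. Terms with fewer than 3 library genes
   are dropped before testing; membership is intersected with the set of
   genes that actually have scores, and no ontology-graph propagation is
   performed — the annotation arrives as a flat term-to-gene table.

## The simulator

`simulate_library()` and `simulate_screen()` generate screens with known
ground truth. Each gene gets a category — essential, positive or negative
interactor, or null — and per-context fitness in log2 units/day; per-guide
abundance follows `a(t) ∝ a(0) · 2^(φ·t)`, and each sample's counts are a
single multinomial draw at the configured total depth, so replicates
differ only by independent sequencing sampling. Defaults (all in
`sim_config()`):

* **Design:** 1000 genes × 3 guides, timepoints 0–18 days every 3 days,
  3 replicates, 500 expected reads/guide. These mirror a targeted
  dropout-screen design with ~1000× library representation.
* **Essential genes:** 10% of genes at −0.25 log2/day (−4.5 log2 units
  over 18 days), the canonical dropout signal used for QC.
* **Interactions:** 50 positive and 50 negative GI genes at ±1.5 log2
  units of differential fitness at the 18-day endpoint.
* **Background heterogeneity:** per-gene fitness spread of 0.05 log2/day
  shared across contexts (knockouts are not fitness-neutral in general),
  and a per-gene context-specific jitter of 0.0083 log2/day (0.15 log2
  units at day 18) — real knockout effects are never perfectly identical
  across genotype backgrounds, and a simulator without this background
  interaction variation would make null genes an unrealistically uniform
  block.
* **Guide behaviour:** per-guide efficiency deviation of 0.02 log2/day,
  shared across contexts (a guide's cutting efficiency is a property of
  the guide, so it cancels from the differential); lognormal starting
  abundances with sdlog 0.5.
* **Optional bias:** `ma_bias_slope` multiplies mutant-context abundances
  by `2^(slope · Â)` with `Â` the guide's expected mean LFC at that
  timepoint, creating exactly the abundance-dependent artifact the
  MA/loess step exists to remove; the test suite demonstrates that the
  artifact inflates null-gene GI scores without loess and is removed with
  it.

Multiplicity of infection and library representation are recorded in the
config for provenance but do not enter the count model: infection
bottlenecking is upstream of what the analysis assumes, and abundance
dynamics compose multiplicatively regardless of the 3-day passaging
rhythm, so fitness is parameterized per day.

What the simulator does **not** emulate: PCR jackpotting and
amplification overdispersion beyond multinomial sampling, copy-number
effects at cut sites, guide-specific off-target toxicity, and bottleneck
drift between passages. Passing tests therefore show that the pipeline
recovers truth under clean sequencing-sampling noise at realistic depth —
not that it is robust to every artifact of real screens.

## Numerical choices and edge cases

* Samples with all-zero counts are an error (a failed sample should be
  dropped explicitly, not normalized).
* A guide failing the abundance filter in any single T0 sample is
  excluded everywhere; the filter is monotone in its thresholds.
* Degenerate variance structure: all per-gene variances zero is an error;
  all equal (nonzero) yields an infinite prior df and finite statistics.
* Zero-variance LFC vectors yield `NA` correlations with a warning rather
  than an error, so one flat replicate does not abort a QC report.
* `σ = 0` across all GI scores makes gene-set z-scores undefined and is
  an error.
* Result tables are written with 9 significant digits in scientific
  notation; two writes of the same table are byte-identical.

## Validation

The test suite validates each stage against independent oracles:
brute-force step-up evaluation for BH, pair counting for AUC, the
closed-form classical t at `d0 = 0` and `limma`'s empirical-Bayes fit as
an external cross-check for the moderated test, a from-first-principles
weighted regression for the loess smoother, and hand-computed gene-set
z-score examples. End-to-end, on the default simulation: essential-gene
dropout AUC clears 0.85, replicate correlations clear 0.9, the mean
empirical false-discovery proportion among called interactors over 20
simulated screens stays under the 0.2 call threshold, and the Spearman
correlation between true endpoint GI and estimated gene GI reaches ~0.9 —
the binding noise floor there is sequencing-depth sampling error relative
to the background interaction spread, so recovery is reported at the
default depth of 500 reads/guide. Problem sizes in the suite (60–1000
genes, 20 simulation replicates for the FDR check) were chosen so the
whole suite exercises the full screen-scale design while remaining quick
to run.

## Limitations

* The moderated test treats guides as exchangeable replicates of their
  gene; replicate-level correlation structure within a guide is averaged
  away first.
* Exact-match FASTQ counting is a deterministic fixture for amplicon
  reads, not an aligner; mismatch-tolerant counting is out of scope.
* The gene-set z-score treats genes as independent; overlapping terms and
  co-functional correlation are not corrected beyond BH.
* No copy-number correction or guide-efficiency weighting is applied.
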