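---
title: "Methods: super-enhancer domain analysis with sedomain"
author: "sedomain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer domain analysis with sedomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sedomain` implements an integrative analysis of the active-chromatin
landscape in tumor/normal cohorts profiled with H3K27ac ChIP-seq and
RNA-seq. The pipeline identifies regulatory elements and super-enhancers
per sample, pools them into a shared domain geometry, asks which
transcription factors preferentially bind tumor- versus normal-specific
domains, and integrates mRNA and enhancer-RNA (eRNA) expression to
characterise the genes those domains regulate — including their response to
the BET bromodomain inhibitor JQ1, which displaces BRD4 from acetylated
chromatin and is expected to collapse super-enhancer-driven transcription.
Every stage is exercised end to end on a synthetic cohort with planted
effects, so each statistical claim the package makes is validated against a
known truth.

## Elements, super-enhancers and domains

The inputs are per-sample peak calls with a normalized H3K27ac density
(already corrected for copy number and GC bias upstream). A peak is
classified as a **promoter** when its interval intersects the closed window
of `promoter_window` bp (default 2500) on either side of any annotated TSS,
and as an **enhancer** otherwise. The window test uses interval
intersection — the most inclusive reading of "located within a window" —
and a peak touching several gene windows is still a single promoter.

Each enhancer receives a super-enhancer score: the sum over its constituent
peaks of signal times covered bases. An optional stitching distance
(default 0) merges nearby enhancer peaks before scoring; the default leaves
each peak as its own element because the upstream element caller used by
this kind of study already emits consolidated peaks. Scores are then
thresholded with the ROSE geometric criterion, per sample: sort scores
ascending, rescale ranks and scores to the unit square, and take the argmax
of `x − y`, which is the point where the convex rank-score curve attains
slope 1. Ties in the argmax resolve to the largest index (fewest
super-enhancers), so a constant or exactly linear score vector yields no
super-enhancers at all; elements strictly above the cutoff score are
super-enhancers. This closed form is oracle-checkable — the test suite
compares it against brute-force search over every index — and is equivalent
to the classic tangent construction for convex curves.

Domains are the cross-sample union of overlapping elements of one category
(promoter, enhancer, super-enhancer pooled separately, gap 0): every base
covered in at least one sample belongs to exactly one domain, giving all
samples a common coordinate geometry. A domain supported only by tumor
samples is tumor-specific (T), only by normal samples normal-specific (N),
and otherwise common (C). The domain center is the floor of the interval
midpoint in 0-based coordinates.

## Shade-controlled TF binding-site enrichment

To ask whether a TF's binding sites concentrate in a domain set, each
domain of length L contributes two control regions ("shades") of the same
length at a fixed edge-to-edge distance D, one upstream and one downstream.
Shades that would cross a chromosome boundary are dropped whole (clipping
would break the length matching); overlapping shades within a control set
are merged. Shades are deliberately local controls: they inherit the
large-scale genomic context of their domain (gene density, GC regime),
which a genome-wide background would not.

The TF catalog (one region list per TF, the "cistrome") is first merged at
a configurable gap and then restricted to regions of 50–10000 bp. For each
TF and each D the pipeline counts regions with at least one base of overlap
— region-level, not hit-level — into a 2×2 table and applies the exact
test. The two-sided p-value is the exact hypergeometric tail (all tables
with probability not exceeding the observed one); the odds ratio is the
sample cross-product estimate, with the Haldane–Anscombe +0.5 applied to
every cell when any cell is zero — to the OR only, never to the p-value, so
the p stays exact while log-OR contrasts stay finite.

Two distances are tested (10 kb and 100 kb by default) and the **worst
case** is selected componentwise: the smaller odds ratio and the larger
p-value, possibly from different distances. This is the conservative
reading of selecting "a lower odds ratio and a less significant p-value",
and it makes the procedure deliberately deflationary: under a null catalog
the selected p-values are stochastically larger than uniform, which the
type-I-error harness confirms. P-values are Bonferroni-corrected across
TFs; a TF is enriched when the adjusted p is at most 0.05. The
tumor-normal contrast is `delta = ln(OR_T) − ln(OR_N)`; positive delta
means tumor-leaning. Shades are not purged of overlaps with other test
domains — no such exclusion rule is defined for this design — and the
"tumor-leaning" gate used for reporting is significance in the tumor-domain
test together with a positive delta.

## Differential expression

The DE stage is intentionally minimal and pluggable. Counts are normalized
with the standard median-of-ratios estimator; per feature the log2 fold
change is the difference of group means of `log2(normalized + 1)` and the
p-value a two-sided Welch t-test on those values, BH-adjusted across tested
features. Features with all-zero counts are excluded. This engine is a
documented substitute for a full negative-binomial GLM: every downstream
stage consumes only `log2fc` and `p_adj`, and an ingest mode
(`read_de_table()`) accepts externally produced DE tables bit-exactly, so
tables from a dedicated DE package can be dropped in whenever available.
Significance gates are strict: genes need `|log2FC| > 1`, eRNAs
`|log2FC| > 1.5`, both with FDR < 0.05; the set intersections below use the
p-only gate (threshold 0), mirroring how the integrated analysis defines
its inputs.

## Distance-resolved SED regulation

Genes with `p_adj < 0.05` in the tumor-vs-normal DE are assigned to the
nearest SED center (unsigned TSS-to-center distance, ties to the smaller
coordinate) and retained when closer than 2 Mb. Distances are binned at
100 kb up to 2 Mb; within each bin the log2 fold changes of
T-SED-adjacent and N-SED-adjacent genes are compared with the two-sided
Wilcoxon rank-sum test (exact for small tie-free samples, otherwise the
tie- and continuity-corrected normal approximation), BH-adjusted across
bins. Bins where either group has fewer than two genes are untestable and
excluded from the BH family, so the family size reflects tested bins only.
Genes whose nearest SED is common (C) stay in the assignment table but are
excluded from the two-sample contrast, since the contrast is T versus N; an
optional signed mode (upstream negative) exists but is off by default.

## eRNA integration

eRNA abundance is supplied as a counts matrix over SED intervals — the
read-level quantification that produces it is an external concern — and
tested with the same DE engine under the eRNA thresholds. For annotation
each SED is labelled with the gene whose TSS is closest to its center. For
gene-level integration, a gene receives every eRNA whose interval expanded
by ±1.5 Mb contains the gene's TSS (the TSS-to-interval reading of
"overlapped within ±1.5 Mb"; the window is configurable), averaging the
log2 fold changes of multiple contributors. Concordance between gene-level
eRNA and mRNA fold changes is Kendall's tau-b — the tie-corrected variant,
chosen because a defined tie policy is needed even if real fold-change
vectors rarely tie — with an exact p for small tie-free samples and the
normal approximation otherwise.

## Core gene set and overlap statistics

The core set intersects (1) genes significantly upregulated in tumors
(p-only gate), (2) genes whose nearest SED center is tumor-specific and
within 2 Mb — the same window the distance analysis establishes as the
search range, surfaced in every report — and (3) genes downregulated after
JQ1 in both cell lines. Overlap strength is quantified with
background-relative Fisher tests: presence/absence tables against the
universe of tested genes, the sample odds ratio, and a Wald 95% CI on the
log odds ratio with Haldane correction for zero cells (the CI method is a
standard choice; nothing in the analysis depends on the CI flavor).
The BH family for these tests is the set of contrasts in one run (three by
default).

## Preranked gene-set enrichment

Rankings are log2 fold changes. The enrichment score is the classic
running-sum maximum deviation with hit increments proportional to
`|statistic|^weight` (weight 1 by default, the established preranked
convention; weight 0 is retained because it is analytically checkable) and
uniform miss decrements. Ranking ties break by gene id for determinism. The
null is gene-label permutation at fixed set size; the p-value is the
fraction of same-sign null ES at least as extreme (reported as 0 when the
observed score exceeds every same-sign permutation — the literal empirical
fraction, with a `1/(n_perm+1)` fallback when no same-sign null exists);
NES divides ES by the mean |null ES| of the same sign, and the FDR is the
standard NES-ratio estimate over the pooled normalized null. Gene-set
collections are user-supplied GMT files; the package ships only a tiny
fictional collection as a fixture. Hypergeometric over-representation
(upper tail, BH across terms) covers the GO-style analysis of discrete
gene sets.

## The synthetic cohort

The generator (`simulate_cohort()`) emulates the statistical structure of
the study design rather than its sequences. Its defaults are the packaged
study conditions:

* **Genome and domains.** 8 chromosomes × 220 Mb; 340 planted SEDs (150
  tumor-specific, 150 normal-specific, 40 common) centred on a 5 Mb block
  grid, 25–45 kb wide. This is a ~6× scale-down of the thousands of SEDs a
  real cohort yields, keeping every harness inside desk-scale runtimes
  while preserving the per-domain statistics.
* **Peaks.** 2 tumor + 2 normal ChIP samples. Per sample: promoter peaks
  at 70% of TSSs, ~3000 background enhancers with log-normal signal (the
  heavy-tailed score background), and wide high-signal peaks at the planted
  SEDs of the matching condition, jittered per sample. Planted scores sit
  far above the background tail, so the rank-score curve is convex with a
  distinct super-enhancer tail.
* **Expression.** Negative-binomial counts (dispersion 0.1 for the 12 vs 12
  cohort, 0.02 for the cleaner 5 + 5 cell-line replicates), gene base means
  log-normal around 100, library sizes varying ±30% to exercise
  normalization. Every gene's tumor/normal log2 fold change follows its
  distance d to the nearest planted SED center:
  `lfc = ±effect_lfc · max(0, 1 − d / decay_range)` (+ near T, − near N,
  0 near C), with `effect_lfc = 2` and a 1 Mb decay range. The linear-to-
  zero shape is the simplest decay consistent with a regulatory reach that
  empirically ends between 0.8 and 1.3 Mb; it is configurable.
* **JQ1 arm.** 50 designated core genes sit close (30–200 kb) to distinct
  T-SEDs, are strongly expressed (base means ~4× the genome median, as
  befits SE-driven oncogenes), and are reversed under treatment by
  `−jq1_reversal_fraction × lfc` (default 0.8) in both cell lines.
  Restricting the reversal to a designated subset reflects the biology the
  pipeline is meant to detect — SE-dependent genes are the BET-sensitive
  ones — and gives the recovery harness a well-defined truth set. A further
  ~300 genes outside the decay footprint carry an SE-independent treatment
  response (shared across lines, N(0, 1.5) log2FC), emulating the broad
  transcriptional footprint of BET inhibition.
* **TF catalog.** 40 TFs × 24000 short regions (log-uniform 50–2000 bp,
  uniform placement); 5 TFs receive extra regions inside T-SED intervals
  so their per-bp region density there is 3× background.
* **eRNA layer.** One eRNA per planted SED with true log2FC
  `ρ·s + sqrt(1−ρ²)·ε`, where s is ±`effect_lfc` by specificity, ε is
  Gaussian noise of matching scale, and ρ = `erna_coupling` (default 0.8).
  Because ρ only reweights fixed draws, concordance rises strictly with ρ
  at a fixed seed.

The packaged fixture seed is 17. What the generator does **not** emulate:
read-level noise, copy-number or GC artifacts, correlated gene neighbours,
overlapping SEDs, strand effects, or a realistic gene-density landscape.
Passing the harnesses therefore demonstrates that the statistical machinery
recovers planted structure under the stated noise model — not that any
biological conclusion transfers to a particular real cohort.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on disk (BED convention) and 1-based
  closed in memory (`GRanges`); the GTF reader is the only place 1-based
  arithmetic happens on input (TSS = start on +, end on −).
* Nearest-feature ties always break to the smaller coordinate;
  `rose_cutoff` argmax ties break to the larger index; GSEA ranking ties
  break by gene id. All three make reruns byte-identical.
* The exact 2×2 p sums hypergeometric probabilities `≤ p_obs·(1+1e−9)`;
  the relative tolerance absorbs floating-point noise in the pmf, and the
  enumeration oracle in the tests uses the same guard with independent
  `choose()` arithmetic.
* `merge_intervals` treats "neighbouring" as an end-to-start gap of at most
  the merge distance; book-ended intervals merge at distance 0.
* Degenerate DE features (identical values in both groups) report p = 1
  when the means agree and p = 0 otherwise rather than NaN.
* Empty domain or shade sets, empty TF catalogs, and untestable bins raise
  errors or propagate NA as documented instead of silently vanishing —
  except inside `enrich_tfs()`, where a failing TF is skipped with a
  warning so one degenerate catalog entry cannot abort a 200-TF scan.

## Problem sizes

The shipped analyses and tests run the full default cohort (340 SEDs, 2000
genes, 40 TFs × 24000 regions, 12 vs 12 + 2×(5+5) samples) for single-seed
analyses, 50 seeds for the TF- and distance-recovery harnesses, 100 seeds
for the null distance harness, and 1000 permutations for enrichment
p-values. These sizes were chosen so the complete validation suite
exercises every claim at meaningful power on a single CPU.

## Known limitations

* The Welch-on-log-counts DE engine is less powerful than a dispersion-
  shrinking NB model at small n; use the ingest mode for production DE.
* Shade controls assume the flanks are representative background; in real
  genomes, domains abutting assembly gaps or clustered regulatory regions
  can bias the control set, and the diagnostic counts should be inspected.
* The NES-ratio FDR is the standard preranked estimate and shares its known
  conservatism for small set collections.
* The core-set definition depends on the "near T-SED" window; 2 Mb is the
  search window the distance analysis justifies, but all downstream counts
  move with it, which is why every report surfaces the window used.
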