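# sedomain

Super-enhancer domain analysis for tumor/normal H3K27ac cohorts.

## The problem

In cancers with few genetic mutations but pervasive epigenetic
dysregulation, much of the oncogenic transcriptional program is driven by
**super-enhancers (SEs)** — clusters of H3K27ac-marked enhancers whose
summed signal stands far above the typical-enhancer background. `sedomain`
is for computational biologists who have per-sample H3K27ac peak calls
(with normalized signal), a gene annotation, a TF binding-site catalog, and
mRNA/eRNA count matrices, and who want to answer, with explicit statistics:

* Which regulatory elements are super-enhancers, and which **domains**
  (cross-sample unions of elements) are tumor-specific (T), normal-specific
  (N), or common (C)?
* Which transcription factors' binding sites are enriched in T- versus
  N-specific domains, controlling for local genomic context?
* How far does super-enhancer-domain (SED) regulation reach along the
  chromosome, and which genes respond?
* Do enhancer RNAs (eRNAs) over SEDs move coordinately with nearby mRNAs?
* Which genes form the core SE-driven program that a BET bromodomain
  inhibitor (JQ1) switches off?

## The statistics at the core

* **ROSE tangent cutoff.** Enhancer scores `s_(1) ≤ … ≤ s_(n)` (sum of
  signal × covered bases per element) are rescaled with their ranks to the
  unit square; the SE cutoff is `argmax_i (x_i − y_i)`, the slope-1 tangent
  point of the convex rank-score curve. Ties resolve to the fewest SEs.
* **Shade-controlled Fisher enrichment.** Each domain of length L gets two
  length-L control regions ("shades") at edge-to-edge distance D up- and
  downstream. Per TF, region-level overlap counts form a 2×2 table; the
  p-value is the exact two-sided hypergeometric tail and the odds ratio the
  sample estimate (Haldane +0.5 when a cell is zero, applied to the OR
  only). Two distances (10 kb, 100 kb) are tested and the worst case (min
  OR, max p, componentwise) is kept; Bonferroni across TFs; the
  tumor–normal contrast is `Δ = ln OR_T − ln OR_N`.
* **Distance-resolved regulation.** DE genes (FDR < 0.05) are assigned to
  the nearest SED center and binned at 100 kb up to 2 Mb; per bin, T- vs
  N-adjacent log2 fold changes are compared with the two-sided Wilcoxon
  rank-sum test, BH-adjusted across testable bins.
* **eRNA–mRNA concordance.** Gene-level eRNA log2FC (mean over eRNAs whose
  ±1.5 Mb-expanded interval contains the TSS) versus mRNA log2FC, by
  Kendall's tau-b.
* **Core set.** `up_tumor ∩ near_T-SED ∩ down_JQ1(line1) ∩ down_JQ1(line2)`,
  with background-relative Fisher overlap tests (OR, Wald 95% CI, BH).
* **Preranked GSEA.** Running-sum ES with |log2FC|-weighted hits,
  gene-label permutation null, sign-matched NES, NES-ratio FDR.

A synthetic-cohort generator (`simulate_cohort()`) plants every one of
these effects — SE score tails, T/N/C domains, 3× TF binding density in
T-SEDs, a linear 1 Mb distance decay of expression effects, eRNA–mRNA
coupling, and a 50-gene JQ1-reversible core program — so the whole pipeline
is validated against known truth. See the methods vignette
(`vignettes/sedomain-methods.Rmd`) for model details and assumptions.

## Worked example

The numbered scripts under `analysis/` run the full study on the packaged
seed-17 cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_elements_domains.R
Rscript analysis/03_tf_enrichment.R
# ... through analysis/08_pathways.R
```

`02_elements_domains.R` pools the four samples' elements into
`PD 2010, ED 11705, SED 375` domains; the 375 SEDs split `171 T / 164 N /
40 C`, and every one of the 340 planted SEDs is recovered with the correct
specificity (the extras are sample-specific background enhancers that clear
the ROSE cutoff). `03_tf_enrichment.R` then reports, for the five TFs
planted at 3× binding density in T-SEDs:

```
     tf or_T  or_N p_bonferroni_T delta
1 TF001 2.87 0.987       1.59e-06  1.07
2 TF002 4.39 1.053       1.12e-12  1.43
3 TF003 3.13 0.961       1.60e-07  1.18
4 TF004 2.95 1.027       7.40e-07  1.06
5 TF005 2.53 0.743       5.71e-05  1.23
```

i.e. all five are Bonferroni-significant against their shades in T-SEDs
(`or_T`), flat in N-SEDs (`or_N`), and tumor-leaning (`delta > 0`); none of
the 35 null TFs is called. `05_sed_distance.R` shows the planted 1 Mb
regulatory reach: bins out to 0.8–0.9 Mb are significant (e.g. bin 0–100 kb:
median log2FC +1.82 for T-adjacent vs −1.85 for N-adjacent genes,
`p_adj = 5.3e-10`), and every bin beyond 0.9 Mb is quiet.
`06_erna.R` reports the eRNA–mRNA concordance

```
Kendall tau (eRNA vs mRNA log2FC) = 0.3833 (p = 4.53e-105, n = 1441)
```

and `07_core_set.R` recovers the planted program:

```
Core set: 49 genes; precision 1 recall 0.98 against the 50 planted genes
  contrast  a odds_ratio ci_low ci_high    p_adj
1    line1 49       2.74   1.90    3.95 2.50e-07
2    line2 49       2.74   1.90    3.95 2.50e-07
3     core 49       2.97   2.05    4.29 1.53e-07
```

— the tumor-upregulated, T-SED-proximal genes overlap the JQ1-downregulated
genes of each cell line far beyond chance. Finally `08_pathways.R` runs the
preranked enrichment: the planted SE-driven program scores `NES = 2.78
(p = 0, FDR = 0)` on the tumor-vs-normal ranking and flips to `NES ≈ −2.4`
on both JQ1 rankings, the signature of an SE-driven, BET-sensitive program.

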