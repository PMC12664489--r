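#!/usr/bin/env Rscript
# Differential expression: tumor vs normal for the RNA cohort and JQ1 vs
# DMSO for both cell lines (median-of-ratios normalization, Welch test on
# log2 counts, BH adjustment).

source("analysis/_common.R")

de <- get_de()
cfg <- de_config()
up <- significant_set(de$mrna, "up", cfg$lfc_threshold_gene, cfg$fdr)
dn <- significant_set(de$mrna, "down", cfg$lfc_threshold_gene, cfg$fdr)
cat("Cohort DE: ", length(up), "genes up,", length(dn),
    "down at |log2FC| > 1, FDR < 0.05\n")
for (ln in names(de$jq1)) {
  d <- significant_set(de$jq1[[ln]], "down", 0, cfg$fdr)
  cat("  ", ln, ":", length(d), "genes down after treatment (p-only gate)\n")
}
save_table(de$mrna, "de_mrna_tumor_vs_normal.tsv")
for (ln in names(de$jq1))
  save_table(de$jq1[[ln]], paste0("de_jq1_", ln, ".tsv"))
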