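#!/usr/bin/env Rscript
# The core SE-driven, treatment-sensitive gene set: intersect
# tumor-upregulated, T-SED-proximal, and JQ1-downregulated (both lines)
# genes, then quantify the overlaps with background-relative Fisher tests.

source("analysis/_common.R")

co <- get_cohort()
de <- get_de()
seds <- get_domains()$SED
up <- significant_set(de$mrna, "up", 0, 0.05)
near <- near_tsed_genes(co$genes, seds)
downs <- lapply(de$jq1, significant_set, direction = "down",
                lfc_threshold = 0, fdr = 0.05)
core <- intersect_core(up, near, downs[[1]], downs[[2]])
truth <- co$truth$genes$gene_id[co$truth$genes$jq1_reversed]
cat("Core set:", length(core$core_genes), "genes;",
    "precision", round(mean(core$core_genes %in% truth), 3),
    "recall", round(mean(truth %in% core$core_genes), 3),
    "against the", length(truth), "planted genes\n")

bg <- de$mrna$feature_id
up_near <- intersect(up, near)
ov <- core_overlap_table(list(
  line1 = list(set_a = up_near, set_b = downs[[1]]),
  line2 = list(set_a = up_near, set_b = downs[[2]]),
  core = list(set_a = up_near,
              set_b = intersect(downs[[1]], downs[[2]]))), bg)
print(ov[, c("contrast", "a", "odds_ratio", "ci_low", "ci_high", "p_adj")],
      digits = 3)
save_table(data.frame(gene_id = core$core_genes), "core_genes.tsv")
save_table(ov, "core_overlap_fisher.tsv")
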