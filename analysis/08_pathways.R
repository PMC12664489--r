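#!/usr/bin/env Rscript
# Preranked gene-set enrichment on the tumor-vs-normal log2FC ranking: the
# planted SE-driven program (as a stand-in for a curated collection)
# against size-matched random sets, on both the cohort and the treatment
# contrasts.

source("analysis/_common.R")

co <- get_cohort()
de <- get_de()
planted <- co$truth$genes$gene_id[co$truth$genes$jq1_reversed]
set.seed(STUDY_SEED + 1)
sets <- c(list(planted_tsed_program = planted),
          setNames(lapply(1:9, function(i)
            sample(de$mrna$feature_id, length(planted))),
            sprintf("random_%02d", 1:9)))

for (contrast in c("tumor_vs_normal", names(de$jq1))) {
  tab <- if (contrast == "tumor_vs_normal") de$mrna else de$jq1[[contrast]]
  ranking <- setNames(tab$log2fc, tab$feature_id)
  res <- preranked_gsea(ranking, sets, n_perm = 1000,
                        seed = STUDY_SEED + 2)
  row <- res[res$set_name == "planted_tsed_program", ]
  cat(sprintf("%-16s planted program: ES %.3f, NES %.2f, p %.4g, FDR %.3g\n",
              contrast, row$es, row$nes, row$p_value, row$fdr))
  save_table(res[, setdiff(names(res), "leading_edge")],
             paste0("gsea_", contrast, ".tsv"))
}
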