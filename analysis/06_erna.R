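#!/usr/bin/env Rscript
# eRNA layer: differential expression of eRNA counts over the SED
# intervals, closest-gene annotation, +/-1.5 Mb assignment of eRNA fold
# changes to genes, and the Kendall concordance with mRNA fold changes.

source("analysis/_common.R")

co <- get_cohort()
iv <- sed_intervals(co)
de_m <- get_de()$mrna
de_e <- erna_de(co$counts$erna, co$counts$erna_labels, seds = iv)
cfg <- de_config()
sig_e <- significant_set(de_e, "both", cfg$lfc_threshold_erna, cfg$fdr)
cat("eRNAs tested:", nrow(de_e), "; significant at |log2FC| > 1.5:",
    length(sig_e), "\n")

closest <- annotate_closest_gene(iv, co$genes)
de_e$closest_gene <- unname(closest[de_e$feature_id])
ge <- erna_to_genes(de_e, iv, co$genes)
conc <- erna_mrna_concordance(ge, de_m)
cat(sprintf("Kendall tau (eRNA vs mRNA log2FC) = %.4f (p = %.3g, n = %d)\n",
            conc$tau, conc$p_value, conc$n))
save_table(de_e, "de_erna.tsv")
save_table(ge, "gene_erna_fold_changes.tsv")
save_table(data.frame(tau = conc$tau, p = conc$p_value, n = conc$n),
           "erna_mrna_concordance.tsv")
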