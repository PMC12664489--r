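#!/usr/bin/env Rscript
# Shade-controlled TF binding-site enrichment in tumor- vs normal-specific
# SEDs: length-matched flanking controls at D = 10 kb and 100 kb, Fisher
# tests with worst-case selection over D, Bonferroni correction, and the
# delta of log odds ratios.

source("analysis/_common.R")

co <- get_cohort()
dom <- get_domains()$SED
cis <- prepare_cistrome(co$cistrome, 10000)
ct <- tf_domain_contrast(dom, cis, co$genome)
ct <- merge(ct, co$truth$tfs, by = "tf")

cat("TFs tested:", nrow(ct), "\n")
lean <- ct$significant_T & ct$delta > 0
cat("Tumor-leaning and Bonferroni-significant:", sum(lean),
    "of which planted:", sum(lean & ct$enriched), "/", sum(ct$enriched), "\n")
print(ct[ct$enriched, c("tf", "or_T", "or_N", "p_bonferroni_T", "delta")],
      digits = 3)
save_table(ct, "tf_enrichment_SED.tsv")
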