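#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a tumor/normal H3K27ac peak atlas
# with planted super-enhancer domains, a TF binding catalog with five TFs
# enriched inside tumor-specific SEDs, and NB count matrices for the RNA
# cohort, the eRNA layer, and two JQ1-treated cell lines.

source("analysis/_common.R")

co <- get_cohort()
cat("Cohort at seed", STUDY_SEED, "\n")
cat("  genome:", length(co$genome), "chromosomes x",
    format(co$genome[1], big.mark = ","), "bp\n")
cat("  planted SEDs:", nrow(co$truth$sed), "(",
    sum(co$truth$sed$specificity == "T"), "T /",
    sum(co$truth$sed$specificity == "N"), "N /",
    sum(co$truth$sed$specificity == "C"), "C )\n")
cat("  peaks per sample:", paste(sapply(co$peaks, length), collapse = ", "), "\n")
cat("  genes:", nrow(co$genes), "; designated JQ1-reversed core genes:",
    sum(co$truth$genes$jq1_reversed), "\n")

write_cohort(co, file.path(RESULTS, "cohort"))
cat("  cohort inputs written under", file.path(RESULTS, "cohort"), "\n")
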