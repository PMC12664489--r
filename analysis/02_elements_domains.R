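#!/usr/bin/env Rscript
# Classify peaks into promoters/enhancers, call super-enhancers with the
# per-sample ROSE tangent cutoff, and pool elements across samples into
# PD/ED/SED domains with tumor/normal/common specificity.

source("analysis/_common.R")

els <- get_elements()
for (sid in names(els))
  cat(sprintf("  %s: %s\n", sid,
              paste(capture.output(print(table(mcols(els[[sid]])$element_class))),
                    collapse = " ")))

dom <- get_domains()
cat("Domains:", paste(names(dom), sapply(dom, length), collapse = ", "), "\n")
cat("SED specificity:\n")
print(table(mcols(dom$SED)$specificity))

for (cat_ in names(dom)) {
  d <- dom[[cat_]]
  save_table(data.frame(chrom = as.character(seqnames(d)),
                        start = start(d) - 1, end = end(d),
                        domain_id = mcols(d)$domain_id,
                        specificity = mcols(d)$specificity,
                        center = mcols(d)$center,
                        supporters = mcols(d)$supporting_samples),
             paste0("domains_", cat_, ".tsv"))
}
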