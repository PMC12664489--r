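# Shared plumbing for the numbered analysis scripts: loads the package,
# fixes the study seed, and memoises the expensive stages under
# results/cache so each script can be run on its own or in sequence.

suppressPackageStartupMessages({
  library(sedomain)
  library(GenomicRanges)
})

STUDY_SEED <- 17
RESULTS <- "results"
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

memo <- function(name, expr) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- force(expr)
  saveRDS(value, path)
  value
}

get_cohort <- function() memo("cohort", simulate_cohort(sim_config(STUDY_SEED)))

get_elements <- function() memo("elements", {
  co <- get_cohort()
  lapply(co$peaks, call_regulatory_elements, genes = co$genes)
})

get_domains <- function() memo("domains", {
  build_domains(get_elements(), get_cohort()$conditions)
})

get_de <- function() memo("de", {
  co <- get_cohort()
  list(mrna = de_test(co$counts$mrna, co$counts$mrna_labels,
                      "tumor", "normal"),
       jq1 = lapply(co$counts$jq1, function(x)
         de_test(x$counts, x$labels, "JQ1", "DMSO")))
})

sed_intervals <- function(cohort) {
  sed <- cohort$truth$sed
  iv <- GRanges(sed$chrom, IRanges(sed$start + 1, sed$end))
  mcols(iv)$domain_id <- sed$sed_id
  mcols(iv)$specificity <- sed$specificity
  mcols(iv)$center <- round(sed$center)
  iv
}

save_table <- function(df, name) {
  path <- file.path(RESULTS, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  wrote", path, "\n")
}
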