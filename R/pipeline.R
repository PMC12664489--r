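# End-to-end orchestration of the analysis on a synthetic cohort:
# simulate -> call elements -> build domains -> TF enrichment -> DE ->
# distance bins -> eRNA integration -> core set -> pathway enrichment,
# with a manifest hashing every written artifact.

#' Significance stars for adjusted p-values
#' @param p_adj Numeric vector.
#' @return Character vector: `***` below 0.001, `**` below 0.01, `*` below
#'   0.05, empty otherwise.
#' @export
significance_stars <- function(p_adj) {
  ifelse(is.na(p_adj), "",
         ifelse(p_adj < 0.001, "***",
                ifelse(p_adj < 0.01, "**",
                       ifelse(p_adj < 0.05, "*", ""))))
}

#' Join TF enrichment with expression fold changes across contrasts
#'
#' Restricts to tumor-leaning TFs (positive delta and significant in the
#' tumor-domain test), resolves TF names to gene ids through an alias map,
#' and assembles a matrix of log2 fold changes across the supplied DE
#' tables with significance stars. Unresolvable TFs are dropped with a
#' warning.
#'
#' @param enrichment Output of [tf_domain_contrast()].
#' @param de_tables Named list of DE tables (e.g. tumor_vs_normal and one
#'   per cell line).
#' @param alias Named character vector mapping TF name to gene id.
#' @return data.frame with one row per tumor-leaning TF: `tf`, `gene_id`,
#'   then `log2fc_<contrast>` and `stars_<contrast>` per DE table.
#' @export
tf_expression_join <- function(enrichment, de_tables, alias) {
  lean <- enrichment[enrichment$delta > 0 & enrichment$significant_T, ,
                     drop = FALSE]
  out <- data.frame(tf = lean$tf,
                    gene_id = unname(alias[lean$tf]),
                    stringsAsFactors = FALSE)
  drop <- is.na(out$gene_id)
  if (any(drop))
    warning("dropping TFs with no gene alias: ",
            paste(out$tf[drop], collapse = ", "), call. = FALSE)
  out <- out[!drop, , drop = FALSE]
  for (nm in names(de_tables)) {
    de <- de_tables[[nm]]
    idx <- match(out$gene_id, de$feature_id)
    miss <- is.na(idx)
    if (any(miss))
      warning("TF gene(s) absent from DE table ", nm, ": ",
              paste(out$gene_id[miss], collapse = ", "), call. = FALSE)
    out[[paste0("log2fc_", nm)]] <- de$log2fc[idx]
    out[[paste0("stars_", nm)]] <- significance_stars(de$p_adj[idx])
  }
  out[!is.na(out$gene_id), , drop = FALSE]
}

#' Run the full analysis on a synthetic cohort
#'
#' Executes every stage in dependency order on a cohort generated from
#' `config`, writes each stage's tables under `outdir`, and returns the
#' in-memory results together with a manifest of output files and their
#' md5 hashes. Rerunning with the same configuration reproduces identical
#' hashes.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param cistrome_merge_distance Merge gap for cistrome preparation (bp).
#' @param shade_distances Shade distances D in bp.
#' @param de_cfg A [de_config()].
#' @param n_perm Permutations for the pathway stage.
#' @return List with the stage results (`cohort`, `elements`, `domains`,
#'   `tf`, `de`, `distance`, `erna`, `core`, `gsea`, `tf_expression`) and
#'   `manifest` (data.frame stage/file/md5).
#' @export
run_all <- function(config = sim_config(), outdir = tempfile("sedomain_run_"),
                    cistrome_merge_distance = 10000,
                    shade_distances = c(10000, 100000),
                    de_cfg = de_config(), n_perm = 500) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  register <- function(stage, files) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE))
  }
  wtab <- function(df, stage, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    register(stage, p)
    p
  }

  ## 1 simulate
  cohort <- simulate_cohort(config)
  input_dir <- file.path(outdir, "input")
  register("simulate", write_cohort(cohort, input_dir))

  ## 2 call elements per sample
  elements <- lapply(cohort$peaks, call_regulatory_elements,
                     genes = cohort$genes)
  for (sid in names(elements)) {
    el <- elements[[sid]]
    mcols(el)$name <- paste0(mcols(el)$element_class, "_", seq_along(el))
    mcols(el)$score <- ifelse(is.na(mcols(el)$se_score), 0,
                              mcols(el)$se_score)
    p <- file.path(outdir, paste0("elements_", sid, ".bed"))
    write_bed(el, p)
    register("call-elements", p)
  }

  ## 3 build domains
  domains <- build_domains(elements, cohort$conditions)
  for (cat in names(domains)) {
    dom <- domains[[cat]]
    mcols(dom)$name <- paste0(mcols(dom)$domain_id, "|",
                              mcols(dom)$specificity, "|",
                              mcols(dom)$supporting_samples)
    p <- file.path(outdir, paste0("domains_", cat, ".bed"))
    write_bed(dom, p)
    register("build-domains", p)
  }

  ## 4 TF enrichment on SED (the headline contrast)
  cistrome <- prepare_cistrome(cohort$cistrome, cistrome_merge_distance)
  tf <- tf_domain_contrast(domains$SED, cistrome, cohort$genome,
                           D_values = shade_distances)
  wtab(tf, "tf-enrich", "tf_enrichment_SED.tsv")

  ## 5 differential expression
  de_mrna <- de_test(cohort$counts$mrna, cohort$counts$mrna_labels,
                     "tumor", "normal", de_cfg)
  wtab(de_mrna, "de", "de_mrna_tumor_vs_normal.tsv")
  de_jq1 <- lapply(cohort$counts$jq1, function(x)
    de_test(x$counts, x$labels, "JQ1", "DMSO", de_cfg))
  for (ln in names(de_jq1))
    wtab(de_jq1[[ln]], "de", paste0("de_jq1_", ln, ".tsv"))

  ## 6 distance-resolved SED regulation
  assignments <- assign_genes(cohort$genes, domains$SED, de_mrna,
                              fdr = de_cfg$fdr)
  bins <- bin_and_test(assignments)
  wtab(assignments, "distance", "gene_sed_assignments.tsv")
  wtab(bins, "distance", "distance_bins.tsv")

  ## 7 eRNA integration (counts are keyed by planted SED ids)
  sed_truth <- cohort$truth$sed
  erna_iv <- GRanges(sed_truth$chrom,
                     IRanges(sed_truth$start + 1, sed_truth$end))
  mcols(erna_iv)$domain_id <- sed_truth$sed_id
  mcols(erna_iv)$specificity <- sed_truth$specificity
  mcols(erna_iv)$center <- round(sed_truth$center)
  de_erna <- erna_de(cohort$counts$erna, cohort$counts$erna_labels,
                     seds = erna_iv, cfg = de_cfg)
  closest <- annotate_closest_gene(erna_iv, cohort$genes)
  de_erna$closest_gene <- unname(closest[de_erna$feature_id])
  gene_erna <- erna_to_genes(de_erna, erna_iv, cohort$genes)
  conc <- erna_mrna_concordance(gene_erna, de_mrna)
  wtab(de_erna, "erna", "de_erna.tsv")
  wtab(gene_erna, "erna", "gene_erna_fold_changes.tsv")
  wtab(data.frame(tau = conc$tau, p_value = conc$p_value, n = conc$n),
       "erna", "erna_mrna_concordance.tsv")

  ## 8 core gene set
  up_tumor <- significant_set(de_mrna, "up", lfc_threshold = 0,
                              fdr = de_cfg$fdr)
  near <- near_tsed_genes(cohort$genes, domains$SED)
  downs <- lapply(de_jq1, significant_set, direction = "down",
                  lfc_threshold = 0, fdr = de_cfg$fdr)
  core <- intersect_core(up_tumor, near, downs[[1]], downs[[2]])
  background <- de_mrna$feature_id
  up_near <- intersect(up_tumor, near)
  overlaps <- core_overlap_table(list(
    line1 = list(set_a = up_near, set_b = downs[[1]]),
    line2 = list(set_a = up_near, set_b = downs[[2]]),
    core = list(set_a = up_near,
                set_b = intersect(downs[[1]], downs[[2]]))), background)
  wtab(data.frame(gene_id = core$core_genes), "core-set", "core_genes.tsv")
  wtab(data.frame(set = names(core$venn_counts),
                  n = as.integer(core$venn_counts)),
       "core-set", "venn_counts.tsv")
  wtab(overlaps, "core-set", "core_overlap_fisher.tsv")

  ## 9 pathway enrichment on the tumor-vs-normal ranking; the planted
  ## treatment-sensitive program plays the role of a curated gene set,
  ## alongside size-matched random sets
  ranking <- setNames(de_mrna$log2fc, de_mrna$feature_id)
  planted_set <- cohort$truth$genes$gene_id[cohort$truth$genes$jq1_reversed]
  set.seed(config$seed + 1L)
  rand_sets <- lapply(1:9, function(i)
    sample(names(ranking), length(planted_set)))
  names(rand_sets) <- sprintf("random_%02d", 1:9)
  gene_sets <- c(list(planted_tsed_program = planted_set), rand_sets)
  gsea <- preranked_gsea(ranking, gene_sets, n_perm = n_perm,
                         seed = config$seed + 2L)
  wtab(gsea, "gsea", "gsea_tumor_vs_normal.tsv")

  ## 10 TF expression join (synthetic alias: TF i -> i-th gene)
  alias <- setNames(cohort$genes$gene_id[seq_along(cohort$cistrome)],
                    names(cohort$cistrome))
  tf_expr <- tf_expression_join(tf, c(list(tumor_vs_normal = de_mrna),
                                      de_jq1), alias)
  wtab(tf_expr, "tf-expression", "tf_expression.tsv")

  list(cohort = cohort, elements = elements, domains = domains, tf = tf,
       de = list(mrna = de_mrna, jq1 = de_jq1, erna = de_erna),
       distance = list(assignments = assignments, bins = bins),
       erna = list(gene_erna = gene_erna, concordance = conc),
       core = list(result = core, overlaps = overlaps),
       gsea = gsea, tf_expression = tf_expr,
       manifest = manifest, outdir = outdir)
}
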