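# eRNA integration: differential expression of eRNAs quantified over SED
# intervals, closest-gene annotation, window-based eRNA-to-gene fold-change
# assignment, and Kendall concordance between eRNA and mRNA fold changes.

#' Differential expression of eRNAs over SED intervals
#'
#' Delegates to the shared DE engine with the eRNA significance thresholds
#' (`|log2FC| > 1.5`, FDR < 0.05). Count rows must be keyed by SED domain
#' ids matching the SED set.
#'
#' @param erna_counts SED-by-sample count matrix (rownames = sed ids).
#' @param labels Per-sample condition labels.
#' @param group_a,group_b The contrast (A over B).
#' @param seds Optional SED `GRanges`; when given, row ids are checked
#'   against `domain_id` and orphans raise an error.
#' @param cfg A [de_config()].
#' @return DE table as from [de_test()].
#' @export
erna_de <- function(erna_counts, labels, group_a = "tumor",
                    group_b = "normal", seds = NULL, cfg = de_config()) {
  if (!is.null(seds)) {
    orphans <- setdiff(rownames(erna_counts), mcols(seds)$domain_id)
    if (length(orphans))
      stop("eRNA rows with no matching SED: ",
           paste(utils::head(orphans, 5), collapse = ", "))
  }
  de_test(erna_counts, labels, group_a, group_b, cfg)
}

#' Assign eRNA fold changes to genes within a window
#'
#' A gene receives every eRNA whose interval, expanded by `window` bp on
#' each side, contains the gene's TSS; its eRNA fold change is the
#' arithmetic mean over contributing eRNAs. Genes reached by no eRNA are
#' absent from the result.
#'
#' @param erna_de DE table for eRNAs (feature_id = sed id).
#' @param erna_intervals `GRanges` of the eRNA/SED intervals with
#'   `domain_id` metadata matching the DE table.
#' @param genes Gene table.
#' @param window Expansion in bp (default 1.5 Mb).
#' @return data.frame with `gene_id`, `erna_log2fc_mean`,
#'   `n_contributing_ernas`.
#' @export
erna_to_genes <- function(erna_de, erna_intervals, genes, window = 1.5e6) {
  idx <- match(mcols(erna_intervals)$domain_id, erna_de$feature_id)
  keep <- !is.na(idx)
  ivs <- erna_intervals[keep]
  lfc <- erna_de$log2fc[idx[keep]]
  ext <- GRanges(seqnames(ivs),
                 IRanges(pmax(1, start(ivs) - window), end(ivs) + window))
  tss <- GRanges(genes$chrom, IRanges(genes$tss, width = 1))
  hits <- findOverlaps(tss, ext, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(0), erna_log2fc_mean = numeric(0),
                      n_contributing_ernas = integer(0)))
  m <- tapply(lfc[subjectHits(hits)], queryHits(hits), mean)
  n <- tapply(subjectHits(hits), queryHits(hits), length)
  gi <- as.integer(names(m))
  data.frame(gene_id = genes$gene_id[gi],
             erna_log2fc_mean = as.numeric(m),
             n_contributing_ernas = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Annotate each SED with the gene closest to its center
#'
#' The closest gene minimizes |TSS - SED center|; ties break to the smaller
#' TSS coordinate.
#'
#' @param seds SED `GRanges` with `domain_id` and `center`.
#' @param genes Gene table (nonempty).
#' @return Named character vector, sed id -> gene id.
#' @export
annotate_closest_gene <- function(seds, genes) {
  if (nrow(genes) == 0L) stop("gene set is empty")
  nn <- distance_to_nearest(as.character(seqnames(seds)),
                            mcols(seds)$center,
                            genes$chrom, genes$tss)
  setNames(ifelse(is.na(nn$target_idx), NA_character_,
                  genes$gene_id[nn$target_idx]),
           mcols(seds)$domain_id)
}

#' Gene-level eRNA-mRNA fold-change concordance
#'
#' Computes Kendall's tau-b between the gene-level eRNA fold change (from
#' [erna_to_genes()]) and the mRNA fold change, over genes carrying both.
#'
#' @param gene_erna Output of [erna_to_genes()].
#' @param mrna_de mRNA DE table.
#' @return List with `tau`, `p_value`, `n`.
#' @export
erna_mrna_concordance <- function(gene_erna, mrna_de) {
  idx <- match(gene_erna$gene_id, mrna_de$feature_id)
  ok <- !is.na(idx)
  kendall_tau(gene_erna$erna_log2fc_mean[ok], mrna_de$log2fc[idx[ok]])
}
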