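# Distance-resolved SED regulatory reach: assign each differentially
# expressed gene to its nearest SED center, bin by distance, and compare
# log2 fold changes of T-SED-adjacent vs N-SED-adjacent genes per bin.

#' Assign genes to their nearest SED center
#'
#' Joins the tumor-vs-normal DE table onto the gene table, keeps genes with
#' `p_adj < fdr`, computes the distance from each TSS to the nearest SED
#' center (ties to the smaller coordinate), and keeps genes closer than
#' `max_distance`. Genes whose nearest SED is common (C) stay in the table
#' but are excluded from the T-vs-N test downstream.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param seds SED `GRanges` with `domain_id`, `specificity`, `center`.
#' @param de DE table keyed by `feature_id` = gene id.
#' @param max_distance Maximum TSS-to-center distance in bp (default 2 Mb).
#' @param fdr Adjusted-p gate on the DE table (default 0.05).
#' @return data.frame with `gene_id`, `sed_id`, `sed_specificity`,
#'   `distance`, `log2fc`, `p_adj`.
#' @export
assign_genes <- function(genes, seds, de, max_distance = 2e6, fdr = 0.05) {
  if (length(seds) == 0L) stop("no SEDs to assign genes to")
  de <- de[match(genes$gene_id, de$feature_id), ]
  keep <- !is.na(de$p_adj) & de$p_adj < fdr
  g <- genes[keep, , drop = FALSE]
  d <- de[keep, , drop = FALSE]
  nn <- distance_to_nearest(g$chrom, g$tss,
                            as.character(seqnames(seds)),
                            mcols(seds)$center)
  ok <- !is.na(nn$distance) & nn$distance < max_distance
  data.frame(gene_id = g$gene_id[ok],
             sed_id = mcols(seds)$domain_id[nn$target_idx[ok]],
             sed_specificity = mcols(seds)$specificity[nn$target_idx[ok]],
             distance = nn$distance[ok],
             log2fc = d$log2fc[ok],
             p_adj = d$p_adj[ok],
             stringsAsFactors = FALSE)
}

#' Distance-binned T-SED vs N-SED fold-change comparison
#'
#' Splits assignments into consecutive distance bins and compares the log2
#' fold changes of T-SED-adjacent vs N-SED-adjacent genes per bin with the
#' two-sided Wilcoxon rank-sum test. Bins in which either group has fewer
#' than 2 genes are untestable (`p = NA`) and excluded from the BH family;
#' adjustment is across tested bins only.
#'
#' @param assignments Output of [assign_genes()].
#' @param bin_width Bin width in bp (default 100 kb).
#' @param max_distance Upper end of the last bin (default 2 Mb).
#' @return data.frame with `bin_lo`, `bin_hi`, `n_T`, `n_N`,
#'   `median_lfc_T`, `median_lfc_N`, `p`, `p_adj`.
#' @export
bin_and_test <- function(assignments, bin_width = 1e5, max_distance = 2e6) {
  lo <- seq(0, max_distance - bin_width, by = bin_width)
  hi <- lo + bin_width
  a <- assignments[assignments$sed_specificity %in% c("T", "N"), ,
                   drop = FALSE]
  bin <- findInterval(a$distance, c(lo, max_distance),
                      rightmost.closed = FALSE)
  res <- data.frame(bin_lo = lo, bin_hi = hi, n_T = 0L, n_N = 0L,
                    median_lfc_T = NA_real_, median_lfc_N = NA_real_,
                    p = NA_real_)
  for (i in seq_along(lo)) {
    xt <- a$log2fc[bin == i & a$sed_specificity == "T"]
    xn <- a$log2fc[bin == i & a$sed_specificity == "N"]
    res$n_T[i] <- length(xt)
    res$n_N[i] <- length(xn)
    if (length(xt)) res$median_lfc_T[i] <- median(xt)
    if (length(xn)) res$median_lfc_N[i] <- median(xn)
    if (length(xt) >= 2L && length(xn) >= 2L)
      res$p[i] <- wilcoxon_rank_sum(xt, xn)
  }
  res$p_adj <- bh_adjust(res$p)
  res
}
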