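# Core-gene-set integration: the three-way intersection of tumor-upregulated,
# T-SED-proximal, and treatment-downregulated genes, with background-relative
# Fisher overlap statistics.

#' Genes whose nearest SED center is tumor-specific and within a window
#'
#' A gene qualifies when the SED center nearest to its TSS belongs to a
#' tumor-specific (T) SED and lies within `window` bp. Genes whose nearest
#' SED is N or C are excluded even if some T-SED is also nearby
#' (nearest-specificity rule).
#'
#' @param genes Gene table.
#' @param seds SED `GRanges` with `specificity` and `center`.
#' @param window Maximum TSS-to-center distance in bp (default 2 Mb).
#' @return Character vector of gene ids.
#' @export
near_tsed_genes <- function(genes, seds, window = 2e6) {
  if (length(seds) == 0L || nrow(genes) == 0L) return(character(0))
  nn <- distance_to_nearest(genes$chrom, genes$tss,
                            as.character(seqnames(seds)),
                            mcols(seds)$center)
  ok <- !is.na(nn$distance) & nn$distance <= window &
    mcols(seds)$specificity[nn$target_idx] == "T"
  genes$gene_id[ok]
}

#' Intersect the core gene set
#'
#' The core set is the intersection of genes upregulated in tumors, genes
#' near tumor-specific SEDs, and genes downregulated by treatment in both
#' cell lines. Per-input Venn counts are reported alongside.
#'
#' @param up_tumor,near_tsed,down_jq1_line1,down_jq1_line2 Character
#'   vectors of gene ids from one background namespace.
#' @return List with `core_genes`, `inputs` (the four sets) and
#'   `venn_counts`.
#' @export
intersect_core <- function(up_tumor, near_tsed, down_jq1_line1,
                           down_jq1_line2) {
  inputs <- list(up_tumor = unique(up_tumor),
                 near_tsed = unique(near_tsed),
                 down_jq1_line1 = unique(down_jq1_line1),
                 down_jq1_line2 = unique(down_jq1_line2))
  core <- Reduce(intersect, inputs)
  venn <- c(vapply(inputs, length, 0L),
            up_and_near = length(intersect(inputs$up_tumor,
                                           inputs$near_tsed)),
            up_near_line1 = length(Reduce(intersect,
                                          inputs[c(1, 2, 3)])),
            up_near_line2 = length(Reduce(intersect,
                                          inputs[c(1, 2, 4)])),
            core = length(core))
  list(core_genes = sort(core), inputs = inputs, venn_counts = venn)
}

#' Background-relative Fisher overlap of two gene sets
#'
#' Builds the 2x2 presence/absence table of two sets against a background
#' universe, tests it with the exact test, and reports the sample odds
#' ratio with a Wald 95% confidence interval on the log odds ratio
#' (Haldane +0.5 on every cell when any cell is zero).
#'
#' @param set_a,set_b Character vectors, subsets of `background`.
#' @param background Character vector, the universe of tested genes.
#' @return List with `table` (a, b, c, d), `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
overlap_fisher <- function(set_a, set_b, background) {
  background <- unique(background)
  bad_a <- setdiff(set_a, background)
  bad_b <- setdiff(set_b, background)
  if (length(bad_a) || length(bad_b))
    stop("sets must be subsets of the background; offenders: ",
         paste(utils::head(c(bad_a, bad_b), 5), collapse = ", "))
  set_a <- unique(set_a); set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(background) - a - b - c_
  ft <- fisher_exact_2x2(a, b, c_, d)
  cells <- c(a, b, c_, d)
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  se <- sqrt(sum(1 / cc))
  lor <- log((cc[1] * cc[4]) / (cc[2] * cc[3]))
  list(table = c(a = a, b = b, c = c_, d = d),
       odds_ratio = ft$odds_ratio,
       ci_low = exp(lor - 1.96 * se),
       ci_high = exp(lor + 1.96 * se),
       p_value = ft$p_value)
}

#' Fisher overlap statistics for the core-set contrasts
#'
#' Runs [overlap_fisher()] for each requested contrast against one shared
#' background and BH-adjusts the p-values across the reported contrasts.
#'
#' @param contrasts Named list of `list(set_a =, set_b =)` pairs.
#' @param background Universe of tested genes.
#' @return data.frame with one row per contrast: table counts, odds ratio,
#'   CI, `p_value`, `p_adj`.
#' @export
core_overlap_table <- function(contrasts, background) {
  rows <- lapply(names(contrasts), function(nm) {
    fo <- overlap_fisher(contrasts[[nm]]$set_a, contrasts[[nm]]$set_b,
                         background)
    data.frame(contrast = nm, a = fo$table["a"], b = fo$table["b"],
               c = fo$table["c"], d = fo$table["d"],
               odds_ratio = fo$odds_ratio, ci_low = fo$ci_low,
               ci_high = fo$ci_high, p_value = fo$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p_value)
  out
}
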