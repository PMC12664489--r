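# Minimal differential-expression stage shared by mRNA and eRNA counts:
# median-of-ratios normalization, per-feature Welch test on log2 counts,
# BH adjustment, and the study's significance gates. External DE tables can
# be ingested unchanged.

#' Differential-expression configuration
#'
#' @param lfc_threshold_gene Absolute log2FC gate for genes (default 1).
#' @param lfc_threshold_erna Absolute log2FC gate for eRNAs (default 1.5).
#' @param fdr BH-adjusted p-value gate (default 0.05).
#' @param pseudocount Added before log2 (default 1).
#' @return List of class `de_config`.
#' @export
de_config <- function(lfc_threshold_gene = 1, lfc_threshold_erna = 1.5,
                      fdr = 0.05, pseudocount = 1) {
  if (lfc_threshold_gene <= 0 || lfc_threshold_erna <= 0)
    stop("log2FC thresholds must be positive")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  structure(list(lfc_threshold_gene = lfc_threshold_gene,
                 lfc_threshold_erna = lfc_threshold_erna,
                 fdr = fdr, pseudocount = pseudocount),
            class = "de_config")
}

#' Median-of-ratios normalization
#'
#' Size factor of a sample is the median, over features positive in every
#' sample, of the ratio of its count to the feature's geometric mean across
#' samples (the standard median-of-ratios estimator).
#'
#' @param counts Nonnegative feature-by-sample matrix.
#' @return List with `size_factors` (one per sample) and `normalized`
#'   (counts divided by size factors).
#' @export
median_ratio_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) == 1L) {
    return(list(size_factors = setNames(1, colnames(counts)),
                normalized = counts))
  }
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no feature with positive counts in all samples; ",
         "add a pseudocount before normalizing")
  lg <- log(counts[allpos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - geo)))
  list(size_factors = sf,
       normalized = sweep(counts, 2L, sf, "/"))
}

#' Per-feature differential expression test
#'
#' Counts are median-of-ratios normalized; per feature, the log2 fold change
#' is the difference of group means of `log2(normalized + pseudocount)`
#' (group A minus group B) and the p-value comes from a two-sided Welch
#' t-test on the same values, BH-adjusted across all tested features.
#' Features with zero counts in every sample are excluded.
#'
#' @param counts Feature-by-sample count matrix (rownames = feature ids).
#' @param labels Character vector of per-sample condition labels.
#' @param group_a,group_b Labels of the two conditions; the fold change is
#'   A over B.
#' @param cfg A [de_config()].
#' @return data.frame with `feature_id`, `mean_expression`, `log2fc`,
#'   `p_value`, `p_adj`.
#' @export
de_test <- function(counts, labels, group_a, group_b, cfg = de_config()) {
  counts <- as.matrix(counts)
  stopifnot(length(labels) == ncol(counts))
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need at least two samples per condition")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  norm <- median_ratio_normalize(counts)$normalized
  lx <- log2(norm + cfg$pseudocount)
  ma <- rowMeans(lx[, ia, drop = FALSE])
  mb <- rowMeans(lx[, ib, drop = FALSE])
  va <- apply(lx[, ia, drop = FALSE], 1L, var)
  vb <- apply(lx[, ib, drop = FALSE], 1L, var)
  na <- length(ia); nb <- length(ib)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate features: identical values in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(ma[flat] == mb[flat], 1, 0)
  data.frame(feature_id = rownames(counts),
             mean_expression = rowMeans(norm),
             log2fc = ma - mb,
             p_value = p,
             p_adj = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Select significant features from a DE table
#'
#' Features with `p_adj < fdr` and log2 fold change strictly beyond the
#' threshold in the requested direction. A threshold of 0 reproduces the
#' p-only gates used for set intersections.
#'
#' @param results DE table from [de_test()] or [read_de_table()].
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param lfc_threshold Absolute log2FC threshold (strict inequality).
#' @param fdr BH-adjusted p-value gate (strict inequality).
#' @return Character vector of feature ids.
#' @export
significant_set <- function(results, direction = c("up", "down", "both"),
                            lfc_threshold = 1, fdr = 0.05) {
  direction <- match.arg(direction)
  ok <- !is.na(results$p_adj) & results$p_adj < fdr
  ok <- ok & switch(direction,
                    up = results$log2fc > lfc_threshold,
                    down = results$log2fc < -lfc_threshold,
                    both = abs(results$log2fc) > lfc_threshold)
  results$feature_id[ok]
}

#' Ingest an externally produced DE table
#'
#' Reads a TSV with columns `feature_id`, `log2fc`, `p_value`, `p_adj` (and
#' optionally `mean_expression`), preserving every value bit-exactly so that
#' tables from other DE engines can drive the downstream stages.
#'
#' @param path TSV path.
#' @return data.frame in the [de_test()] output layout.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("feature_id", "log2fc", "p_value", "p_adj")
  if (!all(need %in% names(df)))
    stop("DE table ", path, " must have columns ", paste(need, collapse = ", "))
  if (is.null(df$mean_expression)) df$mean_expression <- NA_real_
  df[, c("feature_id", "mean_expression", "log2fc", "p_value", "p_adj")]
}

#' Write a DE table to TSV
#' @param results DE table.
#' @param path Output path.
#' @export
write_de_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats pt
NULL
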