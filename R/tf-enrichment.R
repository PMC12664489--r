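# Shade-controlled TF binding-site enrichment: cistrome preparation,
# length-matched flanking controls ("shades") at fixed distances, per-TF
# Fisher tests with worst-case selection over distances, Bonferroni
# correction, and the tumor-normal delta of log odds ratios.

#' Prepare a cistrome catalog for enrichment testing
#'
#' Per TF, neighbouring binding regions separated by at most `merge_distance`
#' bp are merged, then regions shorter than `min_len` or longer than
#' `max_len` bp are dropped. TFs left with no region are removed from the
#' catalog.
#'
#' @param catalog Named list of `GRanges`, one per TF.
#' @param merge_distance Merge gap in bp.
#' @param min_len,max_len Region length bounds in bp (defaults 50 and 10000).
#' @return Filtered named list of `GRanges`.
#' @export
prepare_cistrome <- function(catalog, merge_distance = 0,
                             min_len = 50, max_len = 10000) {
  out <- lapply(catalog, function(gr) {
    m <- merge_intervals(gr, merge_distance)
    m[width(m) >= min_len & width(m) <= max_len]
  })
  out[vapply(out, length, 0L) > 0L]
}

#' Build length-matched control regions ("shades") for a domain set
#'
#' For each domain of length L, two control regions of the same length are
#' placed at fixed edge-to-edge distance `D`: one immediately upstream
#' (ending D bp before the domain start) and one downstream (starting D bp
#' after the domain end). Shades that would extend beyond the chromosome are
#' dropped whole; finally, overlapping shades within the control set are
#' merged.
#'
#' @param domains Domain `GRanges`.
#' @param D Edge-to-edge distance in bp (> 0).
#' @param genome Genome table (named lengths) used for bounds.
#' @return `GRanges` of merged control regions.
#' @export
make_shades <- function(domains, D, genome) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0) stop("D must be > 0")
  check_genome(genome)
  chr <- as.character(seqnames(domains))
  L <- width(domains)
  up <- GRanges(chr, IRanges(start = start(domains) - D - L,
                             end = start(domains) - D - 1))
  down <- GRanges(chr, IRanges(start = end(domains) + D + 1,
                               end = end(domains) + D + L))
  shades <- c(up, down)
  keep <- start(shades) >= 1 &
    end(shades) <= genome[as.character(seqnames(shades))]
  merge_intervals(shades[keep], 0)
}

#' 2x2 region-level overlap table for a TF
#'
#' Counts regions (not hits): `a` test regions with at least 1 bp of overlap
#' with any TF region, `b` without; `c`, `d` likewise for the control set.
#'
#' @param test,control `GRanges` of test and control regions (both nonempty).
#' @param tf_regions `GRanges` of the TF's binding regions.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
overlap_table <- function(test, control, tf_regions) {
  if (length(test) == 0L || length(control) == 0L)
    stop("test and control sets must be nonempty")
  a <- sum(overlapsAny(test, tf_regions, ignore.strand = TRUE))
  c_ <- sum(overlapsAny(control, tf_regions, ignore.strand = TRUE))
  c(a = a, b = length(test) - a, c = c_, d = length(control) - c_)
}

#' Shade-controlled TFBS enrichment for one domain set
#'
#' For every TF and every distance `D`, shades are built, the region-level
#' 2x2 overlap table is formed, and the Fisher exact test is run. The
#' worst case over distances is selected componentwise: the smaller odds
#' ratio and the larger (less significant) p-value, possibly from different
#' distances. P-values are Bonferroni-corrected for the number of TFs
#' tested; a TF is significantly enriched when the adjusted p-value is at
#' most 0.05.
#'
#' @param domains Domain `GRanges` (one category and specificity class).
#' @param cistrome Prepared cistrome catalog (named list of `GRanges`).
#' @param genome Genome table.
#' @param D_values Distances in bp (default `c(10000, 100000)`).
#' @param alpha Significance level on the Bonferroni-adjusted p (0.05).
#' @return data.frame with one row per TF: per-distance odds ratios and
#'   p-values, `selected_or`, `selected_p`, `p_bonferroni`, `significant`,
#'   and the four selected-table counts.
#' @export
enrich_tfs <- function(domains, cistrome, genome,
                       D_values = c(10000, 100000), alpha = 0.05) {
  if (length(domains) == 0L) stop("domain set is empty")
  n_tf <- length(cistrome)
  shade_sets <- lapply(D_values, make_shades, domains = domains,
                       genome = genome)
  rows <- vector("list", n_tf)
  for (i in seq_len(n_tf)) {
    tf <- names(cistrome)[i]
    res <- tryCatch({
      ors <- numeric(length(D_values))
      ps <- numeric(length(D_values))
      tabs <- vector("list", length(D_values))
      for (j in seq_along(D_values)) {
        tab <- overlap_table(domains, shade_sets[[j]], cistrome[[i]])
        ft <- fisher_exact_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
        ors[j] <- ft$odds_ratio
        ps[j] <- ft$p_value
        tabs[[j]] <- tab
      }
      row <- data.frame(tf = tf, stringsAsFactors = FALSE)
      dl <- format(D_values, scientific = FALSE, trim = TRUE)
      for (j in seq_along(D_values)) {
        row[[paste0("or_", dl[j])]] <- ors[j]
        row[[paste0("p_", dl[j])]] <- ps[j]
      }
      row$selected_or <- min(ors)
      row$selected_p <- max(ps)
      row$p_bonferroni <- min(1, max(ps) * n_tf)
      row$significant <- row$p_bonferroni <= alpha
      sel <- tabs[[which.min(ors)]]
      row$a <- sel["a"]; row$b <- sel["b"]; row$c <- sel["c"]; row$d <- sel["d"]
      row
    }, error = function(e) {
      warning("skipping TF ", tf, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Tumor-normal delta of log odds ratios for one TF
#'
#' `delta = ln(selected_or_T) - ln(selected_or_N)` on continuity-corrected
#' odds ratios; a positive delta means higher enrichment in tumor-specific
#' domains.
#'
#' @param record_t,record_n Single-row data.frames (or list-like) for the
#'   same TF from [enrich_tfs()] run against T- and N-specific domains.
#' @return Numeric delta.
#' @export
delta_enrichment <- function(record_t, record_n) {
  if (is.null(record_t) || is.null(record_n))
    stop("both tumor and normal records are required")
  if (!identical(as.character(record_t$tf), as.character(record_n$tf)))
    stop("records are for different TFs")
  log(record_t$selected_or) - log(record_n$selected_or)
}

#' Contrast TF enrichment between tumor- and normal-specific domains
#'
#' Runs [enrich_tfs()] separately on the T- and N-specific domains of one
#' category and joins the results per TF with the delta of log odds ratios.
#'
#' @param domains Pooled domain `GRanges` of one category (with
#'   `specificity` metadata).
#' @param cistrome Prepared cistrome catalog.
#' @param genome Genome table.
#' @inheritParams enrich_tfs
#' @return data.frame with per-TF `log_or_T`, `log_or_N`, `delta`,
#'   `significant_T`, `significant_N` alongside the selected statistics.
#' @export
tf_domain_contrast <- function(domains, cistrome, genome,
                               D_values = c(10000, 100000), alpha = 0.05) {
  dom_t <- domains[mcols(domains)$specificity == "T"]
  dom_n <- domains[mcols(domains)$specificity == "N"]
  rec_t <- enrich_tfs(dom_t, cistrome, genome, D_values, alpha)
  rec_n <- enrich_tfs(dom_n, cistrome, genome, D_values, alpha)
  common <- intersect(rec_t$tf, rec_n$tf)
  rec_t <- rec_t[match(common, rec_t$tf), ]
  rec_n <- rec_n[match(common, rec_n$tf), ]
  data.frame(
    tf = common,
    or_T = rec_t$selected_or, p_T = rec_t$selected_p,
    p_bonferroni_T = rec_t$p_bonferroni,
    or_N = rec_n$selected_or, p_N = rec_n$selected_p,
    p_bonferroni_N = rec_n$p_bonferroni,
    log_or_T = log(rec_t$selected_or),
    log_or_N = log(rec_n$selected_or),
    delta = log(rec_t$selected_or) - log(rec_n$selected_or),
    significant_T = rec_t$significant,
    significant_N = rec_n$significant,
    stringsAsFactors = FALSE
  )
}
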