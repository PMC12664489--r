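# Promoter/enhancer classification, super-enhancer calling via the ROSE
# tangent cutoff, and cross-sample pooling into PD/ED/SED domains.

#' Classify H3K27ac peaks into promoters and enhancers
#'
#' A peak is a promoter iff its interval intersects the closed window
#' `[TSS - w, TSS + w]` of any gene (`w = promoter_window`); every other peak
#' is an enhancer. The partition is exhaustive and exclusive; a peak touching
#' the windows of several genes is still one promoter.
#'
#' @param peaks `GRanges` with metadata columns `signal` (normalized H3K27ac
#'   density, >= 0) and `sample_id`.
#' @param genes Gene table (data.frame with `gene_id`, `chrom`, `tss`).
#' @param promoter_window Half-width of the TSS window in bp (default 2500).
#' @return `peaks` with an added `element_class` column.
#' @export
classify_peaks <- function(peaks, genes, promoter_window = 2500) {
  stopifnot(is(peaks, "GRanges"))
  if (nrow(genes) == 0L) stop("cannot classify peaks with an empty gene list")
  if (promoter_window <= 0) stop("promoter_window must be positive")
  if (is.null(mcols(peaks)$signal)) stop("peaks must carry a 'signal' column")
  if (any(mcols(peaks)$signal < 0)) stop("peak signal must be >= 0")
  win <- GRanges(genes$chrom,
                 IRanges(pmax(1, genes$tss - promoter_window),
                         genes$tss + promoter_window))
  hit <- overlapsAny(peaks, win, ignore.strand = TRUE)
  mcols(peaks)$element_class <- ifelse(hit, "promoter", "enhancer")
  peaks
}

#' Score enhancer elements by summed signal density
#'
#' The super-enhancer score of an element is the sum over its constituent
#' peaks of `signal * (bases of overlap)`. For unstitched elements (each
#' element one peak) this is `signal * width`.
#'
#' @param elements `GRanges` of enhancer elements.
#' @param peaks `GRanges` with a `signal` column (the same sample's peaks).
#' @return Numeric vector of scores, one per element.
#' @export
score_enhancers <- function(elements, peaks) {
  score <- numeric(length(elements))
  if (length(elements) == 0L || length(peaks) == 0L) return(score)
  hits <- findOverlaps(elements, peaks, ignore.strand = TRUE)
  if (length(hits) == 0L) return(score)
  ov <- width(pintersect(elements[queryHits(hits)], peaks[subjectHits(hits)]))
  contrib <- ov * mcols(peaks)$signal[subjectHits(hits)]
  agg <- tapply(contrib, queryHits(hits), sum)
  score[as.integer(names(agg))] <- as.numeric(agg)
  score
}

#' ROSE tangent cutoff on a rank-ordered score curve
#'
#' Scores are sorted ascending; ranks and scores are each rescaled to
#' \[0, 1\] and the cutoff index is the argmax of `x - y`, the point at which
#' the convex rank-score curve attains slope 1 (the classic ROSE geometric
#' threshold). Ties in the argmax break to the largest index, i.e. the fewest
#' super-enhancers; a constant score vector yields no super-enhancers.
#' Elements with score strictly greater than the cutoff score are
#' super-enhancers.
#'
#' @param scores Numeric vector of >= 3 enhancer scores.
#' @return List with `cutoff` (score at the tangent point) and `index`
#'   (position of the cutoff in the ascending sort).
#' @export
rose_cutoff <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 scores")
  s <- sort(scores)
  n <- length(s)
  if (s[n] == s[1L]) return(list(cutoff = s[n], index = n))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1L]) / (s[n] - s[1L])
  d <- x - y
  idx <- max(which(d >= max(d) - 1e-12))
  list(cutoff = s[idx], index = idx)
}

#' Call regulatory elements for one sample
#'
#' Classifies peaks against TSS windows, optionally stitches nearby enhancer
#' peaks, scores enhancers by summed signal density, and promotes the
#' strongest enhancers to super-enhancers using the per-sample ROSE cutoff.
#'
#' @param peaks One sample's peaks (`GRanges` with `signal`, `sample_id`).
#' @param genes Gene table.
#' @param promoter_window TSS window half-width in bp.
#' @param stitch_distance Gap (bp) bridged between enhancer peaks before
#'   scoring; 0 keeps each peak as its own element.
#' @return `GRanges` of elements with `element_class` in
#'   `{promoter, enhancer, super_enhancer}`, `se_score` (NA for promoters)
#'   and `sample_id`.
#' @export
call_regulatory_elements <- function(peaks, genes, promoter_window = 2500,
                                     stitch_distance = 0) {
  cls <- classify_peaks(peaks, genes, promoter_window)
  sample_id <- unique(mcols(peaks)$sample_id)
  if (length(sample_id) != 1L) stop("call_regulatory_elements is per sample")
  prom <- cls[mcols(cls)$element_class == "promoter"]
  enh <- cls[mcols(cls)$element_class == "enhancer"]
  if (stitch_distance > 0 && length(enh) > 1L) {
    stitched <- merge_intervals(granges(enh), stitch_distance)
  } else {
    stitched <- granges(sort(enh))
  }
  score <- score_enhancers(stitched, enh)
  cut <- if (length(score) >= 3L) rose_cutoff(score)$cutoff else Inf
  out_enh <- stitched
  mcols(out_enh)$element_class <- ifelse(score > cut, "super_enhancer",
                                         "enhancer")
  mcols(out_enh)$se_score <- score
  out_prom <- granges(prom)
  if (length(out_prom)) {
    mcols(out_prom)$element_class <- "promoter"
    mcols(out_prom)$se_score <- NA_real_
  }
  out <- sort(c(out_prom, out_enh))
  mcols(out)$sample_id <- sample_id
  out
}

#' Pool per-sample elements of one category into domains
#'
#' Domains are the cross-sample union of overlapping elements of a single
#' category: every base covered by that category in at least one sample lies
#' in exactly one domain. Each domain records its supporting samples and is
#' labeled tumor-specific (T) when all supporters are tumor samples,
#' normal-specific (N) when all are normal, and common (C) otherwise.
#'
#' @param element_sets List of per-sample element `GRanges` (as returned by
#'   [call_regulatory_elements()]).
#' @param category One of `"P"`, `"E"`, `"SE"`.
#' @param conditions Named character vector mapping `sample_id` to
#'   `"tumor"` or `"normal"`.
#' @return `GRanges` of domains with `domain_id`, `category`, `specificity`,
#'   `supporting_samples` (comma-joined) and `center` metadata.
#' @export
pool_domains <- function(element_sets, category = c("P", "E", "SE"),
                         conditions) {
  category <- match.arg(category)
  cls <- c(P = "promoter", E = "enhancer", SE = "super_enhancer")[category]
  if (length(element_sets) < 1L) stop("need at least one sample")
  parts <- lapply(element_sets, function(el) {
    el[mcols(el)$element_class == cls]
  })
  all_el <- suppressWarnings(do.call(c, unname(lapply(parts, granges))))
  if (length(all_el) == 0L) {
    out <- GRanges()
    mcols(out)$domain_id <- character(0)
    mcols(out)$category <- character(0)
    mcols(out)$specificity <- character(0)
    mcols(out)$supporting_samples <- character(0)
    mcols(out)$center <- numeric(0)
    return(out)
  }
  dom <- merge_intervals(all_el, 0)
  supporters <- vector("list", length(dom))
  for (p in parts) {
    if (length(p) == 0L) next
    sid <- unique(mcols(p)$sample_id)
    hits <- unique(queryHits(findOverlaps(dom, p, ignore.strand = TRUE)))
    for (h in hits) supporters[[h]] <- c(supporters[[h]], sid)
  }
  supporters <- lapply(supporters, function(s) sort(unique(s)))
  cond <- lapply(supporters, function(s) unique(unname(conditions[s])))
  spec <- vapply(cond, function(cc) {
    if (all(cc == "tumor")) "T" else if (all(cc == "normal")) "N" else "C"
  }, "")
  mcols(dom)$domain_id <- sprintf("%sD_%05d", category, seq_along(dom))
  mcols(dom)$category <- paste0(category, "D")
  mcols(dom)$specificity <- spec
  mcols(dom)$supporting_samples <-
    vapply(supporters, paste, "", collapse = ",")
  # domain center, floor of the midpoint in 0-based half-open coordinates
  mcols(dom)$center <- floor((start(dom) - 1 + end(dom)) / 2) + 1
  dom
}

#' Pool all three domain categories for a cohort of samples
#'
#' @inheritParams pool_domains
#' @return Named list with `PD`, `ED`, `SED` domain `GRanges`.
#' @export
build_domains <- function(element_sets, conditions) {
  list(PD = pool_domains(element_sets, "P", conditions),
       ED = pool_domains(element_sets, "E", conditions),
       SED = pool_domains(element_sets, "SE", conditions))
}
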