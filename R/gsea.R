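# Preranked gene-set enrichment: running-sum enrichment score with a
# gene-label permutation null, sign-matched NES, and the standard NES-ratio
# FDR; plus hypergeometric over-representation for GO-style term sets.

#' Read gene sets in GMT format
#' @param path GMT file: set name, description, then member genes, tab
#'   separated, one set per line.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line in ", path, " at line ", bad[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

# enrichment score from sorted hit positions
# pos: sorted positions of set members in the descending ranking
# w: |stat|^weight at those positions; N: universe size
.es_from_positions <- function(pos, w, N) {
  n <- length(pos)
  nr <- sum(w)
  miss <- 1 / (N - n)
  cumw <- cumsum(w)
  if (nr == 0) {  # all-zero weights (weight > 0 with zero stats): hits inert
    after <- -(pos - seq_len(n)) * miss
    before <- after
  } else {
    after <- cumw / nr - (pos - seq_len(n)) * miss
    before <- c(0, cumw[-n] / nr) - (pos - 1 - (seq_len(n) - 1)) * miss
  }
  es_pos <- max(after, 0)
  es_neg <- min(before, 0)
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are sorted by the ranking statistic, descending, with ties broken
#' by gene id. The enrichment score (ES) is the maximum deviation of a
#' running sum that increments at set members proportionally to
#' `|statistic|^weight` (normalized to 1 within the set) and decrements by
#' `1/(N - n)` elsewhere. The null distribution comes from `n_perm` random
#' gene-label permutations at fixed set size; the p-value is the fraction
#' of same-sign null ES at least as extreme, the
#' NES divides the ES by the mean |null ES| of the same sign, and the FDR
#' is the standard preranked NES-ratio estimate over the pooled normalized
#' null.
#'
#' @param ranking Named numeric vector, gene -> statistic; the names define
#'   the universe.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param weight Hit-weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe (defaults 5 and 500); sets outside are skipped.
#' @return data.frame with `set_name`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, `leading_edge` (comma-joined gene ids).
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, seed = 1,
                           weight = 1, min_size = 5, max_size = 500) {
  if (any(!is.finite(ranking))) stop("ranking statistics must be finite")
  universe <- names(ranking)
  if (is.null(universe) || anyDuplicated(universe))
    stop("ranking must be named with unique gene ids")
  o <- order(-ranking, universe)  # descending, ties by gene id
  stat <- ranking[o]
  gene <- universe[o]
  N <- length(stat)
  w_all <- abs(stat)^weight
  sets <- lapply(sets, function(s) which(gene %in% s))
  keep <- vapply(sets, length, 0L)
  usable <- keep >= min_size & keep <= max_size & keep < N
  if (!any(usable))
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      leading_edge = character(0)))
  sets <- sets[usable]
  set.seed(seed)
  res <- data.frame(set_name = names(sets),
                    size = vapply(sets, length, 0L),
                    es = NA_real_, nes = NA_real_, p_value = NA_real_,
                    fdr = NA_real_, leading_edge = NA_character_,
                    stringsAsFactors = FALSE)
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pos <- sort(sets[[i]])
    n <- length(pos)
    es <- .es_from_positions(pos, w_all[pos], N)
    null_es <- vapply(seq_len(n_perm), function(b) {
      p <- sort(sample.int(N, n))
      .es_from_positions(p, w_all[p], N)
    }, 0)
    pos_null <- null_es[null_es >= 0]
    neg_null <- null_es[null_es < 0]
    if (es >= 0) {
      p <- if (length(pos_null)) mean(pos_null >= es) else 1 / (n_perm + 1)
      denom <- mean(pos_null)
    } else {
      p <- if (length(neg_null)) mean(neg_null <= es) else 1 / (n_perm + 1)
      denom <- mean(abs(neg_null))
    }
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    norm_null <- null_es
    if (length(pos_null) && mean(pos_null) > 0)
      norm_null[null_es >= 0] <- pos_null / mean(pos_null)
    if (length(neg_null) && mean(abs(neg_null)) > 0)
      norm_null[null_es < 0] <- neg_null / mean(abs(neg_null))
    null_nes[[i]] <- norm_null
    # leading edge: members up to (from) the running-sum extremum
    w <- w_all[pos]
    nr <- sum(w)
    miss <- 1 / (N - n)
    run_after <- if (nr > 0) cumsum(w) / nr - (pos - seq_len(n)) * miss else
      -(pos - seq_len(n)) * miss
    if (es >= 0) {
      le <- gene[pos[seq_len(which.max(run_after))]]
    } else {
      run_before <- run_after - if (nr > 0) w / nr else 0
      le <- gene[pos[seq(which.min(run_before), n)]]
    }
    res$es[i] <- es
    res$nes[i] <- nes
    res$p_value[i] <- p
    res$leading_edge[i] <- paste(le, collapse = ",")
  }
  all_null <- unlist(null_nes)
  for (i in seq_len(nrow(res))) {
    nes <- res$nes[i]
    if (!is.finite(nes)) next
    if (nes >= 0) {
      num <- mean(all_null >= nes)
      den <- mean(res$nes >= nes, na.rm = TRUE)
    } else {
      num <- mean(all_null <= nes)
      den <- mean(res$nes <= nes, na.rm = TRUE)
    }
    res$fdr[i] <- min(1, if (den > 0) num / den else 1)
  }
  res
}

#' Hypergeometric over-representation of term sets in a query
#'
#' Per term: upper-tail hypergeometric p-value for observing at least `k`
#' query genes in the term, with `N = |background|`,
#' `K = |term `&cap;` background|`, `n = |query|`; BH adjustment across
#' terms.
#'
#' @param query Character vector of genes, a subset of `background`.
#' @param terms Named list of character vectors.
#' @param background Universe of genes.
#' @param min_size,max_size Term-size bounds within the background.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `p_value`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, terms, background,
                             min_size = 5, max_size = 500) {
  background <- unique(background)
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query genes missing from background: ",
         paste(utils::head(bad, 5), collapse = ", "))
  query <- unique(query)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(terms), function(nm) {
    term <- intersect(terms[[nm]], background)
    K <- length(term)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, term))
    data.frame(term = nm, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adj = numeric(0)))
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p_value)
  out
}
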