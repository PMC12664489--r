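# Independent oracles and a light-weight simulation config used across the
# test suite. Oracles deliberately use different algorithms (and different
# numeric paths) from the implementation they check.

# exact two-sided Fisher p by enumeration with choose() arithmetic
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c; N <- n1 + n2
  xs <- max(0, K - n2):min(n1, K)
  probs <- choose(n1, xs) * choose(n2, K - xs) / choose(N, K)
  p_obs <- choose(n1, a) * choose(n2, K - a) / choose(N, K)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# BH step-up by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# tau-b by O(n^2) pair counting
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# two-sided Wilcoxon rank-sum p by full enumeration of group assignments
oracle_wilcox_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}

# transitive-closure interval merge by O(n^2) scanning
oracle_merge <- function(starts, ends, gap = 0) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:n) {
      if (grp[i] != grp[j] &&
          starts[i] <= ends[j] + gap && starts[j] <= ends[i] + gap) {
        g <- min(grp[i], grp[j])
        grp[grp == grp[i] | grp == grp[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- t(vapply(unique(grp), function(g)
    c(min(starts[grp == g]), max(ends[grp == g])), c(0, 0)))
  out[order(out[, 1]), , drop = FALSE]
}

# enrichment score by a literal gene-by-gene running sum
oracle_es <- function(stat_sorted, member, weight) {
  N <- length(stat_sorted)
  n <- sum(member)
  w <- abs(stat_sorted)^weight
  nr <- sum(w[member])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (member[i]) w[i] / nr else -1 / (N - n)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# small, fast cohort configuration for unit tests
small_cfg <- function(seed = 17, ...) {
  args <- list(seed = seed, n_chrom = 2, chrom_length = 5e7,
               n_genes = 300, n_rna_tumor = 6, n_rna_normal = 6,
               n_rep_jq1 = 4, n_tfs = 6, n_enriched_tfs = 2,
               tf_regions_per_tf = 3000, n_sed_t = 8, n_sed_n = 8,
               n_sed_c = 4, n_jq1_reversed = 6, n_jq1_background = 40,
               n_bg_enhancers = 500)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# GRanges shorthand
gr <- function(chrom, start, end, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}
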