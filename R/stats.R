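# Shared statistical primitives: exact 2x2 test with the sample odds ratio,
# BH adjustment, rank-sum and Kendall wrappers with defined exactness regimes.

#' Two-sided Fisher exact test on a 2x2 table with sample odds ratio
#'
#' The p-value is the exact two-sided probability: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. The odds ratio is the sample
#' (cross-product) estimate `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 on every cell) is applied to the odds
#' ratio only, never to the p-value.
#'
#' @param a,b,c,d Nonnegative integer cell counts; rows are test/control,
#'   columns are overlap/no-overlap. Both row margins must be positive.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be >= 0")
  if ((a + b) <= 0 || (c + d) <= 0) stop("both row margins must be positive")
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  # hypergeometric over tables with fixed margins; column margin K = a + c
  n1 <- a + b
  n2 <- c + d
  K <- a + c
  x <- max(0L, K - n2):min(n1, K)
  pmf <- dhyper(x, n1, n2, K)
  p_obs <- dhyper(a, n1, n2, K)
  p <- min(1, sum(pmf[pmf <= p_obs * (1 + 1e-9)]))
  list(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across a family of p-values; `NA` entries are
#' excluded from the family size and returned as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (via the exact rank-sum distribution) when the pooled
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Kendall's tau-b with two-sided p-value
#'
#' Tau is the tie-corrected tau-b. The p-value is exact (enumeration over the
#' permutation distribution) for n <= 8 without ties, and otherwise uses the
#' normal approximation with tie correction.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `tau`, `p_value` and `n`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  ties <- (anyDuplicated(x) > 0L) || (anyDuplicated(y) > 0L)
  tau <- cor(x, y, method = "kendall")
  p <- suppressWarnings(
    cor.test(x, y, method = "kendall", alternative = "two.sided",
             exact = (n <= 8L && !ties), continuity = FALSE)$p.value
  )
  list(tau = tau, p_value = min(1, p), n = n)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for drawing `n` genes from a background of size `N` containing
#' `K` term members.
#'
#' @param k Observed overlap.
#' @param K Term size within the background.
#' @param n Query size.
#' @param N Background size.
#' @return Upper-tail p-value.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @importFrom stats cor.test dhyper phyper wilcox.test t.test
NULL
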