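# Promoter/enhancer classification, SE scoring, the ROSE cutoff, and
# cross-sample domain pooling.

genes1 <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                     tss = 100001)  # 0-based TSS 100000

test_that("classify_peaks applies the TSS-window rule with half-open bounds", {
  # [98000,99000) intersects the window around TSS 100000 at w = 2500
  pk <- gr("chr1", 98001, 99000, signal = 1, sample_id = "s")
  out <- classify_peaks(pk, genes1, 2500)
  expect_equal(mcols(out)$element_class, "promoter")
  # [90000,97000) ends one base short of the window start 97500
  pk <- gr("chr1", 90001, 97000, signal = 1, sample_id = "s")
  out <- classify_peaks(pk, genes1, 2500)
  expect_equal(mcols(out)$element_class, "enhancer")
  # overlapping the windows of two genes still yields one promoter
  g2 <- rbind(genes1, data.frame(gene_id = "g2", chrom = "chr1",
                                 strand = "-", tss = 101001))
  pk <- gr("chr1", 99001, 103000, signal = 1, sample_id = "s")
  out <- classify_peaks(pk, g2, 2500)
  expect_equal(length(out), 1L)
  expect_equal(mcols(out)$element_class, "promoter")
  expect_error(classify_peaks(pk, genes1[0, ], 2500), "empty gene")
})

test_that("score_enhancers sums signal times overlap length", {
  el <- gr("chr1", 1001, 2000)
  pk <- gr("chr1", 1001, 2000, signal = 2)
  expect_equal(score_enhancers(el, pk), 2000)
  mcols(pk)$signal <- 0
  expect_equal(score_enhancers(el, pk), 0)
  # two peaks inside one element: 1.0 x 500 bp + 3.0 x 100 bp = 800
  el <- gr("chr1", 1, 1000)
  pk <- gr("chr1", c(101, 701), c(600, 800), signal = c(1, 3))
  expect_equal(score_enhancers(el, pk), 800)
})

test_that("rose_cutoff finds the slope-1 tangent of a convex curve", {
  n <- 1000
  scores <- (seq_len(n) / n)^2
  cut <- rose_cutoff(scores)
  # d/dx x^2 = 1 at x = 0.5: cutoff at scaled rank 0.5 +/- 1 rank
  expect_lte(abs(cut$index - n / 2), 1)
  # all equal -> no super-enhancers (nothing strictly above the cutoff)
  cut <- rose_cutoff(rep(3, 10))
  expect_equal(sum(rep(3, 10) > cut$cutoff), 0L)
  # strictly linear -> x - y == 0 -> tie resolves to the last index
  cut <- rose_cutoff(seq(0, 1, length.out = 50))
  expect_equal(cut$index, 50L)
  expect_error(rose_cutoff(c(1, 2)), "at least 3")
})

test_that("rose_cutoff equals exhaustive argmax on random convex curves", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(10:500, 1)
    k <- runif(1, 1.5, 6)
    scores <- sort(runif(n))^k * runif(1, 10, 1e4)
    got <- rose_cutoff(scores)
    s <- sort(scores)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    d <- x - y
    best <- max(which(d >= max(d) - 1e-12))
    expect_equal(got$index, best)
    expect_equal(got$cutoff, s[best])
  }
})

test_that("super-enhancer count is non-increasing in the cutoff score", {
  set.seed(12)
  scores <- rlnorm(500, 3, 1)
  cuts <- sort(runif(20, min(scores), max(scores)))
  n_se <- vapply(cuts, function(cc) sum(scores > cc), 0L)
  expect_true(all(diff(n_se) <= 0))
})

test_that("pool_domains merges across samples and labels specificity", {
  conds <- c(tumor1 = "tumor", tumor2 = "tumor", normal1 = "normal")
  mk <- function(sample_id, start, end, class = "super_enhancer") {
    gr("chr1", start, end, element_class = class, se_score = 1,
       sample_id = sample_id)
  }
  # SE [0,1000) in tumor1 + SE [500,1500) in normal1 -> one common SED
  dom <- pool_domains(list(mk("tumor1", 1, 1000), mk("normal1", 501, 1500)),
                      "SE", conds)
  expect_equal(length(dom), 1L)
  expect_equal(c(start(dom), end(dom)), c(1, 1500))
  expect_equal(mcols(dom)$specificity, "C")
  expect_equal(mcols(dom)$supporting_samples, "normal1,tumor1")
  # exclusively tumor -> T
  dom <- pool_domains(list(mk("tumor1", 1, 1000)), "SE", conds)
  expect_equal(mcols(dom)$specificity, "T")
  # present in every sample -> C
  dom <- pool_domains(list(mk("tumor1", 1, 1000), mk("tumor2", 10, 900),
                           mk("normal1", 100, 1100)), "SE", conds)
  expect_equal(mcols(dom)$specificity, "C")
  # center = floor((start0 + end0) / 2), reported 1-based
  dom <- pool_domains(list(mk("tumor1", 1, 1000)), "SE", conds)
  expect_equal(mcols(dom)$center, floor((0 + 1000) / 2) + 1)
  expect_error(pool_domains(list(), "SE", conds), "at least one")
})

test_that("pooling is independent of sample order and categories stay apart", {
  co <- simulate_cohort(small_cfg(), parts = "peaks")
  els <- lapply(co$peaks, call_regulatory_elements, genes = co$genes)
  d1 <- pool_domains(els, "SE", co$conditions)
  d2 <- pool_domains(rev(els), "SE", co$conditions)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  # domains of one category are pairwise non-overlapping
  for (cat in c("P", "E", "SE")) {
    dom <- pool_domains(els, cat, co$conditions)
    expect_equal(sum(countOverlaps(dom, dom) != 1L), 0L)
  }
})

test_that("per-sample element calling recovers the planted SE tail", {
  co <- simulate_cohort(small_cfg(), parts = "peaks")
  els <- lapply(co$peaks, call_regulatory_elements, genes = co$genes)
  dom <- build_domains(els, co$conditions)
  sed <- co$truth$sed
  planted <- gr(sed$chrom, sed$start + 1, sed$end)
  hit <- findOverlaps(planted, dom$SED)
  # every planted SED is recovered with matching specificity
  expect_equal(length(unique(queryHits(hit))), nrow(sed))
  first <- hit[!duplicated(queryHits(hit))]
  expect_equal(mcols(dom$SED)$specificity[subjectHits(first)],
               sed$specificity[queryHits(first)])
})
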