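# Cistrome preparation, shade construction, overlap tables, and the
# worst-case-over-distance enrichment contrast.

test_that("prepare_cistrome merges then filters by region length", {
  cat <- list(TFA = gr("chr1", c(1, 41), c(30, 60)))
  # [0,30) + [40,60) merge at 10 kb -> one region of 60 bp, kept
  out <- prepare_cistrome(cat, 10000)
  expect_equal(width(out$TFA), 60)
  # a 40 bp region (< 50) is dropped, eliminating the TF
  out <- prepare_cistrome(list(TFB = gr("chr1", 100, 139)), 0)
  expect_length(out, 0L)
  # merged length 12000 (> 10000) is dropped too
  out <- prepare_cistrome(list(TFC = gr("chr1", c(1, 6001), c(6000, 12000))),
                          500)
  expect_length(out, 0L)
})

test_that("shades are length-matched flanks at distance D, clipped whole", {
  genome <- c(chr1 = 1e6)
  # domain [50000,52000) at D = 10 kb -> [38000,40000) and [62000,64000)
  dom <- gr("chr1", 50001, 52000)
  sh <- make_shades(dom, 10000, genome)
  expect_equal(start(sh), c(38001, 62001))
  expect_equal(end(sh), c(40000, 64000))
  expect_equal(width(sh), c(2000, 2000))
  # upstream shade would cross the chromosome start: only downstream kept
  dom <- gr("chr1", 5001, 7000)
  sh <- make_shades(dom, 10000, genome)
  expect_equal(length(sh), 1L)
  expect_equal(start(sh), 17001)
  # the downstream shade of domain 1 and the upstream shade of domain 2
  # both land on [120001,130000]: merged into one control region
  doms <- gr("chr1", c(100001, 140001), c(110000, 150000))
  sh <- make_shades(doms, 10000, genome)
  expect_equal(length(sh), 3L)
  expect_equal(sum(width(sh)), 30000)
  expect_error(make_shades(dom, 0, genome), "D must be")
})

test_that("shade coverage is at most twice domain coverage", {
  co <- simulate_cohort(small_cfg(), parts = "peaks")
  els <- lapply(co$peaks, call_regulatory_elements, genes = co$genes)
  dom <- build_domains(els, co$conditions)$SED
  for (D in c(1e4, 1e5)) {
    sh <- make_shades(dom, D, co$genome)
    expect_lte(sum(width(sh)), 2 * sum(width(dom)))
  }
  # far from chromosome ends with disjoint flanks, equality holds
  dom <- gr("chr1", c(1e5, 9e5), c(1e5 + 999, 9e5 + 1999))
  sh <- make_shades(dom, 1e4, c(chr1 = 2e6))
  expect_equal(sum(width(sh)), 2 * sum(width(dom)))
})

test_that("overlap_table counts regions once regardless of hit multiplicity", {
  test_r <- gr("chr1", c(1, 1001, 2001), c(500, 1500, 2500))
  ctl_r <- gr("chr1", c(5001, 6001), c(5500, 6500))
  tf <- gr("chr1", c(100, 1100), c(200, 1200))
  tab <- overlap_table(test_r, ctl_r, tf)
  expect_equal(unname(tab), c(2L, 1L, 0L, 2L))
  # empty TF catalog: a = c = 0 and the exact test is flat
  tab <- overlap_table(test_r, ctl_r, GRanges())
  expect_equal(unname(tab[c("a", "c")]), c(0L, 0L))
  ft <- fisher_exact_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
  expect_equal(ft$p_value, 1)
  # one region hit by two TF regions still counts once
  tf2 <- gr("chr1", c(1, 250), c(100, 400))
  tab <- overlap_table(test_r, ctl_r, tf2)
  expect_equal(unname(tab["a"]), 1L)
  expect_error(overlap_table(GRanges(), ctl_r, tf), "nonempty")
})

test_that("enrichment selects the worst case over distances", {
  co <- simulate_cohort(small_cfg(), parts = c("peaks", "cistrome"))
  els <- lapply(co$peaks, call_regulatory_elements, genes = co$genes)
  dom <- build_domains(els, co$conditions)$SED
  cis <- prepare_cistrome(co$cistrome, 10000)
  rec <- enrich_tfs(dom[mcols(dom)$specificity == "T"], cis, co$genome)
  # componentwise worst case: min OR, max p, possibly from different D
  expect_equal(rec$selected_or, pmin(rec$or_10000, rec$or_100000))
  expect_equal(rec$selected_p, pmax(rec$p_10000, rec$p_100000))
  expect_equal(rec$p_bonferroni, pmin(1, rec$selected_p * length(cis)))
  expect_true(all(rec$significant == (rec$p_bonferroni <= 0.05)))
  # a single tested TF gets no multiplicity penalty
  one <- enrich_tfs(dom[mcols(dom)$specificity == "T"], cis[1], co$genome)
  expect_equal(one$p_bonferroni, min(1, one$selected_p))
  expect_error(enrich_tfs(dom[0], cis, co$genome), "empty")
})

test_that("delta of log odds ratios behaves as a contrast", {
  rec <- data.frame(tf = "TFX", selected_or = exp(2))
  rec_n <- data.frame(tf = "TFX", selected_or = exp(1))
  expect_equal(delta_enrichment(rec, rec_n), 1)
  expect_equal(delta_enrichment(rec, rec), 0)
  expect_error(delta_enrichment(rec, NULL), "required")
  expect_error(delta_enrichment(rec,
                                data.frame(tf = "TFY", selected_or = 1)),
               "different TFs")
})

test_that("planted TFs come out tumor-leaning on the small cohort", {
  co <- simulate_cohort(small_cfg(n_sed_t = 30, n_sed_n = 30, n_sed_c = 4,
                                  n_chrom = 4, chrom_length = 1e8, n_genes = 500,
                                  n_jq1_reversed = 10),
                        parts = c("peaks", "cistrome"))
  els <- lapply(co$peaks, call_regulatory_elements, genes = co$genes)
  dom <- build_domains(els, co$conditions)$SED
  cis <- prepare_cistrome(co$cistrome, 10000)
  ct <- tf_domain_contrast(dom, cis, co$genome)
  m <- merge(ct, co$truth$tfs, by = "tf")
  expect_true(all(m$delta[m$enriched] > 0))
  expect_equal(colnames(ct)[1], "tf")
})
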