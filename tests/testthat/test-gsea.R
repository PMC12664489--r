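# Preranked enrichment: running-sum ES against a literal oracle and the
# reference implementation, permutation p behaviour, and hypergeometric
# over-representation.

test_that("read_gmt parses the packaged fixture", {
  sets <- read_gmt(system.file("extdata", "example_sets.gmt",
                               package = "sedomain"))
  expect_named(sets, c("setA", "setB", "setHuge"))
  expect_equal(sets$setA, sprintf("g%03d", 1:6))
  expect_length(sets$setHuge, 120L)
  tmp <- tempfile()
  writeLines("only_name\tdesc", tmp)
  expect_error(read_gmt(tmp), "line 1")
})

test_that("the unweighted ES of a top-1 set is 1 at the first position", {
  ranking <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  res <- preranked_gsea(ranking, list(top = "g1"), n_perm = 50, seed = 1,
                        weight = 0, min_size = 1, max_size = 4)
  expect_equal(res$es, 1.0)
  expect_equal(res$leading_edge, "g1")
})

test_that("sets outside the size bounds are excluded", {
  ranking <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  res <- preranked_gsea(ranking,
                        list(whole = names(ranking),
                             tiny = names(ranking)[1:2],
                             ok = names(ranking)[1:10]),
                        n_perm = 20, seed = 1, min_size = 5, max_size = 30)
  expect_equal(res$set_name, "ok")
})

test_that("the unweighted ES flips sign under ranking reversal", {
  set.seed(14)
  ranking <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  members <- sample(names(ranking), 15)
  a <- preranked_gsea(ranking, list(s = members), n_perm = 10, seed = 2,
                      weight = 0)
  # reverse the order; break rank ties identically by negating
  b <- preranked_gsea(-ranking, list(s = members), n_perm = 10, seed = 2,
                      weight = 0)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("ES agrees with a literal running-sum oracle and with fgsea", {
  set.seed(15)
  for (rep in 1:10) {
    N <- 200
    ranking <- setNames(rnorm(N), sprintf("g%03d", 1:N))
    members <- sample(names(ranking), sample(10:40, 1))
    for (w in c(0, 1)) {
      res <- preranked_gsea(ranking, list(s = members), n_perm = 5,
                            seed = 3, weight = w)
      o <- order(-ranking, names(ranking))
      es_ref <- oracle_es(ranking[o], names(ranking)[o] %in% members, w)
      expect_equal(res$es, es_ref, tolerance = 1e-12)
    }
  }
  skip_if_not_installed("fgsea")
  ranking <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  members <- sample(names(ranking), 30)
  res <- preranked_gsea(ranking, list(s = members), n_perm = 5, seed = 4,
                        weight = 1)
  stats_sorted <- sort(ranking, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(stats_sorted,
                             which(names(stats_sorted) %in% members),
                             gseaParam = 1)
  expect_equal(res$es, ref, tolerance = 1e-9)
})

test_that("a planted top set is called confidently, with FDR near zero", {
  set.seed(16)
  N <- 1000
  ranking <- setNames(rnorm(N), sprintf("g%04d", 1:N))
  top <- names(sort(ranking, decreasing = TRUE))[1:100]
  planted <- sample(top, 25)
  rand <- lapply(1:5, function(i) sample(names(ranking), 25))
  names(rand) <- paste0("r", 1:5)
  res <- preranked_gsea(ranking, c(list(planted = planted), rand),
                        n_perm = 500, seed = 5)
  row <- res[res$set_name == "planted", ]
  expect_gt(row$nes, 0)
  expect_lte(row$p_value, 0.01)
  expect_lte(row$fdr, 0.05)
})

test_that("hypergeom_enrich matches enumeration for small universes", {
  bg <- sprintf("g%02d", 1:20)
  terms <- list(t1 = bg[1:5], t2 = bg[3:10], tiny = bg[1:2])
  q <- bg[c(1:3, 6)]
  res <- hypergeom_enrich(q, terms, bg, min_size = 3)
  expect_false("tiny" %in% res$term)
  r1 <- res[res$term == "t1", ]
  expect_equal(r1$p_value,
               (choose(5, 3) * 15 + choose(5, 4)) / choose(20, 4),
               tolerance = 1e-12)
  # exhaustive enumeration over all draws of size n for N <= 25
  for (row_i in seq_len(nrow(res))) {
    K <- res$K[row_i]; n <- res$n[row_i]; k <- res$k[row_i]; N <- res$N[row_i]
    p_enum <- sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x), 0)) / choose(N, n)
    expect_equal(res$p_value[row_i], p_enum, tolerance = 1e-12)
  }
  # query = term is the extreme case among same-size terms
  res2 <- hypergeom_enrich(bg[1:5], list(self = bg[1:5], other = bg[6:10]),
                           bg, min_size = 3)
  expect_lt(res2$p_value[res2$term == "self"],
            res2$p_value[res2$term == "other"])
  expect_error(hypergeom_enrich(c(q, "nope"), terms, bg), "nope")
})
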