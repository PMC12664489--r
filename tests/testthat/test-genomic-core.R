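# Interval algebra and format I/O. BED-style 0-based half-open coordinates
# on disk map to 1-based closed GRanges in memory, so the half-open interval
# [s, e) appears as start = s + 1, end = e below.

test_that("merge_intervals unions overlaps and bridges gaps up to the limit", {
  # [0,10) + [5,15) with no gap bridging -> [0,15)
  m <- merge_intervals(gr("chr1", c(1, 6), c(10, 15)), 0)
  expect_equal(start(m), 1)
  expect_equal(end(m), 15)
  # [0,100) + [5000,5100): gap 4900 <= 10000 is bridged
  m <- merge_intervals(gr("chr1", c(1, 5001), c(100, 5100)), 10000)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(1, 5100))
  # same intervals stay apart at merge distance 0
  m <- merge_intervals(gr("chr1", c(1, 5001), c(100, 5100)), 0)
  expect_equal(length(m), 2L)
  expect_error(merge_intervals(gr("chr1", 1, 10), -1), "merge_distance")
})

test_that("merging is idempotent, matches brute force, never loses coverage", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    s <- sample.int(1e5, n, replace = TRUE)
    e <- s + sample.int(500, n, replace = TRUE)
    gap <- sample(c(0, 10, 300), 1)
    g <- gr("chr1", s, e)
    m <- merge_intervals(g, gap)
    # idempotent
    m2 <- merge_intervals(m, gap)
    expect_identical(as.data.frame(m), as.data.frame(m2))
    # equals O(n^2) transitive-closure merge
    ref <- oracle_merge(s, e, gap)
    expect_equal(start(m), ref[, 1])
    expect_equal(end(m), ref[, 2])
    # coverage never decreases
    expect_gte(sum(width(m)), sum(width(reduce(g))))
  }
})

test_that("distance_to_nearest finds nearest targets with smaller-coordinate ties", {
  r <- distance_to_nearest("chr1", 1000, c("chr1", "chr1"), c(500, 5000))
  expect_equal(r$distance, 500)
  expect_equal(r$target_idx, 1L)
  r <- distance_to_nearest("chr1", 500, "chr1", 500)
  expect_equal(r$distance, 0)
  # 3000 is equidistant from 1000 and 5000: the smaller coordinate wins
  r <- distance_to_nearest("chr1", 3000, c("chr1", "chr1"), c(1000, 5000))
  expect_equal(r$distance, 2000)
  expect_equal(r$target_idx, 1L)
  # query on a chromosome with no target is unassigned
  r <- distance_to_nearest(c("chr1", "chr2"), c(10, 10), "chr1", 100)
  expect_true(is.na(r$distance[2]))
  expect_error(distance_to_nearest("chr1", 1, character(0), numeric(0)),
               "empty")
})

test_that("distance_to_nearest matches an exhaustive scan", {
  set.seed(7)
  qc <- sample(c("chr1", "chr2"), 500, replace = TRUE)
  qp <- sample.int(1e6, 500)
  tc <- sample(c("chr1", "chr2"), 80, replace = TRUE)
  tp <- sample.int(1e6, 80)
  r <- distance_to_nearest(qc, qp, tc, tp)
  for (i in seq_len(500)) {
    d <- ifelse(tc == qc[i], abs(tp - qp[i]), Inf)
    expect_equal(r$distance[i], min(d))
    # among equidistant targets the smallest coordinate must be chosen
    cand <- which(d == min(d))
    expect_equal(tp[r$target_idx[i]], min(tp[cand]))
  }
})

test_that("BED I/O is a 0-based half-open round trip", {
  tmp <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tx\t5", tmp)
  g <- read_bed(tmp)
  expect_equal(start(g), 101)  # 0-based 100 -> 1-based 101
  expect_equal(end(g), 200)
  expect_equal(mcols(g)$score, 5)
  expect_equal(mcols(g)$name, "x")
  # write-then-read identity
  g3 <- gr("chr2", c(11, 51, 101), c(20, 70, 150),
           name = c("a", "b", "c"), score = c(1.5, 2, 3))
  write_bed(g3, tmp)
  back <- read_bed(tmp)
  expect_equal(as.data.frame(back), as.data.frame(g3))
})

test_that("malformed BED lines raise errors naming file and line", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10\tok", "chr1\tbroken"), tmp)
  expect_error(read_bed(tmp), "line 2")
  writeLines("chr1\t50\t40", tmp)
  expect_error(read_bed(tmp), "line 1")
  writeLines("chrUn\t1\t10", tmp)
  expect_error(read_bed(tmp, genome = c(chr1 = 1000)), "chrUn")
})

test_that("gene tables convert GTF 1-based and TSV 0-based TSS correctly", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t200\t.\t-\t.\tgene_id "gneg";',
    'chr1\tsrc\tgene\t501\t900\t.\t+\t.\tgene_id "gpos";'), gtf)
  genes <- read_gene_table(gtf)
  # minus-strand gene spanning 101..200 (1-based): TSS at 200 = 0-based 199
  expect_equal(genes$tss[genes$gene_id == "gneg"], 200)
  expect_equal(genes$tss[genes$gene_id == "gpos"], 501)
  # TSV dialect round trip (tss is 0-based on disk)
  tsv <- tempfile(fileext = ".tsv")
  write_gene_table(genes, tsv)
  back <- read_gene_table(tsv)
  expect_equal(back, genes)
  raw <- read.table(tsv, header = TRUE)
  expect_equal(raw$tss[raw$gene_id == "gneg"], 199)
})

test_that("count matrices and chromosome sizes round trip", {
  m <- matrix(rpois(12, 10), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  tmp <- tempfile(fileext = ".tsv")
  write_counts(m, tmp)
  expect_equal(read_counts(tmp), m)
  cs <- tempfile()
  writeLines(c("chr1\t1000", "chr2\t2000"), cs)
  expect_equal(read_chrom_sizes(cs), c(chr1 = 1000, chr2 = 2000))
  writeLines(c("chr1\t1000", "chr1\t500"), cs)
  expect_error(read_chrom_sizes(cs), "duplicate")
})
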