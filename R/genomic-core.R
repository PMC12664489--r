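#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths Seqinfo seqlevels
#' @importFrom stats p.adjust rnbinom rnorm runif setNames
#' @importFrom utils read.table write.table
NULL

# ---- genome table -----------------------------------------------------------

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom, length (no header).
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "length"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names in ", path)
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  setNames(as.numeric(df$length), df$chrom)
}

#' Validate a genome table (named vector of chromosome lengths)
#' @param genome Named numeric vector, chrom -> length.
#' @keywords internal
check_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome table must have unique chromosome names")
  if (any(genome <= 0)) stop("genome table lengths must be positive")
  invisible(genome)
}

#' Convert a genome table to a Seqinfo object
#' @inheritParams check_genome
#' @keywords internal
genome_seqinfo <- function(genome) {
  check_genome(genome)
  Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
}

# Ensure all intervals sit on known chromosomes and inside bounds.
check_intervals <- function(gr, genome = NULL) {
  if (any(width(gr) < 1L)) stop("intervals must have length >= 1")
  if (!is.null(genome)) {
    check_genome(genome)
    chr <- as.character(seqnames(gr))
    unknown <- setdiff(unique(chr), names(genome))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(start(gr) < 1L) || any(end(gr) > genome[chr]))
      stop("interval outside chromosome bounds")
  }
  invisible(gr)
}

# ---- interval algebra -------------------------------------------------------

#' Merge intervals, bridging gaps up to a given distance
#'
#' Collapses a set of genomic intervals into maximal runs in which consecutive
#' intervals are separated by at most `merge_distance` bp. With
#' `merge_distance = 0` only strictly overlapping or book-ended intervals are
#' joined, i.e. the plain union of covered bases.
#'
#' @param gr A `GRanges`.
#' @param merge_distance Maximum gap (bp, >= 0) bridged between neighbours.
#' @return A sorted `GRanges` whose elements are pairwise separated by gaps
#'   strictly greater than `merge_distance`.
#' @export
merge_intervals <- function(gr, merge_distance = 0) {
  stopifnot(is(gr, "GRanges"))
  if (!is.numeric(merge_distance) || length(merge_distance) != 1L ||
      is.na(merge_distance) || merge_distance < 0)
    stop("merge_distance must be a single number >= 0")
  GenomicRanges::reduce(sort(gr), min.gapwidth = merge_distance + 1,
                        ignore.strand = TRUE)
}

#' Distance from query points to the nearest target point
#'
#' For each query position, finds the nearest target position on the same
#' chromosome. Ties at equal distance are broken deterministically toward the
#' target with the smaller coordinate. Queries on chromosomes with no target
#' get `NA` distance and index.
#'
#' @param query_chrom,query_pos Character/numeric vectors of query positions.
#' @param target_chrom,target_pos Character/numeric vectors of target
#'   positions; must be nonempty.
#' @return A data.frame with columns `distance` and `target_idx` (index into
#'   the target vectors), one row per query.
#' @export
distance_to_nearest <- function(query_chrom, query_pos,
                                target_chrom, target_pos) {
  if (length(target_pos) == 0L) stop("target set is empty")
  stopifnot(length(query_chrom) == length(query_pos),
            length(target_chrom) == length(target_pos))
  n <- length(query_pos)
  out_d <- rep(NA_real_, n)
  out_i <- rep(NA_integer_, n)
  for (chr in unique(query_chrom)) {
    qi <- which(query_chrom == chr)
    ti <- which(target_chrom == chr)
    if (length(ti) == 0L) next
    # sort targets by coordinate so that on ties the smaller coordinate wins
    o <- order(target_pos[ti])
    tp <- target_pos[ti][o]
    tidx <- ti[o]
    qp <- query_pos[qi]
    # index of rightmost target <= query
    lo <- findInterval(qp, tp)
    hi <- pmin(lo + 1L, length(tp))
    lo <- pmax(lo, 1L)
    d_lo <- abs(qp - tp[lo])
    d_hi <- abs(qp - tp[hi])
    # smaller coordinate (lo) wins ties
    use_lo <- d_lo <= d_hi
    out_d[qi] <- ifelse(use_lo, d_lo, d_hi)
    out_i[qi] <- ifelse(use_lo, tidx[lo], tidx[hi])
  }
  data.frame(distance = out_d, target_idx = out_i)
}

# ---- BED I/O ----------------------------------------------------------------

#' Read a BED3/BED5/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk and converted to the 1-based
#' closed convention of `GRanges` in memory; `write_bed()` inverts the
#' conversion, so write-then-read is the identity.
#'
#' @param path BED file, tab-separated, no header.
#' @param genome Optional genome table; when given, chromosomes are checked.
#' @return `GRanges` with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GRanges(seqinfo = if (!is.null(genome)) genome_seqinfo(genome)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line in ", path, " at line ", bad[1L],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s < 0 | e <= s)
  if (length(bad))
    stop("malformed BED line in ", path, " at line ", bad[1L],
         ": invalid start/end")
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    mcols(gr)$score <- sc
  }
  if (all(nf >= 6L)) strand(gr) <- vapply(fields, `[[`, "", 6L)
  check_intervals(gr, genome)
  gr
}

#' Write a GRanges to BED (0-based half-open)
#' @param gr `GRanges`; `name` and `score` metadata columns are written when
#'   present.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  has_score <- "score" %in% names(mcols(gr))
  if ("name" %in% names(mcols(gr)) || has_score)
    df$name <- if ("name" %in% names(mcols(gr))) mcols(gr)$name else "."
  if (has_score) df$score <- mcols(gr)$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- gene and count tables --------------------------------------------------

#' Read a gene table (4-column TSV or GTF)
#'
#' The TSV dialect has a header `gene_id, chrom, strand, tss` with `tss` as a
#' 0-based position, matching the BED convention; it is converted to 1-based
#' in memory. GTF input (detected by extension `.gtf` or by `feature` columns)
#' is 1-based inclusive: the TSS of a `gene` record is its `start` on the
#' plus strand and its `end` on the minus strand.
#'
#' @param path Gene table path.
#' @param genome Optional genome table used to bound-check TSS positions.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss` (1-based).
#' @export
read_gene_table <- function(path, genome = NULL) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                     comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 9L) stop("malformed GTF in ", path, ": fewer than 9 columns")
    df <- df[df[[3L]] == "gene", , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9L]])
    genes <- data.frame(gene_id = gid,
                        chrom = df[[1L]],
                        strand = df[[7L]],
                        tss = ifelse(df[[7L]] == "-", df[[5L]], df[[4L]]),
                        stringsAsFactors = FALSE)
  } else {
    genes <- read.table(path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(genes)))
      stop("gene table ", path, " must have columns ",
           paste(need, collapse = ", "))
    genes <- genes[, need]
    genes$tss <- genes$tss + 1  # 0-based on disk -> 1-based in memory
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in ", path)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be + or - in ", path)
  if (!is.null(genome)) {
    check_genome(genome)
    unknown <- setdiff(unique(genes$chrom), names(genome))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(genes$tss < 1 | genes$tss > genome[genes$chrom]))
      stop("TSS outside chromosome bounds in ", path)
  }
  genes
}

#' Write a gene table in the 4-column TSV dialect (0-based tss on disk)
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[, c("gene_id", "chrom", "strand", "tss")]
  out$tss <- format(out$tss - 1, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#' @param path TSV with a header row of sample names and feature ids in the
#'   first column.
#' @return Integer-valued numeric matrix, features in rows.
#' @export
read_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  m
}

#' Write a count matrix to TSV
#' @param counts Feature-by-sample matrix with row and column names.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
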