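# Synthetic cohort generator. Emulates the statistical structure of a
# tumor/normal H3K27ac + RNA-seq study: per-sample peak sets with a
# heavy-tailed enhancer-score distribution and a planted super-enhancer
# tail, tumor-/normal-specific/common domains, per-TF binding regions with
# planted density enrichment inside tumor-specific SEDs, negative-binomial
# mRNA counts whose tumor/normal log2 fold changes decay linearly with
# distance to the nearest tumor-specific SED (reversed under a simulated
# BET-inhibition condition for a designated gene subset), and eRNA counts
# whose fold changes are positively coupled to proximal mRNA fold changes.

.BLOCK_BP <- 5e6  # one planted SED per 5 Mb genome block

#' Configuration of the synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: a
#' human-scale genome (8 x 220 Mb), 340 planted super-enhancer domains
#' (150 tumor-specific, 150 normal-specific, 40 common), 2 + 2 ChIP samples,
#' a 12 vs 12 RNA cohort, two cell lines with 5 + 5 treated/control
#' replicates, and 40 TFs of which 5 carry a 3x binding-density enrichment
#' inside tumor-specific SEDs.
#'
#' @param seed RNG seed (default 17, the packaged fixture seed).
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes Total genes; planted SED-proximal genes come first, the
#'   remainder are placed uniformly away from SED centers.
#' @param n_samples_tumor,n_samples_normal ChIP-seq peak samples.
#' @param n_rna_tumor,n_rna_normal RNA cohort sizes.
#' @param n_cell_lines,n_rep_jq1 Perturbation arm: cell lines and
#'   replicates per condition (treated vs control).
#' @param n_tfs,n_enriched_tfs,tf_density_fold,tf_regions_per_tf Cistrome
#'   shape and the planted binding enrichment.
#' @param n_sed_t,n_sed_n,n_sed_c Planted SED counts by specificity.
#' @param effect_lfc Peak mRNA log2FC at distance 0 from a planted SED.
#' @param decay_range_bp Distance at which the planted effect reaches 0
#'   (default 1 Mb; must be <= 2 Mb).
#' @param nb_dispersion,nb_dispersion_cell NB dispersion for the cohort and
#'   the (cleaner) cell lines.
#' @param mean_expression Median of the lognormal gene base-mean
#'   distribution.
#' @param erna_coupling Correlation strength (0..1) between eRNA and
#'   proximal mRNA log2 fold changes.
#' @param jq1_reversal_fraction Fraction (0..1) by which the planted tumor
#'   effect is reversed under treatment for the designated sensitive genes.
#' @param n_jq1_reversed Number of designated SE-driven, treatment-reversed
#'   genes (placed close to distinct tumor-specific SEDs).
#' @param n_jq1_background Genes with an SE-independent treatment response
#'   (shared across cell lines), emulating the broad transcriptional effect
#'   of BET inhibition.
#' @param n_bg_enhancers Background enhancer peaks per ChIP sample.
#' @param genes_per_sed Planted genes per T/N SED block.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 17,
                       n_chrom = 8, chrom_length = 2.2e8,
                       n_genes = 2000,
                       n_samples_tumor = 2, n_samples_normal = 2,
                       n_rna_tumor = 12, n_rna_normal = 12,
                       n_cell_lines = 2, n_rep_jq1 = 5,
                       n_tfs = 40, n_enriched_tfs = 5,
                       tf_density_fold = 3, tf_regions_per_tf = 24000,
                       n_sed_t = 150, n_sed_n = 150, n_sed_c = 40,
                       effect_lfc = 2, decay_range_bp = 1e6,
                       nb_dispersion = 0.1, nb_dispersion_cell = 0.02,
                       mean_expression = 100,
                       erna_coupling = 0.8,
                       jq1_reversal_fraction = 0.8,
                       n_jq1_reversed = 50,
                       n_jq1_background = 300,
                       n_bg_enhancers = 3000,
                       genes_per_sed = 4) {
  cfg <- as.list(environment())
  counts <- c("n_chrom", "n_genes", "n_samples_tumor", "n_samples_normal",
              "n_rna_tumor", "n_rna_normal", "n_cell_lines", "n_rep_jq1",
              "n_tfs", "n_enriched_tfs", "tf_regions_per_tf",
              "n_sed_t", "n_sed_n", "n_sed_c", "n_jq1_reversed",
              "n_jq1_background", "n_bg_enhancers", "genes_per_sed")
  for (nm in counts)
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (jq1_reversal_fraction < 0 || jq1_reversal_fraction > 1)
    stop("jq1_reversal_fraction must lie in [0, 1]")
  if (erna_coupling < 0 || erna_coupling > 1)
    stop("erna_coupling must lie in [0, 1]")
  if (decay_range_bp <= 0 || decay_range_bp > 2e6)
    stop("decay_range_bp must lie in (0, 2e6]")
  if (n_enriched_tfs > n_tfs) stop("n_enriched_tfs cannot exceed n_tfs")
  if (n_jq1_reversed > n_sed_t)
    stop("n_jq1_reversed cannot exceed n_sed_t")
  slots <- n_chrom * floor(chrom_length / .BLOCK_BP)
  if (n_sed_t + n_sed_n + n_sed_c > slots)
    stop("genome too small for the requested number of planted SEDs")
  structure(cfg, class = "sim_config")
}

# block k (1-based) -> (chrom index, center position)
.block_layout <- function(cfg, k) {
  per_chrom <- floor(cfg$chrom_length / .BLOCK_BP)
  list(chrom = as.integer((k - 1) %/% per_chrom) + 1L,
       center = ((k - 1) %% per_chrom) * .BLOCK_BP + .BLOCK_BP / 2)
}

# uniform positions at least `margin` bp away from every planted SED center
.sample_background_pos <- function(n, cfg, n_blocks, margin = 6e4) {
  per_chrom <- floor(cfg$chrom_length / .BLOCK_BP)
  chrom <- integer(0); pos <- numeric(0)
  while (length(pos) < n) {
    m <- (n - length(pos)) * 2 + 10
    ch <- sample.int(cfg$n_chrom, m, replace = TRUE)
    p <- runif(m, 1, cfg$chrom_length)
    slot <- floor(p / .BLOCK_BP)
    block_id <- (ch - 1L) * per_chrom + slot + 1
    center <- slot * .BLOCK_BP + .BLOCK_BP / 2
    ok <- slot >= per_chrom | block_id > n_blocks |
      abs(p - center) >= margin
    chrom <- c(chrom, ch[ok]); pos <- c(pos, p[ok])
  }
  list(chrom = chrom[seq_len(n)], pos = pos[seq_len(n)])
}

#' Generate a complete synthetic cohort
#'
#' All randomness derives from `config$seed`; the same configuration yields
#' byte-identical output. Truth tables record every planted SED, enriched
#' TF, affected gene and designated treatment-sensitive gene.
#'
#' @param config A [sim_config()].
#' @param parts Which data layers to generate (`"peaks"`, `"cistrome"`,
#'   `"mrna"`, `"jq1"`, `"erna"`); the genome, gene and SED truth layers are
#'   always generated. Layers are drawn in a fixed order, so two cohorts
#'   agree on a layer only if they also share all earlier layers.
#' @return List with `config`, `genome` (named lengths), `genes`,
#'   `sample_sheet`, `peaks` (per-sample `GRanges`), `cistrome`,
#'   `counts` (mRNA, eRNA, per-line treatment matrices with label vectors)
#'   and `truth` (`sed`, `genes`, `tfs` data.frames).
#' @export
simulate_cohort <- function(config,
                            parts = c("peaks", "cistrome", "mrna",
                                      "jq1", "erna")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  genome <- setNames(rep(cfg$chrom_length, cfg$n_chrom),
                     paste0("chr", seq_len(cfg$n_chrom)))

  ## ---- planted SED truth ----------------------------------------------
  n_blocks <- cfg$n_sed_t + cfg$n_sed_n + cfg$n_sed_c
  spec <- sample(c(rep("T", cfg$n_sed_t), rep("N", cfg$n_sed_n),
                   rep("C", cfg$n_sed_c)))
  layout <- lapply(seq_len(n_blocks), .block_layout, cfg = cfg)
  sed_truth <- data.frame(
    sed_id = sprintf("sed_%04d", seq_len(n_blocks)),
    chrom = paste0("chr", vapply(layout, `[[`, 0L, "chrom")),
    center = vapply(layout, `[[`, 0, "center"),
    width = round(runif(n_blocks, 25e3, 45e3)),
    specificity = spec,
    stringsAsFactors = FALSE)
  sed_truth$start <- round(sed_truth$center - sed_truth$width / 2)
  sed_truth$end <- sed_truth$start + sed_truth$width

  ## ---- genes ------------------------------------------------------------
  tn_blocks <- which(sed_truth$specificity %in% c("T", "N"))
  c_blocks <- which(sed_truth$specificity == "C")
  mk_block_genes <- function(blocks, per_block, d_min, d_max) {
    if (length(blocks) == 0L || per_block == 0L)
      return(data.frame(block = integer(0), d = numeric(0)))
    b <- rep(blocks, each = per_block)
    data.frame(block = b,
               d = runif(length(b), d_min, d_max) *
                 sample(c(-1, 1), length(b), replace = TRUE))
  }
  planted <- mk_block_genes(tn_blocks, cfg$genes_per_sed, 3e4, 1.97e6)
  planted_c <- mk_block_genes(c_blocks, 2L, 3e4, 1.97e6)
  # designated treatment-sensitive genes sit close to distinct T-SEDs
  t_blocks <- which(sed_truth$specificity == "T")
  core_blocks <- sort(sample(t_blocks, cfg$n_jq1_reversed))
  core <- mk_block_genes(core_blocks, 1L, 3e4, 2e5)
  blockg <- rbind(planted, planted_c, core)
  blockg$jq1_reversed <- rep(c(FALSE, FALSE, TRUE),
                             c(nrow(planted), nrow(planted_c), nrow(core)))
  n_bg_genes <- max(0L, cfg$n_genes - nrow(blockg))
  bg <- .sample_background_pos(n_bg_genes, cfg, n_blocks)
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(nrow(blockg) + n_bg_genes)),
    chrom = c(sed_truth$chrom[blockg$block], paste0("chr", bg$chrom)),
    strand = sample(c("+", "-"), nrow(blockg) + n_bg_genes, replace = TRUE),
    tss = round(c(sed_truth$center[blockg$block] + blockg$d, bg$pos)),
    stringsAsFactors = FALSE)
  genes$tss <- pmin(pmax(genes$tss, 1), cfg$chrom_length)
  # every gene's planted tumor/normal effect follows its distance to the
  # nearest planted SED center, whatever its placement
  nn <- distance_to_nearest(genes$chrom, genes$tss,
                            sed_truth$chrom, sed_truth$center)
  gene_truth <- data.frame(
    gene_id = genes$gene_id,
    sed_id = sed_truth$sed_id[nn$target_idx],
    sed_specificity = sed_truth$specificity[nn$target_idx],
    distance = nn$distance,
    jq1_reversed = c(blockg$jq1_reversed, rep(FALSE, n_bg_genes)),
    stringsAsFactors = FALSE)
  decay <- function(d) pmax(0, 1 - d / cfg$decay_range_bp)
  sgn <- ifelse(gene_truth$sed_specificity == "T", 1,
                ifelse(gene_truth$sed_specificity == "N", -1, 0))
  gene_truth$lfc_true <- sgn * cfg$effect_lfc * decay(gene_truth$distance)
  gene_truth$jq1_lfc_true <- ifelse(gene_truth$jq1_reversed,
                                    -cfg$jq1_reversal_fraction *
                                      gene_truth$lfc_true, 0)
  # SE-independent treatment response, shared across cell lines, confined
  # to genes outside the planted distance-decay footprint
  eligible <- which(gene_truth$lfc_true == 0 & !gene_truth$jq1_reversed)
  n_jbg <- min(cfg$n_jq1_background, length(eligible))
  jbg <- sample(eligible, n_jbg)
  gene_truth$jq1_lfc_true[jbg] <- rnorm(n_jbg, 0, 1.5)

  ## ---- sample sheet ------------------------------------------------------
  sample_sheet <- data.frame(
    sample_id = c(paste0("tumor", seq_len(cfg$n_samples_tumor)),
                  paste0("normal", seq_len(cfg$n_samples_normal))),
    condition = rep(c("tumor", "normal"),
                    c(cfg$n_samples_tumor, cfg$n_samples_normal)),
    stringsAsFactors = FALSE)
  conditions <- setNames(sample_sheet$condition, sample_sheet$sample_id)

  ## ---- peaks -------------------------------------------------------------
  peaks <- NULL
  if ("peaks" %in% parts) {
    peaks <- lapply(seq_len(nrow(sample_sheet)), function(i) {
      sid <- sample_sheet$sample_id[i]
      cond <- sample_sheet$condition[i]
      want <- sed_truth$specificity == "C" |
        (cond == "tumor" & sed_truth$specificity == "T") |
        (cond == "normal" & sed_truth$specificity == "N")
      se <- sed_truth[want, , drop = FALSE]
      se_center <- se$center + round(runif(nrow(se), -2e3, 2e3))
      se_w <- round(se$width * runif(nrow(se), 0.9, 1.1))
      se_gr <- GRanges(se$chrom,
                       IRanges(start = pmax(1, se_center - se_w %/% 2),
                               width = se_w))
      mcols(se_gr)$signal <- runif(nrow(se), 8, 12)
      prom_idx <- which(runif(nrow(genes)) < 0.7)
      pw <- round(runif(length(prom_idx), 1500, 2500))
      pstart <- pmax(1, genes$tss[prom_idx] - pw %/% 2 +
                       round(runif(length(prom_idx), -300, 300)))
      prom_gr <- GRanges(genes$chrom[prom_idx], IRanges(pstart, width = pw))
      mcols(prom_gr)$signal <- runif(length(prom_idx), 1, 3)
      bgp <- .sample_background_pos(cfg$n_bg_enhancers, cfg, n_blocks)
      bw <- round(runif(cfg$n_bg_enhancers, 1000, 3000))
      bg_gr <- GRanges(paste0("chr", bgp$chrom),
                       IRanges(pmax(1, round(bgp$pos) - bw %/% 2),
                               width = bw))
      mcols(bg_gr)$signal <- rlnorm(cfg$n_bg_enhancers, 0, 0.5)
      gr <- c(se_gr, prom_gr, bg_gr)
      end(gr) <- pmin(end(gr), cfg$chrom_length)
      mcols(gr)$sample_id <- sid
      sort(gr)
    })
    names(peaks) <- sample_sheet$sample_id
  }

  ## ---- cistrome ----------------------------------------------------------
  cistrome <- NULL
  tf_truth <- NULL
  if ("cistrome" %in% parts && cfg$n_tfs > 0) {
    tf_names <- sprintf("TF%03d", seq_len(cfg$n_tfs))
    enriched <- seq_len(cfg$n_enriched_tfs)
    tsed <- sed_truth[sed_truth$specificity == "T", , drop = FALSE]
    tsed_len <- sum(tsed$width)
    genome_len <- cfg$n_chrom * cfg$chrom_length
    cistrome <- lapply(seq_len(cfg$n_tfs), function(i) {
      # short motif-supported binding regions, log-uniform in [50, 2000] bp
      len <- round(exp(runif(cfg$tf_regions_per_tf, log(50), log(2000))))
      ch <- sample.int(cfg$n_chrom, cfg$tf_regions_per_tf, replace = TRUE)
      st <- round(runif(cfg$tf_regions_per_tf, 1, cfg$chrom_length - len))
      gr <- GRanges(paste0("chr", ch), IRanges(st, width = len))
      if (i %in% enriched && nrow(tsed) > 0) {
        # extra regions dropped uniformly into T-SED footprints so that the
        # per-bp density of region centers inside T-SEDs is ~fold x background
        n_extra <- round((cfg$tf_density_fold - 1) * cfg$tf_regions_per_tf *
                           tsed_len / genome_len)
        w <- sample.int(nrow(tsed), n_extra, replace = TRUE,
                        prob = tsed$width)
        elen <- round(exp(runif(n_extra, log(50), log(2000))))
        ctr <- round(runif(n_extra, tsed$start[w], tsed$end[w]))
        egr <- GRanges(tsed$chrom[w],
                       IRanges(pmax(1, ctr - elen %/% 2), width = elen))
        end(egr) <- pmin(end(egr), cfg$chrom_length)
        gr <- c(gr, egr)
      }
      sort(gr)
    })
    names(cistrome) <- tf_names
    tf_truth <- data.frame(tf = tf_names,
                           enriched = seq_len(cfg$n_tfs) %in% enriched,
                           stringsAsFactors = FALSE)
  }

  ## ---- mRNA counts -------------------------------------------------------
  counts <- list()
  base_mean <- rlnorm(nrow(genes), log(cfg$mean_expression), 1)
  # SE-driven core genes are strongly expressed, like real SE target genes
  base_mean[gene_truth$jq1_reversed] <-
    rlnorm(sum(gene_truth$jq1_reversed), log(4 * cfg$mean_expression), 0.5)
  if ("mrna" %in% parts) {
    nT <- cfg$n_rna_tumor; nN <- cfg$n_rna_normal
    libf <- runif(nT + nN, 0.7, 1.3)
    mu_t <- base_mean * 2^(gene_truth$lfc_true / 2)
    mu_n <- base_mean * 2^(-gene_truth$lfc_true / 2)
    mu <- cbind(matrix(rep(mu_t, nT), ncol = nT),
                matrix(rep(mu_n, nN), ncol = nN))
    mu <- sweep(mu, 2L, libf, "*")
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                nrow = nrow(genes))
    rownames(m) <- genes$gene_id
    colnames(m) <- c(sprintf("T%02d", seq_len(nT)),
                     sprintf("N%02d", seq_len(nN)))
    counts$mrna <- m
    counts$mrna_labels <- rep(c("tumor", "normal"), c(nT, nN))
  }

  ## ---- treatment-arm counts ---------------------------------------------
  if ("jq1" %in% parts && cfg$n_cell_lines > 0) {
    counts$jq1 <- vector("list", cfg$n_cell_lines)
    names(counts$jq1) <- paste0("line", seq_len(cfg$n_cell_lines))
    for (ln in seq_len(cfg$n_cell_lines)) {
      nr <- cfg$n_rep_jq1
      libf <- runif(2 * nr, 0.7, 1.3)
      mu_trt <- base_mean * 2^(gene_truth$jq1_lfc_true / 2)
      mu_ctl <- base_mean * 2^(-gene_truth$jq1_lfc_true / 2)
      mu <- cbind(matrix(rep(mu_trt, nr), ncol = nr),
                  matrix(rep(mu_ctl, nr), ncol = nr))
      mu <- sweep(mu, 2L, libf, "*")
      m <- matrix(rnbinom(length(mu), mu = mu,
                          size = 1 / cfg$nb_dispersion_cell),
                  nrow = nrow(genes))
      rownames(m) <- genes$gene_id
      colnames(m) <- c(sprintf("line%d_JQ1_%d", ln, seq_len(nr)),
                       sprintf("line%d_DMSO_%d", ln, seq_len(nr)))
      counts$jq1[[ln]] <- list(counts = m,
                               labels = rep(c("JQ1", "DMSO"), c(nr, nr)))
    }
  }

  ## ---- eRNA counts -------------------------------------------------------
  if ("erna" %in% parts) {
    s_sig <- ifelse(sed_truth$specificity == "T", 1,
                    ifelse(sed_truth$specificity == "N", -1, 0)) *
      cfg$effect_lfc
    eps <- rnorm(n_blocks, 0, cfg$effect_lfc)
    rho <- cfg$erna_coupling
    erna_lfc <- rho * s_sig + sqrt(1 - rho^2) * eps
    sed_truth$erna_lfc_true <- erna_lfc
    base_e <- rlnorm(n_blocks, log(50), 0.8)
    nT <- cfg$n_rna_tumor; nN <- cfg$n_rna_normal
    libf <- runif(nT + nN, 0.7, 1.3)
    mu_t <- base_e * 2^(erna_lfc / 2)
    mu_n <- base_e * 2^(-erna_lfc / 2)
    mu <- cbind(matrix(rep(mu_t, nT), ncol = nT),
                matrix(rep(mu_n, nN), ncol = nN))
    mu <- sweep(mu, 2L, libf, "*")
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                nrow = n_blocks)
    rownames(m) <- sed_truth$sed_id
    colnames(m) <- c(sprintf("T%02d", seq_len(nT)),
                     sprintf("N%02d", seq_len(nN)))
    counts$erna <- m
    counts$erna_labels <- rep(c("tumor", "normal"), c(nT, nN))
  }

  list(config = cfg,
       genome = genome,
       genes = genes,
       sample_sheet = sample_sheet,
       conditions = conditions,
       peaks = peaks,
       cistrome = cistrome,
       counts = counts,
       truth = list(sed = sed_truth, genes = gene_truth, tfs = tf_truth))
}

#' Generate a null cistrome with no planted enrichment
#'
#' Regions are placed uniformly over the genome with lengths drawn from
#' \[50, 10000\] bp, the same generator path as the background component of
#' [simulate_cohort()]; used as a type-I-error harness.
#'
#' @param config A [sim_config()]; `n_tfs` and `tf_regions_per_tf` shape the
#'   catalog.
#' @return Named list of `GRanges`, one per TF (empty list for 0 TFs).
#' @export
simulate_null_tf_regions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_tfs == 0L) return(setNames(list(), character(0)))
  out <- lapply(seq_len(cfg$n_tfs), function(i) {
    len <- round(exp(runif(cfg$tf_regions_per_tf, log(50), log(2000))))
    ch <- sample.int(cfg$n_chrom, cfg$tf_regions_per_tf, replace = TRUE)
    st <- round(runif(cfg$tf_regions_per_tf, 1, cfg$chrom_length - len))
    sort(GRanges(paste0("chr", ch), IRanges(st, width = len)))
  })
  names(out) <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  out
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits chromosome sizes, the gene table, per-sample peak BEDs with the
#' signal in the score column, a sample sheet, per-TF cistrome BEDs, count
#' TSVs, and truth-table TSVs.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return Invisible character vector of written paths.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  write.table(data.frame(names(cohort$genome), cohort$genome),
              w(file.path(outdir, "chrom.sizes")), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gene_table(cohort$genes, w(file.path(outdir, "genes.tsv")))
  write.table(cohort$sample_sheet, w(file.path(outdir, "samples.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$peaks)) {
    for (sid in names(cohort$peaks)) {
      gr <- cohort$peaks[[sid]]
      mcols(gr)$name <- sprintf("%s_peak_%05d", sid, seq_along(gr))
      mcols(gr)$score <- mcols(gr)$signal
      write_bed(gr, w(file.path(outdir, paste0("peaks_", sid, ".bed"))))
    }
  }
  if (!is.null(cohort$cistrome)) {
    cdir <- file.path(outdir, "cistrome")
    dir.create(cdir, showWarnings = FALSE)
    for (tf in names(cohort$cistrome))
      write_bed(cohort$cistrome[[tf]], w(file.path(cdir, paste0(tf, ".bed"))))
  }
  if (!is.null(cohort$counts$mrna))
    write_counts(cohort$counts$mrna, w(file.path(outdir, "mrna_counts.tsv")))
  if (!is.null(cohort$counts$erna))
    write_counts(cohort$counts$erna, w(file.path(outdir, "erna_counts.tsv")))
  if (!is.null(cohort$counts$jq1)) {
    for (ln in names(cohort$counts$jq1))
      write_counts(cohort$counts$jq1[[ln]]$counts,
                   w(file.path(outdir, paste0("jq1_counts_", ln, ".tsv"))))
  }
  for (nm in names(cohort$truth)) {
    if (is.null(cohort$truth[[nm]])) next
    write.table(cohort$truth[[nm]],
                w(file.path(outdir, paste0("truth_", nm, ".tsv"))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' @importFrom stats rlnorm
NULL
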