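# Synthetic multi-histology cohort generator.  Everything downstream of
# alignment/peak calling is emulated on a small genome (chr1-3 carry the
# enhancer peak universe, SNPs and GWAS catalog; chr4 carries TF and decoy
# gene loci for the super-enhancer / clique analyses) with planted,
# recoverable ground truth.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# beta-binomial draws under the (pi, rho) mean/correlation parameterization
.rbetabin <- function(n, size, pi, rho) {
  stopifnot(pi > 0, pi < 1, rho >= 0, rho < 1)
  if (rho == 0) return(rbinom(n, size, pi))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  p <- rbeta(n, a, b)
  rbinom(n, size, p)
}

#' Draw beta-binomial read counts
#'
#' Samples alternate-allele read counts from the beta-binomial
#' distribution parameterized by the mean allelic ratio `pi` and the
#' overdispersion (intra-class correlation) `rho`, i.e. shape parameters
#' `alpha = pi (1 - rho) / rho` and `beta = (1 - pi)(1 - rho) / rho`.
#' `rho = 0` degenerates to the binomial.
#'
#' @param k_trials Number of trials (total reads) per draw; scalar or
#'   vector of length `n_draws`.
#' @param pi Mean allelic ratio in (0, 1).
#' @param rho Overdispersion in [0, 1).
#' @param n_draws Number of draws.
#' @param seed Optional seed; when given, the draws are deterministic and
#'   the caller's RNG state is untouched.
#' @return Integer vector of `n_draws` alternate read counts.
#' @export
simulateBetaBin <- function(k_trials, pi, rho, n_draws, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  draw <- function() .rbetabin(n_draws, k_trials, pi, rho)
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

.simGenome <- function() {
  c(chr1 = 10000000L, chr2 = 10000000L, chr3 = 10000000L, chr4 = 30000000L)
}

# linear slot layout over chr1-3 for the peak universe
.simPeakUniverse <- function(cfg) {
  n <- cfg@n_peaks
  chroms <- paste0("chr", 1:3)
  per_chr <- c(n %/% 3L, n %/% 3L, n - 2L * (n %/% 3L))
  gr <- GenomicRanges::GRanges()
  for (i in 1:3) {
    slot <- 10000000L %/% per_chr[i]
    width <- round(runif(per_chr[i], 500, 1500))
    width <- pmin(width, slot - 200L)
    start0 <- (seq_len(per_chr[i]) - 1L) * slot +
      round(runif(per_chr[i], 50, pmax(51, slot - width - 50)))
    gr <- suppressWarnings(
      c(gr, GenomicRanges::GRanges(chroms[i],
            IRanges::IRanges(start = start0 + 1L, width = width))))
  }
  names(gr) <- sprintf("peak_%05d", seq_len(n))
  gr
}

.simCounts <- function(cfg, universe, labels, specific) {
  n <- length(universe)
  samples <- names(labels)
  base <- rlnorm(n, meanlog = log(150), sdlog = 0.5)
  sf <- runif(length(samples), 0.7, 1.3)
  mu <- outer(base, sf)
  for (h in c("ccRCC", "pRCC", "chRCC")) {
    idx <- which(specific == h)
    mu[idx, labels == h] <- mu[idx, labels == h] * 2^cfg@log2fc_planted
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg@nb_dispersion),
                   nrow = n, dimnames = list(names(universe), samples))
  libsizes <- round(sf * 2e7)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = universe,
    colData = S4Vectors::DataFrame(histology = unname(labels),
                                   libsize = libsizes,
                                   row.names = samples))
}

.simPerSamplePeaks <- function(universe, labels, specific) {
  lapply(names(labels), function(s) {
    keep <- specific == "common" | specific == labels[[s]]
    g <- universe[keep]
    jit <- round(runif(length(g), -50, 50))
    GenomicRanges::start(g) <- pmax(1L, GenomicRanges::start(g) + jit)
    GenomicRanges::end(g) <- GenomicRanges::end(g) +
      round(runif(length(g), -50, 50))
    g$score <- rgamma(length(g), shape = 2, scale = 20) + 2
    sort(g)
  }) |> setNames(names(labels))
}

.simExpression <- function(cfg, labels, tfs, master_of) {
  samples <- names(labels)
  base <- rlnorm(length(tfs), meanlog = log(8), sdlog = 0.8)
  fpkm <- matrix(0, length(tfs), length(samples),
                 dimnames = list(tfs, samples))
  for (j in seq_along(samples)) {
    mu <- base
    mh <- !is.na(master_of)
    mu[mh] <- ifelse(master_of[mh] == labels[[j]], 60, 2)
    fpkm[, j] <- mu * rlnorm(length(tfs), 0, 0.35)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(histology = unname(labels),
                                   row.names = samples))
}

.simPanCancer <- function(tfs, master_of) {
  types <- c("ccRCC", "pRCC", "chRCC", paste0("TCGA_", sprintf("%02d", 1:10)))
  base <- rlnorm(length(tfs), meanlog = log(8), sdlog = 0.8)
  m <- matrix(rep(base, length(types)), nrow = length(tfs),
              dimnames = list(tfs, types)) *
    matrix(rlnorm(length(tfs) * length(types), 0, 0.15),
           nrow = length(tfs))
  mh <- which(!is.na(master_of))
  for (i in mh) {
    m[i, ] <- 1 * rlnorm(length(types), 0, 0.1)
    m[i, master_of[i]] <- 60 * rlnorm(1, 0, 0.1)
  }
  m
}

# gene layout on chr4: TF loci, decoy strong-enhancer genes
.simTss <- function(tfs, n_decoys = 40L) {
  genes <- c(tfs, sprintf("GENE_%03d", seq_len(n_decoys)))
  pos <- 50000L + (seq_along(genes) - 1L) * 80000L
  GenomicRanges::GRanges("chr4", IRanges::IRanges(pos, width = 1L),
                         strand = sample(c("+", "-"), length(genes), TRUE),
                         gene = genes)
}

.simSePeaks <- function(cfg, labels, tss, master_of) {
  gene <- tss$gene
  tf_tss <- setNames(GenomicRanges::start(tss), gene)
  decoys <- grep("^GENE_", gene, value = TRUE)
  tfs <- names(master_of)
  lapply(names(labels), function(s) {
    h <- labels[[s]]
    boosted <- c(tfs[!is.na(master_of) & master_of == h],
                 sample(decoys, 25L))
    weak <- sample(setdiff(tfs, boosted), round(length(tfs) / 2))
    mk <- function(g, npk, scale, shift) {
      centers <- tf_tss[g] + round(runif(npk, -4000, 3400))
      GenomicRanges::GRanges("chr4",
        IRanges::IRanges(start = centers, width = round(runif(npk, 400, 700))),
        signal = rgamma(npk, shape = 2, scale = scale) + shift)
    }
    peaks <- c(
      do.call(c, lapply(boosted, function(g) mk(g, 3L, 1500, 3000))),
      do.call(c, lapply(weak, function(g) mk(g, sample(1:2, 1), 60, 5))))
    sort(peaks)
  }) |> setNames(names(labels))
}

.simAtacPeaks <- function(labels, tss) {
  tf_tss <- GenomicRanges::start(tss)
  lapply(names(labels), function(s) {
    open_loci <- GenomicRanges::GRanges("chr4",
      IRanges::IRanges(start = tf_tss - 2200 - sample(0:100, length(tf_tss), TRUE),
                       end = tf_tss + 2200 + sample(0:100, length(tf_tss), TRUE)),
      score = rgamma(length(tf_tss), 2, scale = 25) + 10)
    bg_start <- sort(sample(seq(1, 9950000, by = 3000), 50))
    bg <- GenomicRanges::GRanges(sample(paste0("chr", 1:3), 50, TRUE),
      IRanges::IRanges(start = bg_start, width = round(runif(50, 300, 900))),
      score = rgamma(50, 2, scale = 25) + 10)
    low <- GenomicRanges::GRanges("chr4",
      IRanges::IRanges(start = sample(seq(25000000, 29000000, by = 10000), 5),
                       width = 300),
      score = rep(0.01, 5))   # spm <= 5, exercised by the filter
    sort(suppressWarnings(c(open_loci, bg, low)))
  }) |> setNames(names(labels))
}

.randomPwm <- function(width = 12L, p_consensus = 0.97) {
  cons <- sample(1:4, width, replace = TRUE)
  m <- matrix((1 - p_consensus) / 3, nrow = 4, ncol = width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(cons, seq_len(width))] <- p_consensus
  m
}

.pwmConsensus <- function(pwm) {
  paste0(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

.simMotifData <- function(cfg, tss, master_of, masters_by_h) {
  tfs <- names(master_of)
  pwms <- lapply(tfs, function(x) .randomPwm())
  names(pwms) <- tfs
  half <- 6000L
  tf_idx <- match(tfs, tss$gene)
  locus <- GenomicRanges::GRanges("chr4",
    IRanges::IRanges(start = GenomicRanges::start(tss)[tf_idx] - half,
                     width = 2L * half))
  names(locus) <- tfs
  seqs <- vapply(seq_along(tfs), function(i)
    paste0(sample(c("A", "C", "G", "T"), 2L * half, replace = TRUE),
           collapse = ""), character(1))
  names(seqs) <- tfs
  # plant, in each master's locus, the consensus of every master of the
  # same histology (mutual + self regulation) within TSS +/- 2 kb
  for (h in names(masters_by_h)) {
    for (m in masters_by_h[[h]]) {
      s <- seqs[[m]]
      offs <- half - 2000L + cumsum(sample(150:350, length(masters_by_h[[h]]),
                                           TRUE))
      for (k in seq_along(masters_by_h[[h]])) {
        motif <- .pwmConsensus(pwms[[masters_by_h[[h]][k]]])
        substr(s, offs[k], offs[k] + nchar(motif) - 1L) <- motif
      }
      seqs[[m]] <- s
    }
  }
  list(pwms = pwms, sequences = Biostrings::DNAStringSet(seqs),
       ranges = locus)
}

.simAllelic <- function(cfg, snp_peaks, ai_truth, genome) {
  groups <- c(rep("ccRCC", cfg@n_individuals_per_group),
              rep("pRCC", cfg@n_individuals_per_group))
  inds <- sprintf("%s_ind%02d", groups,
                  c(seq_len(cfg@n_individuals_per_group),
                    seq_len(cfg@n_individuals_per_group)))
  # per-individual copy-number segments: 5 per chromosome, levels 1..5
  seg_rows <- list()
  for (ind in inds) {
    for (chr in paste0("chr", 1:3)) {
      bnd <- round(seq(0, genome[[chr]], length.out = 6L))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        individual = ind, chrom = chr, start = bnd[-6] + 1L, end = bnd[-1],
        cn_level = sample(seq(1, 5, by = 0.5), 5L, replace = TRUE))
    }
  }
  segments <- do.call(rbind, seg_rows)
  n_snps <- sample(1:3, length(snp_peaks), replace = TRUE)
  rows <- vector("list", length(snp_peaks))
  pi_by_group <- cbind(ccRCC = ai_truth$pi_ccRCC, pRCC = ai_truth$pi_pRCC)
  for (p in seq_along(snp_peaks)) {
    w <- GenomicRanges::width(snp_peaks)[p]
    pos <- GenomicRanges::start(snp_peaks)[p] +
      sort(sample.int(w, n_snps[p])) - 1L
    chr <- as.character(GenomicRanges::seqnames(snp_peaks)[p])
    snp_ids <- sprintf("%s_snp%d", names(snp_peaks)[p], seq_len(n_snps[p]))
    for (j in seq_len(n_snps[p])) {
      het <- rbinom(length(inds), 1, 0.8) == 1
      if (!any(het)) het[sample(seq_along(inds), 2L)] <- TRUE
      n_ind <- sum(het)
      depth <- pmax(2L, rpois(n_ind, cfg@read_depth_snp))
      pis <- pi_by_group[p, groups[het]]
      hap1 <- vapply(seq_len(n_ind), function(i)
        .rbetabin(1L, depth[i], pis[i], cfg@rho_true), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp_ids[j], chrom = chr, pos = pos[j],
        individual = inds[het], group = groups[het],
        hap1_reads = hap1, hap2_reads = depth - hap1)
    }
  }
  counts <- do.call(rbind, rows)
  # annotate each record with the copy-number level of its segment
  counts$cn_level <- NA_real_
  for (ind in inds) {
    sel <- counts$individual == ind
    seg <- segments[segments$individual == ind, ]
    idx <- match(
      paste(counts$chrom[sel], findInterval(counts$pos[sel] - 1,
        c(0, 2e6, 4e6, 6e6, 8e6))),
      paste(seg$chrom, findInterval(seg$start - 1, c(0, 2e6, 4e6, 6e6, 8e6))))
    counts$cn_level[sel] <- seg$cn_level[idx]
  }
  rownames(counts) <- NULL
  list(counts = counts, segments = segments)
}

.simGwas <- function(cfg, universe, ai_peaks, genome) {
  ai <- GenomicRanges::reduce(ai_peaks)
  bg <- GenomicRanges::setdiff(GenomicRanges::reduce(universe), ai)
  A <- sum(GenomicRanges::width(ai))
  B <- sum(GenomicRanges::width(bg))
  n_in <- round(0.8 * cfg@n_gwas_snps)
  # plant the target-peak SNP density at `fold` times the overall peak
  # density, the background the permutation estimator measures
  n_ai <- round(n_in * cfg@gwas_enrichment_fold * A /
                  (A + B))
  n_ai <- min(n_ai, n_in)
  place_in <- function(gr, k) {
    if (k == 0L) return(NULL)
    w <- GenomicRanges::width(gr)
    pk <- sample(length(gr), k, replace = TRUE, prob = w)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[pk],
               pos = GenomicRanges::start(gr)[pk] +
                 vapply(w[pk], function(x) sample.int(x, 1L), integer(1)) - 1L)
  }
  in_ai <- place_in(ai, n_ai)
  in_bg <- place_in(bg, n_in - n_ai)
  n_out <- cfg@n_gwas_snps - n_in
  out <- data.frame(chrom = sample(paste0("chr", 1:3), n_out, TRUE),
                    pos = round(runif(n_out, 1, 10000000)))
  # keep "outside" SNPs genuinely outside the peak universe
  og <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, width = 1))
  hit <- IRanges::overlapsAny(og, universe)
  while (any(hit)) {
    out$pos[hit] <- round(runif(sum(hit), 1, 10000000))
    og <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$pos, width = 1))
    hit <- IRanges::overlapsAny(og, universe)
  }
  gwas <- rbind(in_ai, in_bg, out)
  gwas$snp_id <- sprintf("rs_sim_%04d", seq_len(nrow(gwas)))
  gwas$pheno <- "RCC"
  gwas$sig_flag <- TRUE
  gwas$in_ai_peak <- c(rep(TRUE, nrow(in_ai)),
                       rep(FALSE, nrow(gwas) - nrow(in_ai)))
  gwas[c("snp_id", "chrom", "pos", "pheno", "sig_flag", "in_ai_peak")]
}

.simAse <- function(ai_peaks, balanced_peaks) {
  n_near <- 60L
  n_far <- 60L
  near_idx <- sample(length(ai_peaks), n_near, replace = TRUE)
  near_pos <- GenomicRanges::start(ai_peaks)[near_idx] -
    round(runif(n_near, 1000, 40000))
  far_idx <- sample(length(balanced_peaks), n_far, replace = TRUE)
  far_pos <- GenomicRanges::end(balanced_peaks)[far_idx] +
    round(runif(n_far, 60000, 120000))
  genes <- sprintf("ASE_%03d", seq_len(n_near + n_far))
  tss <- GenomicRanges::GRanges(
    c(as.character(GenomicRanges::seqnames(ai_peaks))[near_idx],
      as.character(GenomicRanges::seqnames(balanced_peaks))[far_idx]),
    IRanges::IRanges(pmax(1, c(near_pos, far_pos)), width = 1L),
    strand = "+", gene = genes)
  is_ase <- c(rbinom(n_near, 1, 0.7), rbinom(n_far, 1, 0.08)) == 1
  depth <- 200L
  hap1 <- ifelse(is_ase, rbinom(length(genes), depth, 0.85),
                 rbinom(length(genes), depth, 0.5))
  list(tss = tss,
       counts = data.frame(gene = genes, hap1_reads = hap1,
                           hap2_reads = depth - hap1),
       ase_truth = setNames(is_ase, genes))
}

.simRepeats <- function(genome) {
  gr <- GenomicRanges::GRanges(
    sample(paste0("chr", 1:3), 40, TRUE),
    IRanges::IRanges(start = round(runif(40, 1, 9.9e6)),
                     width = round(runif(40, 200, 2000))))
  sort(gr)
}

#' Simulate a complete synthetic RCC cohort
#'
#' Generates, deterministically for a given [SimConfig-class], every input
#' the analysis modules consume, together with the planted ground truth:
#' per-sample H3K27ac peak calls and a peak count matrix with
#' histology-specific peaks planted at a known log2 fold change;
#' TF expression (FPKM) and a pan-cancer mean-expression table with
#' planted master TFs; per-sample enhancer peaks whose super-enhancers at
#' master-TF loci carry top ranks; locus sequences with planted motif
#' occurrences wiring each histology's masters into a mutual
#' (auto-regulatory) clique; phased heterozygous-SNP read counts drawn
#' from the beta-binomial with planted group-specific allelic ratios and
#' per-individual overdispersion; per-individual copy-number segments; a
#' GWAS catalog whose SNP density in imbalanced peaks is a planted
#' multiple of the background peak density; a repeat track; and ASE gene
#' haplotype counts.
#'
#' @param config A [SimConfig-class]; see [SimConfig()] for defaults.
#' @return An [RccCohort-class].
#' @examples
#' cohort <- simulateCohort(SimConfig(n_peaks = 200, n_snp_peaks = 50,
#'                                    n_tfs = 40, seed = 7))
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    genome <- .simGenome()
    h <- config@n_samples_per_histology
    labels <- setNames(
      rep(names(h), h),
      unlist(lapply(names(h), function(x)
        sprintf("%s_s%02d", x, seq_len(h[[x]])))))
    names(labels) <- unlist(lapply(names(h), function(x)
      sprintf("%s_s%02d", x, seq_len(h[[x]]))))

    universe <- .simPeakUniverse(config)
    n_spec <- round(config@frac_specific * config@n_peaks)
    specific <- rep("common", config@n_peaks)
    sizes <- rep(n_spec %/% 3L, 3L)
    if (n_spec %% 3L) sizes[seq_len(n_spec %% 3L)] <- sizes[1] + 1L
    spec_idx <- sample(config@n_peaks, n_spec)
    specific[spec_idx] <- rep(c("ccRCC", "pRCC", "chRCC"), sizes)
    names(specific) <- names(universe)

    counts <- .simCounts(config, universe, labels, specific)
    peak_sets <- .simPerSamplePeaks(universe, labels, specific)

    tfs <- sprintf("TF_%03d", seq_len(config@n_tfs))
    master_of <- setNames(rep(NA_character_, config@n_tfs), tfs)
    m_idx <- sample(config@n_tfs, 3L * config@n_master_tfs_per_histology)
    master_of[m_idx] <- rep(c("ccRCC", "pRCC", "chRCC"),
                            each = config@n_master_tfs_per_histology)
    masters_by_h <- split(names(master_of)[!is.na(master_of)],
                          master_of[!is.na(master_of)])

    expr <- .simExpression(config, labels, tfs, master_of)
    pan <- .simPanCancer(tfs, master_of)
    tss_genes <- .simTss(tfs)
    se_sets <- .simSePeaks(config, labels, tss_genes, master_of)
    atac_sets <- .simAtacPeaks(labels, tss_genes)
    motif <- .simMotifData(config, tss_genes, master_of, masters_by_h)

    # allelic truth: SNP-bearing peaks are common peaks (present in every
    # sample, hence guaranteed members of any multi-sample consensus)
    common_idx <- which(specific == "common")
    snp_idx <- sort(sample(common_idx, config@n_snp_peaks))
    snp_peaks <- universe[snp_idx]
    n_imb <- round(config@frac_imbalanced * config@n_snp_peaks)
    n_cc <- round(0.3 * n_imb); n_pp <- round(0.3 * n_imb)
    classes <- rep("balanced", config@n_snp_peaks)
    imb_pos <- sample(config@n_snp_peaks, n_imb)
    classes[imb_pos] <- c(rep("ccRCC", n_cc), rep("pRCC", n_pp),
                          rep("shared", n_imb - n_cc - n_pp))
    ai_truth <- data.frame(
      peak_id = names(snp_peaks),
      chrom = as.character(GenomicRanges::seqnames(snp_peaks)),
      start = GenomicRanges::start(snp_peaks),
      end = GenomicRanges::end(snp_peaks),
      class = classes,
      pi_ccRCC = ifelse(classes %in% c("ccRCC", "shared"),
                        config@pi_imbalanced, 0.5),
      pi_pRCC = ifelse(classes %in% c("pRCC", "shared"),
                       config@pi_imbalanced, 0.5),
      imbalanced = classes != "balanced")
    allelic <- .simAllelic(config, snp_peaks, ai_truth, genome)
    gwas <- .simGwas(config, universe, snp_peaks[ai_truth$imbalanced],
                     genome)
    ase <- .simAse(snp_peaks[ai_truth$imbalanced],
                   snp_peaks[!ai_truth$imbalanced])
    repeats <- .simRepeats(genome)

    truth <- list(
      histology = labels,
      specific_peak_labels = specific,
      master_tf_labels = master_of,
      ai_peaks = ai_truth,
      gwas_in_ai = setNames(gwas$in_ai_peak, gwas$snp_id),
      ase_genes = ase$ase_truth)

    new("RccCohort",
        config = config, genome = genome,
        peakSets = peak_sets, counts = counts, expression = expr,
        tfs = tfs, panCancerMeans = pan,
        sePeakSets = se_sets, atacPeakSets = atac_sets,
        tss = sort(suppressWarnings(c(tss_genes, ase$tss))),
        pwms = motif$pwms, locusSequences = motif$sequences,
        locusRanges = motif$ranges,
        allelic = allelic$counts, cnSegments = allelic$segments,
        gwas = gwas[c("snp_id", "chrom", "pos", "pheno", "sig_flag")],
        repeats = repeats, aseCounts = ase$counts,
        truth = truth)
  })
}
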