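# Chromatin allelic imbalance engine.  Reads from heterozygous SNP j in
# individual i are modeled as hap1 | total ~ BetaBin(pi_j, rho_ij): pi is
# the mean allelic ratio shared across individuals, rho a per-individual
# overdispersion estimated within copy-number strata.  Imbalance
# (pi = 0.5 vs free) and differential imbalance between groups (shared pi
# vs per-group pi) are likelihood-ratio tests on 1 df; peak-level
# multiplicity is Bonferroni within peak then Benjamini-Hochberg q-values
# across peaks.

#' Beta-binomial log-likelihood
#'
#' Exact log pmf of `k_alt` successes in `n_total` trials under the
#' mean/overdispersion parameterization `alpha = pi (1 - rho) / rho`,
#' `beta = (1 - pi)(1 - rho) / rho`, computed via log-gamma. `rho = 0`
#' returns the binomial log pmf; `k = n = 0` contributes 0. Vectorized
#' over `k_alt`, `n_total` and `rho`.
#'
#' @param k_alt Alternate (hap1) read counts.
#' @param n_total Total read counts.
#' @param pi Mean allelic ratio in (0, 1).
#' @param rho Overdispersion in \[0, 1).
#' @return Log-likelihood values.
#' @export
betabinLoglik <- function(k_alt, n_total, pi, rho) {
  if (any(pi <= 0) || any(pi >= 1)) stop("pi must lie in (0, 1)")
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  if (any(k_alt < 0) || any(k_alt > n_total))
    stop("require 0 <= k_alt <= n_total")
  n <- length(k_alt)
  rho <- rep_len(rho, n)
  out <- numeric(n)
  b0 <- rho == 0
  if (any(b0))
    out[b0] <- dbinom(k_alt[b0], n_total[b0], pi, log = TRUE)
  if (any(!b0)) {
    a <- pi * (1 - rho[!b0]) / rho[!b0]
    b <- (1 - pi) * (1 - rho[!b0]) / rho[!b0]
    out[!b0] <- lchoose(n_total[!b0], k_alt[!b0]) +
      lbeta(k_alt[!b0] + a, n_total[!b0] - k_alt[!b0] + b) - lbeta(a, b)
  }
  out
}

#' Assign copy-number strata
#'
#' Adds a `cn_stratum` column: within each individual, records are
#' binned into `n_strata` groups by their copy-number level (equal
#' values always share a stratum).
#'
#' @param counts Phased allelic count `data.frame` with `individual` and
#'   `cn_level`.
#' @param n_strata Number of strata (default 10, i.e. deciles).
#' @return `counts` with a `cn_stratum` column in 1..`n_strata`.
#' @export
assignCnStrata <- function(counts, n_strata = 10) {
  counts$cn_stratum <- NA_integer_
  for (ind in unique(counts$individual)) {
    sel <- counts$individual == ind
    r <- rank(counts$cn_level[sel], ties.method = "min") - 1L
    counts$cn_stratum[sel] <-
      pmin(n_strata, floor(r / sum(sel) * n_strata) + 1L)
  }
  counts
}

.mleRho <- function(k, n, max_rho) {
  optimize(function(r) sum(betabinLoglik(k, n, 0.5, r)),
           lower = 1e-6, upper = max_rho, maximum = TRUE,
           tol = 1e-6)$maximum
}

#' Estimate per-individual overdispersion by copy-number stratum
#'
#' For each individual, the overdispersion `rho` is the beta-binomial
#' maximum-likelihood estimate at fixed `pi = 0.5` over all retained
#' heterozygous SNPs (total reads at least `min_reads`), computed per
#' copy-number stratum; strata with fewer than `min_snps` SNPs inherit
#' the individual's global estimate. Estimates are bounded above by
#' `max_rho`.
#'
#' @param counts Phased allelic counts with `individual`, `hap1_reads`,
#'   `hap2_reads` and `cn_level` (or a precomputed `cn_stratum`).
#' @param max_rho Upper bound on rho (default 0.2).
#' @param min_reads Minimum total reads per retained SNP record.
#' @param min_snps Minimum records per stratum for a stratum-specific
#'   estimate (default 50).
#' @param n_strata Number of copy-number strata (default 10).
#' @return `data.frame` with `individual`, `cn_stratum`, `rho`, `n_snps`
#'   and the per-individual `global_rho`.
#' @export
estimateRho <- function(counts, max_rho = 0.2, min_reads = 5,
                        min_snps = 50, n_strata = 10) {
  if (is.null(counts$cn_stratum))
    counts <- assignCnStrata(counts, n_strata)
  inds <- unique(counts$individual)
  tot <- counts$hap1_reads + counts$hap2_reads
  counts <- counts[tot >= min_reads, ]
  rows <- list()
  for (ind in inds) {
    ci <- counts[counts$individual == ind, ]
    if (nrow(ci) == 0) stop("individual ", ind, " has no usable SNPs")
    global <- .mleRho(ci$hap1_reads, ci$hap1_reads + ci$hap2_reads,
                      max_rho)
    for (st in seq_len(n_strata)) {
      cs <- ci[ci$cn_stratum == st, ]
      rho <- if (nrow(cs) >= min_snps)
        .mleRho(cs$hap1_reads, cs$hap1_reads + cs$hap2_reads, max_rho)
      else global
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, cn_stratum = st, rho = rho,
        n_snps = nrow(cs), global_rho = global)
    }
  }
  do.call(rbind, rows)
}

# per-record rho lookup (individual x stratum; global fallback)
.rhoFor <- function(counts, rho_table) {
  key <- paste(rho_table$individual, rho_table$cn_stratum)
  idx <- match(paste(counts$individual, counts$cn_stratum), key)
  rho <- rho_table$rho[idx]
  miss <- is.na(rho)
  if (any(miss)) {
    gidx <- match(counts$individual[miss], rho_table$individual)
    rho[miss] <- rho_table$global_rho[gidx]
  }
  if (anyNA(rho)) stop("rho not available for some individuals")
  rho
}

#' Maximum-likelihood mean allelic ratio
#'
#' Maximizes the summed beta-binomial log-likelihood over individuals by
#' bounded one-dimensional search on \[0.005, 0.995\] (tolerance 1e-6).
#'
#' @param hap1 Per-individual hap1 read counts.
#' @param total Per-individual total read counts.
#' @param rho Per-individual overdispersion (recycled).
#' @return The MLE of pi.
#' @export
fitPi <- function(hap1, total, rho) {
  if (sum(total) == 0) stop("zero total reads")
  optimize(function(p) sum(betabinLoglik(hap1, total, p, rho)),
           lower = 0.005, upper = 0.995, maximum = TRUE,
           tol = 1e-6)$maximum
}

.prepCounts <- function(counts, rho_table, min_cov = 1) {
  if (is.null(counts$cn_stratum))
    counts <- assignCnStrata(counts)
  counts$total <- counts$hap1_reads + counts$hap2_reads
  counts <- counts[counts$total >= min_cov, ]
  counts$rho <- .rhoFor(counts, rho_table)
  counts
}

#' Per-SNP allelic-imbalance likelihood-ratio test
#'
#' For each SNP, phased read counts across individuals are tested for
#' imbalance: the statistic is twice the log-likelihood gain of a free
#' mean allelic ratio over `pi = 0.5`, referred to chi-square on 1 df.
#' SNPs lacking at least one read on each haplotype are reported with
#' `NA`.
#'
#' @param counts Phased allelic counts (`snp_id`, `individual`,
#'   `hap1_reads`, `hap2_reads`, `cn_level`/`cn_stratum`).
#' @param rho_table Output of [estimateRho()].
#' @param min_cov Minimum total reads per record (default 1).
#' @return `DataFrame` with `snp_id`, `n_ind`, `total_reads`, `pi_hat`,
#'   `lrt`, `pvalue`.
#' @export
testImbalance <- function(counts, rho_table, min_cov = 1) {
  counts <- .prepCounts(counts, rho_table, min_cov)
  by_snp <- split(seq_len(nrow(counts)), counts$snp_id)
  res <- lapply(names(by_snp), function(s) {
    d <- counts[by_snp[[s]], ]
    if (sum(d$hap1_reads) == 0 || sum(d$hap2_reads) == 0)
      return(data.frame(snp_id = s, n_ind = nrow(d),
                        total_reads = sum(d$total), pi_hat = NA_real_,
                        lrt = NA_real_, pvalue = NA_real_))
    pi_hat <- fitPi(d$hap1_reads, d$total, d$rho)
    ll1 <- sum(betabinLoglik(d$hap1_reads, d$total, pi_hat, d$rho))
    ll0 <- sum(betabinLoglik(d$hap1_reads, d$total, 0.5, d$rho))
    lrt <- max(0, 2 * (ll1 - ll0))
    data.frame(snp_id = s, n_ind = nrow(d), total_reads = sum(d$total),
               pi_hat = pi_hat, lrt = lrt,
               pvalue = pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  S4Vectors::DataFrame(do.call(rbind, res))
}

#' Per-SNP differential allelic imbalance between two groups
#'
#' Likelihood-ratio test of a shared mean allelic ratio against
#' group-specific ratios (`pi_g1 = pi_g2` vs `pi_g1 != pi_g2`), each
#' fitted by bounded one-dimensional optimization; chi-square on 1 df.
#' SNPs with reads in only one group are reported `NA`.
#'
#' @param counts1,counts2 Phased allelic counts for the two groups.
#' @param rho_table Output of [estimateRho()] covering both groups'
#'   individuals.
#' @param min_cov Minimum total reads per record.
#' @return `DataFrame` with `snp_id`, per-group `pi_hat`, `lrt`,
#'   `pvalue`.
#' @export
testDifferentialImbalance <- function(counts1, counts2, rho_table,
                                      min_cov = 1) {
  c1 <- .prepCounts(counts1, rho_table, min_cov)
  c2 <- .prepCounts(counts2, rho_table, min_cov)
  snps <- union(c1$snp_id, c2$snp_id)
  res <- lapply(snps, function(s) {
    d1 <- c1[c1$snp_id == s, ]
    d2 <- c2[c2$snp_id == s, ]
    if (nrow(d1) == 0 || nrow(d2) == 0 ||
        sum(d1$total) == 0 || sum(d2$total) == 0)
      return(data.frame(snp_id = s, pi_hat_g1 = NA_real_,
                        pi_hat_g2 = NA_real_, lrt = NA_real_,
                        pvalue = NA_real_))
    p1 <- fitPi(d1$hap1_reads, d1$total, d1$rho)
    p2 <- fitPi(d2$hap1_reads, d2$total, d2$rho)
    ps <- fitPi(c(d1$hap1_reads, d2$hap1_reads), c(d1$total, d2$total),
                c(d1$rho, d2$rho))
    ll_free <- sum(betabinLoglik(d1$hap1_reads, d1$total, p1, d1$rho)) +
      sum(betabinLoglik(d2$hap1_reads, d2$total, p2, d2$rho))
    ll_shared <- sum(betabinLoglik(d1$hap1_reads, d1$total, ps, d1$rho)) +
      sum(betabinLoglik(d2$hap1_reads, d2$total, ps, d2$rho))
    lrt <- max(0, 2 * (ll_free - ll_shared))
    data.frame(snp_id = s, pi_hat_g1 = p1, pi_hat_g2 = p2, lrt = lrt,
               pvalue = pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  S4Vectors::DataFrame(do.call(rbind, res))
}

#' Map SNPs into a peak universe
#'
#' @param counts Allelic counts with `chrom` and `pos` (1-based).
#' @param peaks `GRanges` peak universe (e.g. from [windowConsensus()]).
#' @return Named character vector, SNP id to peak id (`NA` when a SNP
#'   falls outside every peak).
#' @export
assignSnpsToPeaks <- function(counts, peaks) {
  snp <- unique(counts[c("snp_id", "chrom", "pos")])
  gr <- GenomicRanges::GRanges(snp$chrom,
                               IRanges::IRanges(snp$pos, width = 1))
  if (is.null(names(peaks)))
    names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
  hit <- GenomicRanges::findOverlaps(gr, peaks, select = "first")
  setNames(names(peaks)[hit], snp$snp_id)
}

#' Peak-level significance from per-SNP p-values
#'
#' Within each peak all SNP p-values are Bonferroni-corrected and the
#' most significant corrected value becomes the peak's p-value; q-values
#' across peaks are Benjamini-Hochberg adjusted, and peaks with
#' `q < alpha` are flagged imbalanced. SNPs unassigned to a peak, and
#' peaks with no testable SNP, are excluded.
#'
#' @param snp_results Per-SNP `DataFrame` from [testImbalance()] or
#'   [testDifferentialImbalance()].
#' @param peak_of Named vector mapping `snp_id` to peak id.
#' @param alpha Peak-level q-value threshold (default 0.05).
#' @return `DataFrame` with `peak_id`, `n_snps`, `best_snp_id`,
#'   `pvalue` (Bonferroni), `qvalue`, `imbalanced`, and the best SNP's
#'   `pi_hat` columns where available.
#' @export
peakLevelSignificance <- function(snp_results, peak_of, alpha = 0.05) {
  df <- as.data.frame(snp_results)
  df$peak_id <- unname(peak_of[df$snp_id])
  df <- df[!is.na(df$peak_id) & !is.na(df$pvalue), ]
  if (nrow(df) == 0)
    return(S4Vectors::DataFrame(peak_id = character(0),
                                n_snps = integer(0),
                                best_snp_id = character(0),
                                pvalue = numeric(0), qvalue = numeric(0),
                                imbalanced = logical(0)))
  by_peak <- split(seq_len(nrow(df)), df$peak_id)
  res <- lapply(names(by_peak), function(p) {
    d <- df[by_peak[[p]], ]
    best <- which.min(d$pvalue)
    out <- data.frame(peak_id = p, n_snps = nrow(d),
                      best_snp_id = d$snp_id[best],
                      pvalue = min(1, nrow(d) * d$pvalue[best]))
    for (col in intersect(c("pi_hat", "pi_hat_g1", "pi_hat_g2"),
                          names(d)))
      out[[col]] <- d[[col]][best]
    out
  })
  out <- do.call(rbind, res)
  out$qvalue <- p.adjust(out$pvalue, "BH")
  out$imbalanced <- out$qvalue < alpha
  S4Vectors::DataFrame(out[order(out$pvalue), ])
}

#' Classify peaks by group-specific chromatin imbalance
#'
#' A peak is group-1 specific when it is (1) significantly imbalanced in
#' group 1, (2) significantly differentially imbalanced between the
#' groups, and (3) not significantly imbalanced in group 2 alone;
#' mirrored for group 2. Peaks imbalanced in both groups are `shared`;
#' the rest are `none`.
#'
#' @param ai_g1,ai_g2 Peak-level results ([peakLevelSignificance()]) of
#'   the two single-group analyses.
#' @param diff_peaks Peak-level results of the differential test.
#' @param labels Length-2 names of the groups (default `ccRCC`, `pRCC`).
#' @param alpha q-value threshold throughout (default 0.05).
#' @return Named character vector over the union of peak ids.
#' @export
classifyGroupSpecific <- function(ai_g1, ai_g2, diff_peaks,
                                  labels = c("ccRCC", "pRCC"),
                                  alpha = 0.05) {
  ids <- sort(unique(c(ai_g1$peak_id, ai_g2$peak_id,
                       diff_peaks$peak_id)))
  sig <- function(res) {
    s <- setNames(rep(FALSE, length(ids)), ids)
    s[res$peak_id] <- res$qvalue < alpha
    s
  }
  s1 <- sig(ai_g1); s2 <- sig(ai_g2); sd <- sig(diff_peaks)
  lab <- rep("none", length(ids))
  lab[s1 & sd & !s2] <- labels[1]
  lab[s2 & sd & !s1] <- labels[2]
  lab[s1 & s2] <- "shared"
  setNames(lab, ids)
}

#' Read a phased allelic counts table
#'
#' Tab-separated with header columns `snp_id`, `chrom`, `pos`,
#' `individual`, `hap1_reads`, `hap2_reads`, `cn_level` and optionally
#' `group`.
#'
#' @param path File path.
#' @return `data.frame` of counts.
#' @export
readAllelicCounts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "individual", "hap1_reads",
            "hap2_reads", "cn_level")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)),
                                    collapse = ", "))
  df
}
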