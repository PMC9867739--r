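# Shared fixtures and independent oracles.  Everything is built in code;
# nothing is read from disk except files the tests themselves write.

gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

# BED-style builder: 0-based half-open coordinates, as in the worked
# examples; converted to the 1-based closed internal convention
grBed <- function(chrom, start0, end0, ...) {
  gr(chrom, start0 + 1L, end0, ...)
}

# brute-force per-base coverage oracle: counts distinct samples covering
# each base over a small span and returns maximal runs >= min_cover,
# as a data.frame of BED coordinates
bruteCoverageOracle <- function(peaksets, min_cover, span = 1e5) {
  chroms <- unique(unlist(lapply(peaksets, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  out <- list()
  for (chr in chroms) {
    cov <- integer(span)
    for (g in peaksets) {
      sel <- as.character(GenomicRanges::seqnames(g)) == chr
      mask <- logical(span)
      for (i in which(sel)) {
        s <- GenomicRanges::start(g)[i]
        e <- min(GenomicRanges::end(g)[i], span)
        mask[s:e] <- TRUE
      }
      cov <- cov + mask
    }
    hit <- cov >= min_cover
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                             end = ends[keep])
  }
  do.call(rbind, unname(out))
}

asCoordDf <- function(g) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g))
}

# exhaustive maximal-clique oracle (size >= 2) by subset enumeration
oracleCliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  if (n < 2) return(out)
  for (k in 2:n) for (s in combn(n, k, simplify = FALSE)) {
    sub <- adj[s, s, drop = FALSE]
    diag(sub) <- TRUE
    if (all(sub)) {
      others <- setdiff(seq_len(n), s)
      if (!any(vapply(others, function(o) all(adj[o, s]), logical(1))))
        out[[length(out) + 1L]] <- s
    }
  }
  out
}

cliqueSetEqual <- function(got, want_idx, vnames) {
  want <- vapply(want_idx, function(s)
    paste(sort(vnames[s]), collapse = ","), character(1))
  gots <- vapply(got, function(s) paste(sort(s), collapse = ","),
                 character(1))
  setequal(gots, want)
}

# one-sided Wilcoxon rank-sum p by full enumeration of group splits
enumWilcoxGreater <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  obs <- sum(r[seq_along(x)])
  splits <- combn(length(all), length(x))
  stat <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(stat >= obs)
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# quadrature oracle for the beta-binomial log pmf: integrates the
# binomial over the Beta mixing density
quadBetabin <- function(k, n, pi, rho) {
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  log(integrate(function(p) dbinom(k, n, p) * dbeta(p, a, b),
                lower = 0, upper = 1, rel.tol = 1e-12)$value)
}

# a small shared cohort used across module tests (seeded, built once)
smallCohort <- local({
  co <- NULL
  function() {
    if (is.null(co))
      co <<- simulateCohort(SimConfig(
        n_peaks = 400L, n_snp_peaks = 80L, n_tfs = 60L,
        n_master_tfs_per_histology = 3L, n_gwas_snps = 120L,
        n_individuals_per_group = 6L, seed = 11L))
    co
  }
})
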