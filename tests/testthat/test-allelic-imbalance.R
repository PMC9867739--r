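test_that("beta-binomial log-likelihood: closed forms and quadrature", {
  # binomial limit
  expect_equal(betabinLoglik(5, 10, 0.5, 0),
               log(choose(10, 5) * 0.5^10))
  expect_equal(betabinLoglik(0, 0, 0.3, 0.1), 0)
  # quadrature oracle on a parameter grid
  for (pi in c(0.3, 0.5, 0.8)) for (rho in c(0.02, 0.1, 0.18)) {
    for (kn in list(c(3, 10), c(0, 7), c(15, 20))) {
      expect_equal(betabinLoglik(kn[1], kn[2], pi, rho),
                   quadBetabin(kn[1], kn[2], pi, rho),
                   tolerance = 1e-8)
    }
  }
  # pmf sums to one
  expect_equal(sum(exp(betabinLoglik(0:20, rep(20, 21), 0.7, 0.1))), 1,
               tolerance = 1e-10)
  expect_error(betabinLoglik(3, 10, 1.2, 0.1), "pi")
  expect_error(betabinLoglik(3, 10, 0.5, 1), "rho")
  expect_error(betabinLoglik(11, 10, 0.5, 0.1), "k_alt")
})

test_that("overdispersion recovery per individual with cap", {
  mk <- function(rho, n_snps = 500, depth = 20, seed = 1) {
    k <- simulateBetaBin(depth, 0.5, rho, n_snps, seed = seed)
    data.frame(individual = "i1", snp_id = sprintf("s%d", 1:n_snps),
               hap1_reads = k, hap2_reads = depth - k,
               cn_level = rep(1:5, length.out = n_snps))
  }
  rt <- estimateRho(mk(0.05))
  expect_true(all(rt$global_rho >= 0.03 & rt$global_rho <= 0.07))
  rt0 <- estimateRho(mk(0, seed = 2))
  expect_lte(rt0$global_rho[1], 0.01)
  # rho planted beyond the cap is clamped at max_rho
  k_hi <- simulateBetaBin(20, 0.5, 0.5, 500, seed = 3)
  d_hi <- data.frame(individual = "i1", hap1_reads = k_hi,
                     hap2_reads = 20 - k_hi,
                     cn_level = rep(1:5, each = 100))
  rt_hi <- estimateRho(d_hi)
  expect_equal(rt_hi$global_rho[1], 0.2, tolerance = 1e-3)
  # strata with enough SNPs get their own estimate
  expect_true(any(rt$n_snps >= 50))
  # an individual whose records all fall below the read filter errors
  expect_error(estimateRho(data.frame(individual = "i1",
                                      hap1_reads = 1, hap2_reads = 1,
                                      cn_level = 1)),
               "usable")
})

test_that("pi MLE: closed forms, symmetry and recovery", {
  expect_equal(fitPi(9, 10, 0), 0.9, tolerance = 1e-4)
  expect_equal(fitPi(c(7, 3), c(10, 10), 0), 0.5, tolerance = 1e-4)
  set.seed(6)
  k <- simulateBetaBin(30, 0.7, 0.05, 50, seed = 6)
  expect_lt(abs(fitPi(k, rep(30, 50), 0.05) - 0.7), 0.05)
  expect_error(fitPi(0, 0, 0.05), "zero total")
})

test_that("imbalance LRT: hand-computed example and null behaviour", {
  rho0 <- data.frame(individual = "i1", cn_stratum = 1, rho = 0,
                     n_snps = 10, global_rho = 0)
  d <- data.frame(snp_id = "s1", individual = "i1", hap1_reads = 9,
                  hap2_reads = 1, cn_level = 1, cn_stratum = 1)
  res <- testImbalance(d, rho0)
  want_lrt <- 2 * (9 * log(0.9 / 0.5) + 1 * log(0.1 / 0.5))
  expect_equal(res$lrt, want_lrt, tolerance = 1e-3)
  expect_equal(res$pvalue, pchisq(want_lrt, 1, lower.tail = FALSE),
               tolerance = 1e-3)
  d5 <- transform(d, hap1_reads = 5, hap2_reads = 5)
  res5 <- testImbalance(d5, rho0)
  expect_equal(res5$lrt, 0, tolerance = 1e-6)
  expect_equal(res5$pvalue, 1, tolerance = 1e-4)
  # grid-search likelihood oracle agrees with the bounded optimizer
  set.seed(41)
  k <- simulateBetaBin(30, 0.65, 0.05, 8, seed = 41)
  dd <- data.frame(snp_id = "s1",
                   individual = sprintf("i%d", 1:8),
                   hap1_reads = k, hap2_reads = 30 - k,
                   cn_level = 1, cn_stratum = 1)
  rt <- data.frame(individual = sprintf("i%d", 1:8), cn_stratum = 1,
                   rho = 0.05, n_snps = 10, global_rho = 0.05)
  got <- testImbalance(dd, rt)
  grid <- seq(0.005, 0.995, by = 1e-4)
  ll <- vapply(grid, function(p)
    sum(betabinLoglik(k, rep(30, 8), p, 0.05)), numeric(1))
  expect_equal(got$pi_hat, grid[which.max(ll)], tolerance = 2e-4)
  expect_equal(got$lrt,
               2 * (max(ll) - sum(betabinLoglik(k, rep(30, 8), 0.5,
                                                0.05))),
               tolerance = 1e-4)
  expect_gte(got$lrt, 0)
})

test_that("differential imbalance LRT between groups", {
  rt <- data.frame(individual = c("a", "b"), cn_stratum = 1,
                   rho = 0.01, n_snps = 10, global_rho = 0.01)
  mk <- function(ind, k, n) data.frame(
    snp_id = "s1", individual = ind, hap1_reads = k,
    hap2_reads = n - k, cn_level = 1, cn_stratum = 1)
  strong <- testDifferentialImbalance(mk("a", 80, 100), mk("b", 50, 100),
                                      rt)
  expect_lt(strong$pvalue, 0.01)
  same <- testDifferentialImbalance(mk("a", 60, 100), mk("b", 60, 100),
                                    rt)
  expect_equal(same$lrt, 0, tolerance = 1e-6)
  expect_equal(same$pvalue, 1, tolerance = 1e-4)
  # grid oracle for the two-group likelihood surfaces
  g <- testDifferentialImbalance(mk("a", 75, 100), mk("b", 55, 100), rt)
  grid <- seq(0.005, 0.995, by = 1e-4)
  ll1 <- vapply(grid, function(p) betabinLoglik(75, 100, p, 0.01),
                numeric(1))
  ll2 <- vapply(grid, function(p) betabinLoglik(55, 100, p, 0.01),
                numeric(1))
  lls <- ll1 + ll2
  want <- 2 * (max(ll1) + max(ll2) - max(lls))
  expect_equal(g$lrt, want, tolerance = 1e-3)
  # a group with zero usable reads is flagged undefined
  und <- testDifferentialImbalance(mk("a", 10, 20), mk("b", 0, 0), rt)
  expect_true(is.na(und$pvalue))
})

test_that("LRT p-values are uniform under the simulated null", {
  set.seed(17)
  n_snp <- 800; n_ind <- 10; depth <- 30
  d <- expand.grid(individual = sprintf("i%02d", 1:n_ind),
                   snp_id = sprintf("s%04d", 1:n_snp),
                   stringsAsFactors = FALSE)
  d$hap1_reads <- simulateBetaBin(depth, 0.5, 0.05, nrow(d), seed = 17)
  d$hap2_reads <- depth - d$hap1_reads
  d$cn_level <- 1; d$cn_stratum <- 1
  rt <- data.frame(individual = sprintf("i%02d", 1:n_ind),
                   cn_stratum = 1, rho = 0.05, n_snps = 100,
                   global_rho = 0.05)
  res <- testImbalance(d, rt)
  frac <- mean(res$pvalue < 0.05)
  expect_lt(abs(frac - 0.05), 0.025)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak-level multiplicity: Bonferroni then q-values", {
  snp <- S4Vectors::DataFrame(
    snp_id = c("a", "b", "c", "d"),
    pvalue = c(0.01, 0.5, 0.9, 0.2),
    pi_hat = c(0.8, 0.55, 0.5, 0.6))
  peak_of <- c(a = "p1", b = "p1", c = "p1", d = "p2")
  res <- peakLevelSignificance(snp, peak_of)
  r1 <- res[res$peak_id == "p1", ]
  expect_equal(r1$pvalue, 0.03)          # 3 SNPs x min p
  expect_equal(r1$best_snp_id, "a")
  expect_equal(res[res$peak_id == "p2", "pvalue"], 0.2)  # single SNP
  # BH arithmetic on a spiked mixture
  set.seed(10)
  m <- 1000
  pv <- c(rep(1e-4, 100), runif(900))
  snp2 <- S4Vectors::DataFrame(snp_id = sprintf("s%04d", 1:m),
                               pvalue = pv)
  po <- setNames(sprintf("p%04d", 1:m), snp2$snp_id)
  res2 <- peakLevelSignificance(snp2, po)
  strong <- res2$peak_id %in% sprintf("p%04d", 1:100)
  expect_true(all(res2$qvalue[strong] < 0.05))
  expect_equal(as.data.frame(res2)[order(res2$peak_id), "qvalue"],
               p.adjust(pv, "BH")[order(sprintf("p%04d", 1:m))])
  # q-values are monotone in Bonferroni-p rank
  expect_true(all(diff(res2$qvalue[order(res2$pvalue)]) >= -1e-12))
})

test_that("group-specific classification follows the three-part rule", {
  mk <- function(ids, q) S4Vectors::DataFrame(peak_id = ids, qvalue = q)
  g1 <- mk(c("p1", "p2", "p3"), c(0.01, 0.01, 0.5))
  g2 <- mk(c("p1", "p2", "p3"), c(0.9, 0.01, 0.6))
  dd <- mk(c("p1", "p2", "p3"), c(0.01, 0.5, 0.9))
  cls <- classifyGroupSpecific(g1, g2, dd)
  expect_equal(unname(cls[c("p1", "p2", "p3")]),
               c("ccRCC", "shared", "none"))
})

test_that("planted imbalance is recovered on the shared cohort", {
  co <- smallCohort()
  ai <- allelicImbalancePipeline(co)
  truth <- simTruth(co)$ai_peaks
  tg <- gr(truth$chrom, truth$start, truth$end)
  imb <- ai$universe[ai$imbalanced_union]
  # most planted imbalanced peaks found even at 6 individuals per group
  expect_gte(mean(overlapAny(tg[truth$imbalanced], imb)), 0.5)
  # balanced peaks essentially never flagged
  expect_lte(mean(overlapAny(tg[!truth$imbalanced], imb)), 0.05)
  # estimated rho near the planted value
  expect_lt(abs(median(ai$rho_table$global_rho) - co@config@rho_true),
            0.04)
})
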