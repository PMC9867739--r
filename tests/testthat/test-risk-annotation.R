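test_that("SNP density uses union base pairs", {
  peaks <- grBed("chr1", 0, 1000)
  snps <- gr("chr1", seq(50, 950, length.out = 10),
             seq(50, 950, length.out = 10))
  expect_equal(snpDensity(snps, peaks), 0.01)
  expect_equal(snpDensity(gr("chr2", 5, 5), peaks), 0)
  # overlapping peaks cover 150 bp, not 200
  twopk <- grBed("chr1", c(0, 50), c(100, 150))
  one <- gr("chr1", 60, 60)
  expect_equal(snpDensity(one, twopk), 1 / 150)
  expect_error(snpDensity(one, GenomicRanges::GRanges()), "zero")
})

test_that("permutation enrichment: identities and conventions", {
  set.seed(8)
  universe <- grBed("chr1", (0:199) * 5000, (0:199) * 5000 + 1000)
  snps <- gr("chr1", p <- sample(1:1e6, 300), p)
  # targets = universe: every draw is the full set, fold exactly 1
  res <- permutationEnrichment(snps, universe, universe, n_iter = 200,
                               seed = 1)
  expect_equal(res$fold, 1)
  expect_equal(res$empiric_p, 1)
  # empiric p floor 1/(n_iter + 1): universe holding no SNPs at all
  empty_uni <- grBed("chr2", (0:99) * 5000, (0:99) * 5000 + 1000)
  targets <- universe[1:20]
  res2 <- permutationEnrichment(snps, targets, empty_uni, n_iter = 9999,
                                seed = 2)
  expect_equal(res2$empiric_p, 1 / 10000)
  expect_true(all(res2$background_densities == 0))
  expect_error(permutationEnrichment(snps, targets, universe,
                                     n_iter = 10), "at least 100")
})

test_that("permutation enrichment is calibrated on random targets", {
  set.seed(23)
  universe <- grBed("chr1", (0:499) * 3000, (0:499) * 3000 + 1000)
  snps <- gr("chr1", p <- sample(1:15e5, 600), p)
  # a random target subset is exchangeable with the backgrounds: the
  # fold, averaged over independent target draws, sits at 1 within the
  # Monte-Carlo error of that average
  folds <- numeric(8); cvs <- numeric(8); ps <- numeric(8)
  for (r in 1:8) {
    targets <- universe[sample(500, 60)]
    res <- permutationEnrichment(snps, targets, universe, n_iter = 500,
                                 seed = r)
    folds[r] <- res$fold
    cvs[r] <- sd(res$background_densities) /
      mean(res$background_densities)
    ps[r] <- res$empiric_p
  }
  expect_lt(abs(mean(folds) - 1), 2 * mean(cvs) / sqrt(8))
  expect_gt(min(ps), 1 / 501)
  expect_gt(mean(ps > 0.05), 0.7)
  # matched mode stays calibrated too
  targets <- universe[sample(500, 60)]
  resm <- permutationEnrichment(snps, targets, universe, n_iter = 500,
                                matched = TRUE, seed = 99)
  expect_lt(abs(resm$fold - 1), 3 * mean(cvs))
})

test_that("ASE gene calls: extremes and null control", {
  d <- data.frame(gene = c("g1", "g2"), hap1_reads = c(100, 50),
                  hap2_reads = c(0, 50))
  res <- aseGeneTest(d)
  expect_true(res$ase[res$gene == "g1"])
  expect_false(res$ase[res$gene == "g2"])
  # low-coverage genes excluded
  lo <- data.frame(gene = "g3", hap1_reads = 3, hap2_reads = 1)
  expect_equal(nrow(aseGeneTest(lo)), 0L)
  set.seed(19)
  null <- data.frame(gene = sprintf("g%04d", 1:1000),
                     hap1_reads = rbinom(1000, 100, 0.5))
  null$hap2_reads <- 100 - null$hap1_reads
  expect_lte(mean(aseGeneTest(null)$ase), 0.01)
})

test_that("AI-to-ASE linkage builds the proximity table correctly", {
  # 3 imbalanced SNPs: two within 50 kb of an ASE TSS, one far;
  # 2 balanced SNPs: none near
  snps <- data.frame(chrom = "chr1",
                     pos = c(10000, 20000, 500000, 600000, 700000),
                     imbalanced = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                     reads = c(60, 80, 120, 55, 90))
  tss <- gr("chr1", c(30000, 900000), c(30000, 900000),
            gene = c("aseG", "quietG"))
  res <- linkAiToAse(snps, ase_genes = "aseG", tss)
  expect_equal(unname(res$table["imbalanced", ]), c(2L, 1L))
  expect_equal(unname(res$table["balanced", ]), c(0L, 2L))
  expect_equal(res$prop1, 2 / 3)
  expect_true(is.infinite(res$odds_ratio))
  # the read filter drops under-covered SNPs
  snps$reads[1] <- 10
  res2 <- linkAiToAse(snps, "aseG", tss)
  expect_equal(sum(res2$table["imbalanced", ]), 2)
  # identical proportions: OR near 1, Fisher p near 1
  even <- data.frame(chrom = "chr1",
                     pos = c(10000, 500000, 20000, 600000),
                     imbalanced = c(TRUE, TRUE, FALSE, FALSE))
  res3 <- linkAiToAse(even, "aseG", tss)
  expect_equal(res3$odds_ratio, 1)
  expect_equal(res3$fisher_p, 1)
  expect_error(linkAiToAse(even[even$imbalanced, ], "aseG", tss),
               "both imbalanced and balanced")
})

test_that("contingency statistics match hypergeometric oracles", {
  tab <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  st <- contingencyStats(tab)
  expect_equal(st$odds_ratio, (8 * 9) / (2 * 1))
  expect_equal(st$fisher_p, fisher.test(tab)$p.value)
  # Fisher p equals two-sided minimum-likelihood tail summation
  hyper_two_sided <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x <- tab[1, 1]
    support <- max(0, k - n):min(k, m)
    d <- dhyper(support, m, n, k)
    sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
  }
  for (t2 in list(matrix(c(8, 2, 1, 9), 2, byrow = TRUE),
                  matrix(c(3, 7, 6, 4), 2, byrow = TRUE),
                  matrix(c(20, 5, 10, 30), 2, byrow = TRUE))) {
    expect_equal(contingencyStats(t2)$fisher_p, hyper_two_sided(t2),
                 tolerance = 1e-7)
  }
})

test_that("Kruskal-Wallis genotype test matches rank arithmetic", {
  expect_equal(genotypeSignalTest(rep(2.5, 6), c(0, 0, 1, 1, 2, 2)),
               list(H = 0, df = 2L, pvalue = 1))
  # fully separated groups: H by hand from rank means
  got <- genotypeSignalTest(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 1, 2, 2))
  H_hand <- 12 / (6 * 7) * (2 * (1.5 - 3.5)^2 + 0 + 2 * (5.5 - 3.5)^2)
  expect_equal(got$H, H_hand, tolerance = 1e-10)
  expect_equal(got$pvalue, pchisq(H_hand, 2, lower.tail = FALSE))
  expect_error(genotypeSignalTest(1:4, rep(1, 4)), "2 genotype groups")
  # permutation calibration: null p-values roughly uniform
  set.seed(30)
  ps <- replicate(400, {
    x <- rnorm(12)
    g <- sample(rep(0:2, each = 4))
    genotypeSignalTest(x, g)$pvalue
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted GWAS enrichment fold is recovered on the cohort", {
  co <- smallCohort()
  ai <- allelicImbalancePipeline(co)
  gw <- gwasEnrichmentPipeline(co, ai, n_iter = 500, seed = 3)
  # small cohort: wide net, the acceptance suite checks the tight band
  expect_gt(gw$fold, 3)
  expect_lt(gw$empiric_p, 0.05)
})
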