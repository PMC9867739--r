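test_that("differential TF expression: exact p-values and filters", {
  expr <- rbind(
    TFa = c(30, 40, 50, 1, 2, 3),      # complete separation, 3 vs 3
    TFb = c(8, 7, 9, 1, 1, 2),         # high mean below 10 FPKM
    TFc = c(50, 60, 70, 50, 60, 70))   # identical distributions
  labels <- rep(c("q", "r"), each = 3)
  res <- differentialTfExpression(expr, labels, "q", min_fpkm = 10)
  expect_equal(res$pvalue[1], 1 / 20)  # 1 / C(6,3)
  expect_true(res$excluded[2])
  expect_true(is.na(res$pvalue[2]))
  expect_gte(res$pvalue[3], 0.5)
  expect_false(res$pass[3])

  # exact p agrees with full enumeration for random small samples,
  # including tied observations
  set.seed(31)
  for (rep in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- 20 + sample(0:8, n1, TRUE); y <- 18 + sample(0:8, n2, TRUE)
    m <- rbind(TF = c(x, y))
    res_i <- differentialTfExpression(m, rep(c("q", "r"), c(n1, n2)),
                                      "q", min_fpkm = 0, min_tpm = 0)
    expect_equal(res_i$pvalue, enumWilcoxGreater(x, y),
                 tolerance = 1e-12)
  }
  expect_error(differentialTfExpression(expr, c("q", "q", "q", "q", "q", "r"),
                                        "r"), ">= 2 samples")
})

test_that("Jensen-Shannon divergence: worked values and properties", {
  expect_equal(jsDivergence(c(1, 0), c(1, 0)), 0)
  expect_equal(jsDivergence(c(1, 0, 0), c(0, 1, 0)), 1)
  # two types, observed (0.5, 0.5) vs ideal (1, 0)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  want <- ent(c(0.75, 0.25)) - 0.5
  got <- jsDivergence(c(0.5, 0.5), c(1, 0))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, 0.311278, tolerance = 1e-5)
  expect_equal(1 - sqrt(got), 0.442077, tolerance = 1e-5)
  # random distributions: symmetry, bounds, zero iff equal, and
  # agreement with an independent KL-based formulation
  set.seed(14)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k); p <- p / sum(p)
    q <- runif(k); q <- q / sum(q)
    d <- jsDivergence(p, q)
    expect_equal(d, jsDivergence(q, p), tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
    m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
    expect_equal(d, (kl(p, m) + kl(q, m)) / 2, tolerance = 1e-10)
    expect_equal(jsDivergence(p, p), 0, tolerance = 1e-12)
  }
})

test_that("specificity scores flag dual-top-5% candidates", {
  set.seed(9)
  n <- 100
  m <- matrix(rlnorm(n * 4, log(5), 0.3), nrow = n,
              dimnames = list(sprintf("TF%03d", 1:n),
                              c("q", "t2", "t3", "t4")))
  m[1, ] <- c(80, 0, 0, 0)    # perfectly query-specific
  m[2, ] <- c(0, 90, 0, 0)    # specific to another type
  sc <- cactsScores(m, "q")
  expect_equal(unname(sc$specificity[1]), 1, tolerance = 1e-6)
  expect_lt(unname(sc$specificity[2]), 0.05)
  expect_true(sc$candidate[1])
  expect_false(sc$candidate[2])
  # at most ~5% pass each cut, so candidates are rare
  expect_lte(sum(sc$candidate), 6)
  expect_error(cactsScores(m, "nope"), "unknown query")
})

test_that("stitching merges gaps below the stitch distance", {
  pk <- grBed("chr1", c(100, 300, 20000), c(200, 400, 20100),
              signal = c(1, 2, 4))
  st <- stitchPeaks(pk, stitch_bp = 12500)
  expect_equal(asCoordDf(st),
               data.frame(chrom = "chr1", start = c(101L, 20001L),
                          end = c(400L, 20100L)))
  expect_equal(st$signal, c(3, 4))
  # stitch 0: only overlapping/book-ended merge
  st0 <- stitchPeaks(pk, stitch_bp = 0)
  expect_equal(length(st0), 3L)
  one <- stitchPeaks(grBed("chr1", c(0, 5000, 11000),
                           c(100, 5100, 11100), signal = c(1, 1, 1)),
                     stitch_bp = 12500)
  expect_equal(length(one), 1L)
  expect_equal(one$n_peaks, 3L)
})

test_that("the rank-signal elbow separates super-enhancers", {
  reg <- grBed("chr1", (0:5) * 1e5, (0:5) * 1e5 + 1000,
               signal = c(100, 5, 4, 3, 2, 1))
  se <- callSuperenhancers(reg)
  expect_equal(sum(se$is_super), 1L)
  expect_true(se$is_super[se$signal == 100])
  expect_equal(se$rank[se$signal == 100], 1L)
  expect_equal(sort(se$rank), 1:6)

  expect_warning(flat <- callSuperenhancers(
    grBed("chr1", (0:3) * 1e5, (0:3) * 1e5 + 100,
          signal = rep(7, 4))), "constant")
  expect_false(any(flat$is_super))
  expect_error(callSuperenhancers(grBed("chr1", c(0, 100), c(50, 150),
                                        signal = c(1, 2))), "at least 3")

  # adding a region below the cutoff never converts a TE into an SE
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    sig <- sort(c(rexp(n - 2, 1 / 50), 5000, 8000))
    reg <- grBed("chr1", seq_len(n) * 1e5, seq_len(n) * 1e5 + 500,
                 signal = sig)
    se1 <- callSuperenhancers(reg)
    cutoff <- S4Vectors::metadata(se1)$cutoff_signal
    supers1 <- asCoordDf(se1[se1$is_super])
    extra <- grBed("chr1", (n + 1) * 1e5, (n + 1) * 1e5 + 500,
                   signal = runif(1, 0, cutoff * 0.9))
    se2 <- callSuperenhancers(suppressWarnings(c(reg, extra)))
    supers2 <- asCoordDf(se2[se2$is_super])
    expect_true(all(do.call(paste, supers1) %in% do.call(paste, supers2) |
                      nrow(supers2) >= nrow(supers1)))
    expect_false(any(se2$is_super[length(se2)]))
  }
})

test_that("SE-gene assignment: nearest TSS with coordinate tie-break", {
  tss <- gr("chr1", c(1400, 5000), c(1400, 5000),
            gene = c("geneA", "geneB"))
  se <- gr("chr1", 1000, 2000)
  expect_equal(assignSeToGene(se, tss)$assigned_gene, "geneA")
  # equidistant: midpoint 3200 between 1400 and 5000
  tie <- gr("chr1", 3000, 3400)
  tss2 <- gr("chr1", c(3100, 3300), c(3100, 3300),
             gene = c("lo", "hi"))
  expect_equal(assignSeToGene(tie, tss2)$assigned_gene, "lo")
  # midpoint exactly on a TSS
  on <- gr("chr1", 1300, 1500)
  expect_equal(assignSeToGene(on, tss)$assigned_gene, "geneA")
  expect_warning(un <- assignSeToGene(gr("chr9", 10, 20), tss),
                 "without TSS")
  expect_true(is.na(un$assigned_gene))
})

test_that("SE rank matrix: minimum rule and fill value", {
  mk <- function(ranks, supers, genes)
    gr("chr1", seq_along(ranks) * 1000, seq_along(ranks) * 1000 + 100,
       rank = ranks, is_super = supers, assigned_gene = genes)
  calls <- list(
    s1 = mk(c(7L, 30L, 2L), c(TRUE, TRUE, TRUE),
            c("TF1", "TF1", "TF2")),
    s2 = mk(c(1L, 9L), c(TRUE, TRUE), c("TF2", "other")))
  m <- tfSeRankMatrix(calls, c("TF1", "TF2", "TF3"))
  expect_equal(attr(m, "fill_value"), 30L)
  expect_equal(m["TF1", "s1"], 7L)       # minimum over the TF's SEs
  expect_equal(m["TF1", "s2"], 30L)      # fill when absent
  expect_equal(unname(m["TF3", ]), c(30L, 30L))
  expect_equal(m["TF2", "s2"], 1L)
})

test_that("differential SE rank: one-sided test with mean-rank gate", {
  m <- rbind(TF1 = c(1, 2, 3, 1477, 1477, 1477),
             TF2 = c(1200, 1150, 1300, 1250, 1180, 1220),
             TF3 = rep(50, 6))
  labels <- rep(c("q", "r"), each = 3)
  res <- differentialSeRank(m, labels, "q")
  expect_equal(res$pvalue[1], 0.05)      # 1 / C(6,3) one-sided
  expect_true(res$excluded[2])           # mean rank > 1000
  expect_false(res$pass[3])              # identical ranks
})

test_that("motif scanning: strands, thresholds, degenerate symbols", {
  pwm <- matrix(0.01, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- pwm["C", 2] <- pwm["G", 3] <- pwm["T", 4] <- 0.97
  pwms <- list(M = pwm)
  hits <- scanMotifs(pwms, c(fw = "GGGACGTGGG"), threshold = 0.9)
  expect_true(hits["M", "fw"])
  # reverse complement of ACGT is ACGT; use the asymmetric motif ACGA,
  # present only as its reverse complement TCGT on the given strand
  pwm2 <- pwm; pwm2["A", 4] <- 0.97; pwm2["T", 4] <- 0.01
  hits2 <- scanMotifs(list(M = pwm2), c(rc = "CCCTCGTCCC"), 0.9)
  expect_true(hits2["M", "rc"])
  expect_false(scanMotifs(pwms, c(x = "GGGGGGGG"), 0.9)["M", "x"])
  # absolute threshold above the attainable maximum: no hits
  expect_false(scanMotifs(pwms, c(fw = "ACGT"), 100,
                          relative = FALSE)["M", "fw"])
  expect_warning(scanMotifs(pwms, c(n = "ACNTACGT"), 0.9), "non-ACGT")
})

test_that("clique enumeration equals exhaustive subset enumeration", {
  tri <- igraph::make_graph(~ A - B, B - C, A - C)
  expect_equal(enumerateCliques(tri), list(c("A", "B", "C")))
  path <- igraph::make_graph(~ A - B, B - C)
  expect_equal(enumerateCliques(path), list(c("A", "B"), c("B", "C")))
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("A", "B", "C")
  expect_equal(enumerateCliques(lone), list())
  expect_equal(enumerateCliques(igraph::make_empty_graph(0,
                                                         FALSE)), list())
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    adj <- matrix(runif(n * n) < 0.4, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    vn <- paste0("v", seq_len(n))
    dimnames(adj) <- list(vn, vn)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_true(cliqueSetEqual(enumerateCliques(g), oracleCliques(adj),
                               vn))
  }
})

test_that("clique enrichment score is the exact clique fraction", {
  cl <- list(c("A", "B"), c("B", "C"))
  ces <- cliqueEnrichmentScore(cl, c("A", "B", "C", "D"))
  expect_equal(unname(ces), c(0.5, 1, 0.5, 0))
  expect_equal(unname(cliqueEnrichmentScore(list(), c("A", "B"))),
               c(0, 0))
  expect_equal(unname(cliqueEnrichmentScore(list(c("A", "B", "C")),
                                            c("A", "B", "C"))),
               c(1, 1, 1))
})

test_that("differential CES applies the minimum-CES gate", {
  m <- rbind(TF1 = c(0.4, 0.5, 0.6, 0, 0, 0),
             TF2 = c(0.03, 0.03, 0.03, 0, 0, 0),
             TF3 = rep(0.3, 6))
  labels <- rep(c("q", "r"), each = 3)
  res <- differentialCes(m, labels, "q")
  expect_equal(res$pvalue[1], 0.05)
  expect_true(res$excluded[2])
  expect_false(res$pass[3])
})

test_that("master consensus requires DE plus one orthogonal analysis", {
  tfs <- c("T1", "T2", "T3", "T4")
  de <- setNames(c(TRUE, FALSE, TRUE, FALSE), tfs)
  ca <- setNames(c(TRUE, TRUE, FALSE, FALSE), tfs)
  se <- setNames(c(FALSE, TRUE, FALSE, FALSE), tfs)
  ce <- setNames(c(FALSE, FALSE, FALSE, FALSE), tfs)
  tab <- nominateMasterTfs(de, ca, se, ce)
  expect_equal(tab$master, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(tab$evidence, c(2, 2, 1, 0))
  all4 <- nominateMasterTfs(setNames(rep(TRUE, 4), tfs),
                            setNames(rep(TRUE, 4), tfs),
                            setNames(rep(TRUE, 4), tfs),
                            setNames(rep(TRUE, 4), tfs))
  expect_true(all(all4$master))
  expect_equal(all4$evidence, rep(4, 4))
  expect_error(nominateMasterTfs(de, ca[1:3], se, ce), "universes")
})

test_that("planted master TFs are recovered end to end", {
  co <- smallCohort()
  mt <- masterTfPipeline(co)
  truth <- simTruth(co)$master_tf_labels
  noms <- as.data.frame(mt$nominations)
  called <- noms[noms$master, ]
  true_pairs <- paste(names(truth)[!is.na(truth)],
                      truth[!is.na(truth)])
  called_pairs <- paste(called$tf, called$histology)
  expect_gte(mean(true_pairs %in% called_pairs), 0.9)
  expect_lte(mean(!(called_pairs %in% true_pairs)), 0.1)
})
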