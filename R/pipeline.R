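# End-to-end convenience pipelines over an RccCohort: they chain the
# module functions exactly as a user would on real cohort exports.

#' Differential enhancer pipeline
#'
#' Normalizes the cohort count matrix, runs the one-vs-rest
#' negative-binomial test for every histology and applies the
#' histology-specific labeling rule.
#'
#' @param cohort An [RccCohort-class].
#' @param padj_max,log2fc_min Labeling thresholds (defaults 0.001, 3).
#' @return List with `results` (per histology), `labels` (per peak) and
#'   the normalized matrix.
#' @export
differentialPeakPipeline <- function(cohort, padj_max = 0.001,
                                     log2fc_min = 3) {
  se <- peakCounts(cohort)
  labels <- as.character(SummarizedExperiment::colData(se)$histology)
  res <- lapply(unique(labels), function(h)
    nbDifferential(se, target = h))
  names(res) <- unique(labels)
  list(results = res,
       labels = callHistologySpecific(res, padj_max, log2fc_min),
       normalized = normalizeCounts(se))
}

#' Four-pronged master-TF nomination pipeline
#'
#' Runs differential TF expression, specificity scoring against the
#' pan-cancer means, super-enhancer calling with the rank test, and the
#' clique enrichment analysis on every sample, then applies the
#' consensus rule per histology.
#'
#' @param cohort An [RccCohort-class].
#' @param expressed_min_fpkm FPKM floor defining "expressed" for clique
#'   nodes (default 10).
#' @return List with the per-prong tables, the CES matrix, the SE rank
#'   matrix and `nominations` (tf, histology, flags, master).
#' @export
masterTfPipeline <- function(cohort, expressed_min_fpkm = 10) {
  expr <- tfExpression(cohort)
  labels <- as.character(SummarizedExperiment::colData(expr)$histology)
  fpkm <- SummarizedExperiment::assay(expr)
  tfs <- cohort@tfs
  histologies <- unique(labels)

  tf_tss <- cohort@tss[!grepl("^ASE_", cohort@tss$gene)]
  se_calls <- lapply(cohort@sePeakSets, function(pk)
    assignSeToGene(callSuperenhancers(stitchPeaks(pk)), tf_tss))
  rank_mat <- tfSeRankMatrix(se_calls, tfs)

  atac <- filterRepeats(buildAtacConsensus(cohort@atacPeakSets),
                        cohort@repeats)
  samples <- colnames(fpkm)
  ces_mat <- matrix(0, length(tfs), length(samples),
                    dimnames = list(tfs, samples))
  for (s in samples) {
    expressed <- rownames(fpkm)[fpkm[, s] >= expressed_min_fpkm]
    g <- buildCliqueGraph(se_calls[[s]], expressed, cohort@pwms,
                          cohort@locusSequences,
                          setNames(cohort@locusRanges,
                                   names(cohort@locusRanges)),
                          atac = atac)
    ces_mat[, s] <- cliqueEnrichmentScore(enumerateCliques(g), tfs)
  }

  de <- list(); cacts <- list(); se_rank <- list(); ces <- list()
  noms <- list()
  for (h in histologies) {
    de[[h]] <- differentialTfExpression(expr, histology = h)
    cacts[[h]] <- cactsScores(cohort@panCancerMeans, query = h)
    se_rank[[h]] <- differentialSeRank(rank_mat, labels, h)
    ces[[h]] <- differentialCes(ces_mat, labels, h)
    tab <- nominateMasterTfs(
      setNames(de[[h]]$pass, de[[h]]$tf),
      setNames(cacts[[h]]$candidate, cacts[[h]]$tf),
      setNames(se_rank[[h]]$pass, se_rank[[h]]$tf),
      setNames(ces[[h]]$pass, ces[[h]]$tf))
    tab$histology <- h
    noms[[h]] <- tab
  }
  nominations <- do.call(rbind, noms)
  list(de = de, cacts = cacts, se_rank = se_rank, ces = ces,
       se_calls = se_calls, rank_matrix = rank_mat, ces_matrix = ces_mat,
       atac_consensus = atac, nominations = nominations)
}

#' Chromatin allelic-imbalance pipeline
#'
#' Builds the 50-bp-window consensus peak universe, estimates
#' per-individual overdispersion across copy-number strata, and runs the
#' imbalance test for each group, the combined set, and the differential
#' test, with peak-level Bonferroni/q-value multiplicity.
#'
#' @param cohort An [RccCohort-class].
#' @param groups The two groups compared (default ccRCC vs pRCC).
#' @param alpha Peak q-value threshold (default 0.05).
#' @return List with the peak `universe`, `rho_table`, per-analysis
#'   peak-level tables, the `classes` labeling, and the union of
#'   imbalanced peak ids.
#' @export
allelicImbalancePipeline <- function(cohort, groups = c("ccRCC", "pRCC"),
                                     alpha = 0.05) {
  universe <- windowConsensus(peakSets(cohort), window_bp = 50,
                              min_samples = 2)
  names(universe) <- sprintf("cons_%06d", seq_along(universe))
  counts <- assignCnStrata(allelicCounts(cohort))
  rho <- estimateRho(counts)
  peak_of <- assignSnpsToPeaks(counts, universe)
  c1 <- counts[counts$group == groups[1], ]
  c2 <- counts[counts$group == groups[2], ]
  combined <- peakLevelSignificance(testImbalance(counts, rho), peak_of,
                                    alpha)
  g1 <- peakLevelSignificance(testImbalance(c1, rho), peak_of, alpha)
  g2 <- peakLevelSignificance(testImbalance(c2, rho), peak_of, alpha)
  diffp <- peakLevelSignificance(
    testDifferentialImbalance(c1, c2, rho), peak_of, alpha)
  classes <- classifyGroupSpecific(g1, g2, diffp, labels = groups,
                                   alpha = alpha)
  imbalanced_union <- unique(c(
    combined$peak_id[combined$imbalanced],
    g1$peak_id[g1$imbalanced], g2$peak_id[g2$imbalanced]))
  list(universe = universe, rho_table = rho, peak_of = peak_of,
       combined = combined, group1 = g1, group2 = g2,
       differential = diffp, classes = classes,
       imbalanced_union = imbalanced_union)
}

#' GWAS risk-SNP enrichment pipeline
#'
#' Measures the enrichment of the cohort's GWAS catalog in the
#' discovered imbalanced peaks against backgrounds sampled from the full
#' peak universe.
#'
#' @param cohort An [RccCohort-class].
#' @param ai_result Output of [allelicImbalancePipeline()].
#' @param n_iter Background iterations (default 2000 at desk scale).
#' @param matched Match backgrounds by chromosome and size bin?
#' @param seed Optional seed.
#' @return An enrichment result (see [permutationEnrichment()]).
#' @export
gwasEnrichmentPipeline <- function(cohort, ai_result, n_iter = 2000,
                                   matched = FALSE, seed = NULL) {
  targets <- ai_result$universe[ai_result$imbalanced_union]
  universe <- SummarizedExperiment::rowRanges(peakCounts(cohort))
  permutationEnrichment(gwasCatalog(cohort), targets, universe,
                        n_iter = n_iter, matched = matched, seed = seed)
}
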