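# Master-TF nomination prong 1 (differential TF expression), prong 2
# (Jensen-Shannon tissue-specificity scoring against a pan-cancer
# background), and the consensus integration rule.

.exprAndLabels <- function(expr, labels) {
  if (methods::is(expr, "SummarizedExperiment")) {
    if (is.null(labels))
      labels <- as.character(SummarizedExperiment::colData(expr)$histology)
    expr <- SummarizedExperiment::assay(expr)
  }
  list(expr = as.matrix(expr), labels = labels)
}

#' Differential TF expression, one histology versus the rest
#'
#' One-sided Wilcoxon rank-sum test (query greater) per TF on per-sample
#' normalized expression, exact for small groups without ties. TFs whose
#' highest per-histology mean is below `min_fpkm` FPKM are excluded
#' before testing; a second minimum of `min_tpm` on the TPM scale
#' (columns rescaled to sum to one million) is applied as a pass
#' condition. Passing requires FDR < `fdr_max` (Benjamini-Hochberg over
#' tested TFs) and a log2 fold change of query over rest means (with a
#' 1-FPKM pseudocount) of at least `log2fc_min`.
#'
#' @param expr Genes x samples FPKM matrix or `SummarizedExperiment`.
#' @param labels Histology per sample.
#' @param histology Query histology.
#' @param fdr_max,log2fc_min,min_fpkm,min_tpm Thresholds (defaults 0.1,
#'   1, 10, 10).
#' @return `DataFrame` with per-TF means, `log2fc`, `pvalue`, `fdr`,
#'   `excluded`, `pass`.
#' @export
differentialTfExpression <- function(expr, labels = NULL, histology,
                                     fdr_max = 0.1, log2fc_min = 1,
                                     min_fpkm = 10, min_tpm = 10) {
  x <- .exprAndLabels(expr, labels)
  expr <- x$expr; labels <- x$labels
  g1 <- labels == histology
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need >= 2 samples per group")
  hist_means <- vapply(unique(labels), function(h)
    rowMeans(expr[, labels == h, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(hist_means)))
    hist_means <- matrix(hist_means, nrow = 1,
                         dimnames = list(rownames(expr), unique(labels)))
  tpm <- sweep(expr, 2, colSums(expr), "/") * 1e6
  tpm_means <- vapply(unique(labels), function(h)
    rowMeans(tpm[, labels == h, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(tpm_means)))
    tpm_means <- matrix(tpm_means, nrow = 1,
                        dimnames = list(rownames(expr), unique(labels)))
  excluded <- apply(hist_means, 1, max) < min_fpkm
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  lfc <- log2((m1 + 1) / (m2 + 1))
  p <- rep(NA_real_, nrow(expr))
  for (i in which(!excluded))
    p[i] <- .rankSumOneSided(expr[i, g1], expr[i, !g1], "greater")
  fdr <- rep(NA_real_, length(p))
  fdr[!excluded] <- p.adjust(p[!excluded], "BH")
  pass <- !excluded & !is.na(fdr) & fdr < fdr_max & lfc >= log2fc_min &
    apply(tpm_means, 1, max) >= min_tpm
  S4Vectors::DataFrame(
    tf = rownames(expr), mean_query = m1, mean_rest = m2, log2fc = lfc,
    pvalue = p, fdr = fdr, excluded = excluded, pass = pass)
}

#' Jensen-Shannon divergence between two distributions
#'
#' Base-2 JSD, bounded in \[0, 1\]; 0 iff the distributions coincide.
#' Inputs are normalized to sum to one.
#'
#' @param p,q Non-negative vectors of equal length.
#' @return The divergence (not its square root).
#' @export
jsDivergence <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  ent <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  ent(m) - (ent(p) + ent(q)) / 2
}

#' Tissue-specificity (CaCTS-style) scores for TFs
#'
#' For each TF, compares its per-tumor-type mean expression profile to an
#' ideal profile concentrated entirely in the query type. Expression is
#' first shifted so the global minimum is zero; per-type means of zero
#' are replaced by 1e-17; the observed vector is normalized to sum to
#' one; divergence from the one-hot ideal is the base-2 Jensen-Shannon
#' divergence, and the specificity score is `1 - sqrt(JSD)` (1 for a
#' perfectly query-specific TF). Candidates satisfy the dual top-5% rule:
#' top 5% by specificity score and top 5% by mean expression in the
#' query type, ties at either quantile boundary included.
#'
#' @param mean_expr TF x tumor-type matrix of mean expression.
#' @param query Column name of the query tumor type.
#' @param top_frac Quantile fraction for both candidate cuts (default
#'   0.05).
#' @return `DataFrame` with `jsd`, `specificity`, `mean_query_expr`,
#'   `candidate` per TF.
#' @export
cactsScores <- function(mean_expr, query, top_frac = 0.05) {
  mean_expr <- as.matrix(mean_expr)
  if (!query %in% colnames(mean_expr)) stop("unknown query type: ", query)
  shifted <- mean_expr - min(mean_expr)
  if (any(shifted < 0)) stop("negative expression after shift")
  shifted[shifted == 0] <- 1e-17
  ideal <- as.numeric(colnames(mean_expr) == query)
  jsd <- apply(shifted, 1, function(x) jsDivergence(x / sum(x), ideal))
  spec <- 1 - sqrt(pmin(pmax(jsd, 0), 1))
  mq <- mean_expr[, query]
  cand <- spec >= quantile(spec, 1 - top_frac) &
    mq >= quantile(mq, 1 - top_frac)
  S4Vectors::DataFrame(tf = rownames(mean_expr), jsd = jsd,
                       specificity = spec, mean_query_expr = mq,
                       candidate = cand)
}

#' Consensus master-TF nomination
#'
#' A TF is nominated as a master regulator of a histology when it is
#' significantly differentially expressed there AND passes at least one
#' of the three orthogonal analyses: specificity-score candidacy,
#' differential super-enhancer rank, or differential clique enrichment.
#'
#' @param de,cacts,se_rank,ces Named logical vectors (pass flags) over
#'   the same TF universe.
#' @return `DataFrame` with the four flags, the evidence count and the
#'   consensus `master` flag per TF.
#' @export
nominateMasterTfs <- function(de, cacts, se_rank, ces) {
  tfs <- names(de)
  for (v in list(cacts, se_rank, ces))
    if (!identical(sort(names(v)), sort(tfs)))
      stop("TF universes differ between analyses")
  cacts <- cacts[tfs]; se_rank <- se_rank[tfs]; ces <- ces[tfs]
  evidence <- de + cacts + se_rank + ces
  S4Vectors::DataFrame(
    tf = tfs, de = unname(de), cacts = unname(cacts),
    se_rank = unname(se_rank), ces = unname(ces),
    evidence = unname(evidence),
    master = unname(de & (cacts | se_rank | ces)))
}
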