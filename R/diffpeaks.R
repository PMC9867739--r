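# Differential enhancer calling: library-size + quantile normalization,
# a two-group negative-binomial Wald test (method-of-moments dispersion
# shrunk toward a mean-dispersion trend), the one-vs-rest histology
# labeling rule, and Spearman sample clustering.

.countsAndMeta <- function(counts, labels = NULL, libsizes = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(counts)
    if (is.null(labels) && "histology" %in% names(cd))
      labels <- as.character(cd$histology)
    if (is.null(libsizes) && "libsize" %in% names(cd))
      libsizes <- cd$libsize
    counts <- SummarizedExperiment::assay(counts)
  }
  list(counts = as.matrix(counts), labels = labels, libsizes = libsizes)
}

#' Normalize a peak count matrix
#'
#' Scales each sample to reads per million of its total mapped reads,
#' then quantile-normalizes the matrix so every sample shares the same
#' empirical distribution (each column's sorted values are replaced by
#' cross-column rank means; ties receive the mean of their rank range).
#'
#' @param counts Peaks x samples matrix of non-negative counts, or a
#'   `SummarizedExperiment` with `libsize` in its `colData`.
#' @param libsizes Total mapped reads per sample (ignored when `counts`
#'   is a `SummarizedExperiment` carrying them).
#' @return Normalized matrix of the same dimensions.
#' @export
normalizeCounts <- function(counts, libsizes = NULL) {
  x <- .countsAndMeta(counts, libsizes = libsizes)
  if (is.null(x$libsizes)) stop("libsizes are required")
  if (any(x$libsizes <= 0)) stop("libsizes must be positive")
  rpm <- sweep(x$counts, 2, x$libsizes / 1e6, "/")
  out <- limma::normalizeQuantiles(rpm, ties = TRUE)
  dimnames(out) <- dimnames(x$counts)
  out
}

# mean-dispersion trend a0 + a1/mu, fitted on method-of-moments estimates
.dispersionTrend <- function(mu, disp) {
  ok <- is.finite(mu) & is.finite(disp) & mu > 0 & disp > 1e-8
  if (sum(ok) < 10) return(function(m) pmax(median(disp[ok], na.rm = TRUE),
                                            1e-8) + 0 * m)
  fit <- lm(disp[ok] ~ I(1 / mu[ok]))
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Two-group negative-binomial Wald test for peak enrichment
#'
#' Tests each peak for differential signal between one histology and the
#' rest of the cohort. Counts are corrected by library-size factors,
#' per-peak dispersions are estimated by method of moments and shrunk (in
#' log space) toward a fitted mean-dispersion trend, and a Wald statistic
#' on the log2 fold change (target over rest, with a pseudocount) is
#' referred to the standard normal, two-sided. P values are adjusted by
#' Benjamini-Hochberg across peaks; all-zero peaks are flagged `NA` and
#' excluded from the adjustment.
#'
#' @param counts Matrix or `SummarizedExperiment` of raw counts.
#' @param labels Histology per sample.
#' @param target The histology tested against the rest.
#' @param libsizes Total mapped reads per sample; defaults to column sums
#'   when absent.
#' @param normalized Set `TRUE` when `counts` are already library-size
#'   corrected; factors are then not applied again.
#' @param pseudocount Added to group means in the fold change.
#' @return `DataFrame` with `base_mean`, `log2fc`, `se`, `stat`,
#'   `pvalue`, `padj` per peak.
#' @export
nbDifferential <- function(counts, labels = NULL, target, libsizes = NULL,
                           normalized = FALSE, pseudocount = 1) {
  x <- .countsAndMeta(counts, labels, libsizes)
  labels <- x$labels
  if (is.null(labels) || length(labels) != ncol(x$counts))
    stop("labels must be given, one per sample")
  g1 <- labels == target
  if (sum(g1) < 2) stop("group '", target, "' has fewer than 2 samples")
  if (sum(!g1) < 2) stop("group 'rest' has fewer than 2 samples")
  sf <- if (normalized || is.null(x$libsizes)) rep(1, ncol(x$counts))
        else x$libsizes / mean(x$libsizes)
  q <- sweep(x$counts, 2, sf, "/")
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, !g1, drop = FALSE])
  v1 <- apply(q[, g1, drop = FALSE], 1, var)
  v2 <- apply(q[, !g1, drop = FALSE], 1, var)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp_mom <- (v - mu) / pmax(mu, 1e-8)^2
  trend <- .dispersionTrend(mu, disp_mom)
  disp <- exp((log(pmax(disp_mom, 1e-8)) + log(trend(mu))) / 2)
  disp <- pmin(pmax(disp, 1e-8), 10)
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  se <- sqrt(1 / (n1 * pmax(m1, pseudocount)) + disp / n1 +
             1 / (n2 * pmax(m2, pseudocount)) + disp / n2) / log(2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  zero <- mu == 0
  p[zero] <- NA_real_
  stat[zero] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!zero] <- p.adjust(p[!zero], "BH")
  S4Vectors::DataFrame(
    peak_id = if (!is.null(rownames(x$counts))) rownames(x$counts)
              else sprintf("peak_%05d", seq_along(p)),
    base_mean = mu, mean_target = m1, mean_rest = m2,
    log2fc = lfc, se = se, stat = stat, pvalue = p, padj = padj)
}

#' Label peaks as histology-specific
#'
#' A peak is assigned to a histology when its one-vs-rest test passes
#' both thresholds (`padj < padj_max` and `log2fc > log2fc_min`, both
#' strict); a peak passing in several histologies goes to the one with
#' the largest fold change; everything else is `"common"`.
#'
#' @param results Named list of [nbDifferential()] outputs, one per
#'   histology, over a common peak universe.
#' @param padj_max Adjusted-P threshold (default 0.001).
#' @param log2fc_min log2 fold-change threshold (default 3, strict).
#' @return Named character vector of labels over the peak universe.
#' @export
callHistologySpecific <- function(results, padj_max = 0.001,
                                  log2fc_min = 3) {
  ids <- results[[1]]$peak_id
  for (r in results)
    if (!identical(r$peak_id, ids))
      stop("results do not share a peak universe")
  lab <- rep("common", length(ids))
  best_fc <- rep(-Inf, length(ids))
  for (h in names(results)) {
    r <- results[[h]]
    hit <- !is.na(r$padj) & r$padj < padj_max & r$log2fc > log2fc_min
    better <- hit & r$log2fc > best_fc
    lab[better] <- h
    best_fc[better] <- r$log2fc[better]
  }
  setNames(lab, ids)
}

#' Spearman correlation clustering of samples
#'
#' Computes the sample-sample Spearman correlation of a (normalized)
#' peak-by-sample matrix and clusters samples by average linkage on the
#' distance `1 - rho`.
#'
#' @param m Normalized peaks x samples matrix.
#' @return List with `correlation` (samples x samples), `tree` (an
#'   `hclust`), and `order` (leaf order of sample names).
#' @export
sampleCorrelationCluster <- function(m) {
  m <- if (methods::is(m, "SummarizedExperiment"))
    SummarizedExperiment::assay(m) else as.matrix(m)
  if (ncol(m) < 3) stop("need at least 3 samples")
  constant <- apply(m, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(constant)) {
    warning("constant sample column(s): ",
            paste(colnames(m)[constant], collapse = ", "),
            "; correlations set to 0")
    rho[constant, ] <- 0
    rho[, constant] <- 0
    diag(rho) <- 1
  }
  tree <- hclust(as.dist(1 - rho), method = "average")
  list(correlation = rho, tree = tree,
       order = colnames(m)[tree$order])
}
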