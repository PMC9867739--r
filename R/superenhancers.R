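# ROSE-style super-enhancer calling: stitching, rank-signal elbow
# (slope-1 tangent) cutoff, nearest-gene assignment, and the TF-by-sample
# minimum-SE-rank matrix with its one-sided rank test.

#' Stitch enhancer peaks into regions
#'
#' Merges, transitively, peaks on the same chromosome separated by less
#' than `stitch_bp`; the `signal` of a stitched region is the sum over
#' its constituent peaks. Peaks within `tss_exclusion_bp` of a TSS can be
#' removed before stitching (off by default).
#'
#' @param peaks `GRanges` with a `signal` metadata column.
#' @param stitch_bp Maximum gap merged (default 12500); 0 merges only
#'   overlapping or book-ended peaks.
#' @param tss Optional width-1 `GRanges` of TSS positions.
#' @param tss_exclusion_bp Radius of the TSS exclusion (0 disables).
#' @return `GRanges` of stitched regions with `signal` and `n_peaks`.
#' @export
stitchPeaks <- function(peaks, stitch_bp = 12500, tss = NULL,
                        tss_exclusion_bp = 0) {
  if (is.null(peaks$signal)) peaks$signal <- peaks$score
  if (!is.null(tss) && tss_exclusion_bp > 0) {
    zone <- GenomicRanges::resize(tss, width = 2 * tss_exclusion_bp + 1,
                                  fix = "center")
    peaks <- peaks[!IRanges::overlapsAny(peaks, zone)]
  }
  if (length(peaks) == 0) return(GenomicRanges::GRanges())
  regions <- GenomicRanges::reduce(peaks,
                                   min.gapwidth = max(1L, stitch_bp))
  hits <- GenomicRanges::findOverlaps(peaks, regions)
  sig <- tapply(peaks$signal[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  npk <- tapply(S4Vectors::queryHits(hits),
                S4Vectors::subjectHits(hits), length)
  regions$signal <- as.numeric(sig[as.character(seq_along(regions))])
  regions$n_peaks <- as.integer(npk[as.character(seq_along(regions))])
  regions
}

# ROSE elbow: with ranks and signals both rescaled to [0, 1], the cutoff
# is the curve point whose tangent has slope 1; geometrically, the point
# minimizing the number of points below the slope-1 line through it.
.roseCutoffIndex <- function(signal_sorted) {
  n <- length(signal_sorted)
  slope <- (max(signal_sorted) - min(signal_sorted)) / n
  xs <- seq_len(n)
  below <- vapply(xs, function(i) {
    b <- signal_sorted[i] - slope * i
    sum(signal_sorted <= xs * slope + b)
  }, numeric(1))
  max(which(below == min(below)))
}

#' Call super-enhancers by the rank-signal elbow
#'
#' Regions are ordered by ascending signal and the cutoff is placed where
#' the tangent slope of the rescaled rank-signal curve equals one; every
#' region with signal strictly above the cutoff signal is a
#' super-enhancer. Ranks are assigned in descending signal order (rank 1
#' = highest signal).
#'
#' @param regions `GRanges` of stitched regions with `signal`.
#' @return `regions` with `rank` and `is_super` columns and a
#'   `cutoff_signal` attribute in `metadata`.
#' @export
callSuperenhancers <- function(regions) {
  if (length(regions) < 3) stop("need at least 3 stitched regions")
  sig <- regions$signal
  if (max(sig) == min(sig)) {
    warning("constant signal across regions; no super-enhancers called")
    regions$rank <- seq_along(regions)
    regions$is_super <- FALSE
    return(regions)
  }
  sorted <- sort(sig)
  cutoff <- sorted[.roseCutoffIndex(sorted)]
  ord <- order(-sig, as.integer(GenomicRanges::seqnames(regions)),
               GenomicRanges::start(regions))
  rank <- integer(length(sig))
  rank[ord] <- seq_along(sig)
  regions$rank <- rank
  regions$is_super <- sig > cutoff
  S4Vectors::metadata(regions)$cutoff_signal <- cutoff
  regions
}

#' Assign each stitched region to its nearest gene
#'
#' The gene whose TSS is nearest to the region midpoint wins; equidistant
#' TSSs are broken toward the smaller genomic coordinate. Regions on a
#' chromosome without any TSS are left unassigned with a warning.
#'
#' @param se `GRanges` of (super-)enhancer regions.
#' @param tss Width-1 `GRanges` with a `gene` metadata column.
#' @return `se` with an `assigned_gene` column.
#' @export
assignSeToGene <- function(se, tss) {
  if (length(tss) == 0) stop("empty TSS annotation")
  mid <- (GenomicRanges::start(se) + GenomicRanges::end(se)) %/% 2L
  gene <- rep(NA_character_, length(se))
  tss_chr <- as.character(GenomicRanges::seqnames(tss))
  se_chr <- as.character(GenomicRanges::seqnames(se))
  for (chr in unique(se_chr)) {
    sel <- se_chr == chr
    tsel <- which(tss_chr == chr)
    if (!length(tsel)) next
    pos <- GenomicRanges::start(tss)[tsel]
    o <- order(pos)
    pos <- pos[o]; cand_gene <- tss$gene[tsel][o]
    for (i in which(sel)) {
      d <- abs(pos - mid[i])
      hit <- which(d == min(d))
      gene[i] <- cand_gene[hit[which.min(pos[hit])]]
    }
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " region(s) on chromosomes without TSS ",
            "left unassigned")
  se$assigned_gene <- gene
  se
}

#' TF-by-sample minimum super-enhancer rank matrix
#'
#' For each TF and sample, the minimum rank over that sample's
#' super-enhancers assigned to the TF; TFs with no SE in a sample receive
#' the fill value, the maximum SE rank observed in any sample.
#'
#' @param se_calls Named list (per sample) of [callSuperenhancers()]
#'   outputs carrying `assigned_gene`.
#' @param tf_list TF symbols forming the matrix rows.
#' @return Integer matrix with a `fill_value` attribute.
#' @export
tfSeRankMatrix <- function(se_calls, tf_list) {
  supers <- lapply(se_calls, function(g) g[g$is_super])
  fill <- max(1L, max(unlist(lapply(supers, function(g) g$rank), use.names = FALSE),
                      na.rm = TRUE))
  m <- matrix(fill, nrow = length(tf_list), ncol = length(se_calls),
              dimnames = list(tf_list, names(se_calls)))
  for (s in names(se_calls)) {
    g <- supers[[s]]
    g <- g[!is.na(g$assigned_gene) & g$assigned_gene %in% tf_list]
    if (!length(g)) next
    mins <- tapply(g$rank, g$assigned_gene, min)
    m[names(mins), s] <- as.integer(mins)
  }
  attr(m, "fill_value") <- as.integer(fill)
  m
}

#' Differential super-enhancer rank test
#'
#' One-sided Wilcoxon rank-sum test per TF of whether its SE ranks in the
#' query histology are lower (better) than in the rest. TFs whose overall
#' average rank exceeds `mean_rank_max` are excluded beforehand.
#' Benjamini-Hochberg across tested TFs; pass at `fdr <= fdr_max`.
#'
#' @param rank_matrix Output of [tfSeRankMatrix()].
#' @param labels Histology per sample (matrix column).
#' @param histology Query histology.
#' @param fdr_max FDR threshold (default 0.10, inclusive).
#' @param mean_rank_max Exclusion threshold on the overall mean rank.
#' @return `DataFrame` with per-TF `pvalue`, `fdr`, `excluded`, `pass`.
#' @export
differentialSeRank <- function(rank_matrix, labels, histology,
                               fdr_max = 0.10, mean_rank_max = 1000) {
  g1 <- labels == histology
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need >= 2 samples per group")
  excluded <- rowMeans(rank_matrix) > mean_rank_max
  p <- rep(NA_real_, nrow(rank_matrix))
  for (i in which(!excluded))
    p[i] <- .rankSumOneSided(rank_matrix[i, g1], rank_matrix[i, !g1],
                             "less")
  fdr <- rep(NA_real_, length(p))
  fdr[!excluded] <- p.adjust(p[!excluded], "BH")
  S4Vectors::DataFrame(tf = rownames(rank_matrix), pvalue = p, fdr = fdr,
                       excluded = excluded,
                       pass = !excluded & !is.na(fdr) & fdr <= fdr_max)
}
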