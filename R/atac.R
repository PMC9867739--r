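# ATAC-seq "score per million" normalization, multi-sample consensus
# regions, and the full-containment repeat filter.

#' Score-per-million normalization of an ATAC peak set
#'
#' Rescales each peak's score (-log10 P from the caller) to
#' `spm = score / sum(score) * 1e6`, so scores sum to one million per
#' sample, then removes peaks with `spm <= 5` (inclusive boundary).
#'
#' @param peaks `GRanges` with a `score` metadata column.
#' @param spm_min Filter threshold; peaks at or below it are dropped.
#' @return The filtered `GRanges` with an added `spm` column.
#' @export
spmNormalize <- function(peaks, spm_min = 5) {
  if (is.null(peaks$score)) stop("peaks must carry a score column")
  total <- sum(peaks$score)
  if (total <= 0) stop("all peak scores are zero")
  peaks$spm <- peaks$score / total * 1e6
  peaks[peaks$spm > spm_min]
}

#' Consensus accessible regions across samples
#'
#' Applies [spmNormalize()] filtering per sample (unless already done)
#' and keeps the regions covered by at least `min_cover` samples,
#' breaking up peaks at coverage transitions.
#'
#' @param peaksets List of per-sample `GRanges` (already spm-filtered if
#'   `normalize = FALSE`).
#' @param min_cover Minimum number of covering samples (default 2).
#' @param normalize Run [spmNormalize()] on each sample first?
#' @return Disjoint sorted `GRanges` of consensus regions.
#' @export
buildAtacConsensus <- function(peaksets, min_cover = 2, normalize = TRUE) {
  if (length(peaksets) < 2) stop("need at least 2 samples")
  if (normalize) peaksets <- lapply(peaksets, spmNormalize)
  coverageRegions(peaksets, min_cover = min_cover)
}

#' Remove regions fully inside repeat elements
#'
#' A consensus region is dropped only when it lies entirely within the
#' union of repeat intervals; regions partially overlapping repeats are
#' kept intact.
#'
#' @param regions `GRanges` of consensus regions.
#' @param repeats `GRanges` repeat track (e.g. a RepeatMasker export).
#' @return `regions` minus the fully repeat-contained ones.
#' @export
filterRepeats <- function(regions, repeats) {
  if (length(repeats) == 0 || length(regions) == 0) return(regions)
  merged <- GenomicRanges::reduce(repeats)
  contained <- IRanges::overlapsAny(regions, merged, type = "within")
  regions[!contained]
}
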