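#' @import methods
#' @importFrom stats approx coef cor dbinom dist fisher.test hclust integrate
#'   kruskal.test lm median optimize p.adjust pbinom pchisq pnorm quantile
#'   rbeta rbinom rgamma rlnorm rmultinom rnbinom rpois runif sd setNames
#'   var wilcox.test binom.test as.dist cutree rexp
#' @importFrom utils head read.table write.table combn
NULL

# All genomic coordinates are held internally as GRanges (1-based, closed),
# the Bioconductor convention.  BED-family inputs (0-based, half-open) are
# converted at the reader/writer boundary, so half-open semantics such as
# "touching intervals do not overlap" fall out of the closed representation
# automatically.

#' Read a chromosome-sizes file
#'
#' Parses the standard two-column (chromosome, length) tab-separated file
#' into a named integer vector usable as `seqlengths`.
#'
#' @param path Path to a two-column TSV without header.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$chrom)
}

#' Read genomic intervals in BED, narrowPeak or interval-TSV dialects
#'
#' All three dialects are 0-based half-open on disk and are converted to
#' 1-based closed [GenomicRanges::GRanges] on read. For narrowPeak
#' (ENCODE 10-column) the 8th column, the peak's -log10(P value), becomes
#' the `score` metadata column; BED input without a score column gets
#' score 0. A `tsv` file must carry a header with at least
#' `chrom`, `start`, `end` and may carry `score` and `sample_id`.
#'
#' @param path File path.
#' @param format One of `"bed"`, `"narrowPeak"`, `"tsv"`.
#' @param sample_id Optional sample identifier stored in a `sample_id`
#'   metadata column.
#' @param genome Optional named vector of chromosome lengths; when given,
#'   intervals extending beyond a chromosome raise an error.
#' @return A sorted `GRanges` with `score` (and possibly `sample_id`)
#'   metadata columns.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100", "chr2\t5\t50"), bed)
#' readIntervals(bed, "bed")
#' @export
readIntervals <- function(path, format = c("bed", "narrowPeak", "tsv"),
                          sample_id = NULL, genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("interval TSV must have columns chrom, start, end")
    if (is.null(df$score)) df$score <- 0
    lineno <- seq_len(nrow(df)) + 1L   # header occupies line 1
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (format == "narrowPeak" && any(nf < 10))
      stop("malformed narrowPeak line ", which(nf < 10)[1],
           ": expected 10 columns")
    if (format == "bed" && any(nf < 3))
      stop("malformed BED line ", which(nf < 3)[1],
           ": expected at least 3 columns")
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop("malformed line ", bad[1], ": non-numeric coordinates")
    score <- if (format == "narrowPeak") {
      as.numeric(vapply(fields, `[[`, character(1), 8))
    } else if (all(nf >= 5)) {
      suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
    } else rep(0, length(chrom))
    score[is.na(score)] <- 0
    df <- data.frame(chrom = chrom, start = start, end = end, score = score,
                     stringsAsFactors = FALSE)
    lineno <- seq_along(lines)
  }
  bad <- which(df$end <= df$start | df$start < 0 | !nzchar(df$chrom))
  if (length(bad))
    stop("invalid interval at line ", lineno[bad[1]],
         ": require 0 <= start < end and non-empty chrom")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  gr$score <- df$score
  if (!is.null(df$sample_id)) gr$sample_id <- df$sample_id
  if (!is.null(sample_id)) gr$sample_id <- sample_id
  if (!is.null(genome)) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    missing_chr <- setdiff(chr, names(genome))
    if (length(missing_chr))
      stop("chromosome not in genome: ", missing_chr[1])
    if (any(BiocGenerics::end(gr) > unname(genome[chr])))
      stop("interval extends beyond chromosome length")
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  sort(gr)
}

#' Write intervals as BED
#'
#' Converts back to 0-based half-open coordinates. A `score` metadata
#' column, when present, is written as BED column 5 with a placeholder
#' name in column 4.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr))
  if (!is.null(gr$score)) {
    df$name <- if (!is.null(names(gr)) && all(nzchar(names(gr))))
      names(gr) else paste0("region_", seq_along(gr))
    df$score <- gr$score
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-peak overlap indicator
#'
#' For each interval of `a`, reports whether it shares at least one
#' nucleotide with any interval of `b`. Intervals that merely touch under
#' half-open coordinates (e.g. BED `[0,10)` and `[10,20)`) do not overlap.
#'
#' @param a,b `GRanges` objects.
#' @return Logical vector along `a`.
#' @export
overlapAny <- function(a, b) {
  suppressWarnings(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
}

# shared coverage machinery: sum of per-sample occupancy (each sample's
# ranges reduced first so a sample never counts twice at a base)
.sampleCoverage <- function(peaksets) {
  peaksets <- lapply(peaksets, GenomicRanges::reduce)
  all_chr <- unique(unlist(lapply(peaksets, function(g)
    as.character(GenomeInfoDb::seqnames(g)))))
  width_by_chr <- setNames(integer(length(all_chr)), all_chr)
  for (g in peaksets) {
    e <- tapply(BiocGenerics::end(g), as.character(GenomeInfoDb::seqnames(g)), max)
    width_by_chr[names(e)] <- pmax(width_by_chr[names(e)], e)
  }
  total <- NULL
  for (g in peaksets) {
    GenomeInfoDb::seqlevels(g) <- all_chr
    cvg <- GenomicRanges::coverage(g, width = as.list(width_by_chr))
    cvg <- IRanges::RleList(lapply(cvg, function(x) (x >= 1L) + 0L))
    total <- if (is.null(total)) cvg else total + cvg
  }
  total
}

#' Regions covered by at least `min_cover` samples
#'
#' Sweeps per-base coverage over a collection of per-sample peak sets and
#' returns the maximal regions where at least `min_cover` distinct samples
#' have a peak, breaking up peaks at coverage transitions. This is the
#' construction behind multi-sample consensus peak sets.
#'
#' @param peaksets A list of `GRanges`, one element per sample.
#' @param min_cover Minimum number of distinct covering samples.
#' @return Disjoint, sorted `GRanges`.
#' @examples
#' s1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' s2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' coverageRegions(list(s1, s2), min_cover = 2)   # chr1:51-100
#' @export
coverageRegions <- function(peaksets, min_cover = 2) {
  stopifnot(min_cover >= 1)
  peaksets <- peaksets[vapply(peaksets, length, integer(1)) > 0]
  if (length(peaksets) == 0) return(GenomicRanges::GRanges())
  total <- .sampleCoverage(peaksets)
  sliced <- IRanges::slice(total, lower = min_cover, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sliced)
  sort(gr)
}

#' Windowed multi-sample consensus
#'
#' Tiles the genome into fixed half-open windows (BED coordinates
#' `[k*w, (k+1)*w)`) and retains every window overlapped by peaks from at
#' least `min_samples` distinct samples; adjacent retained windows are
#' merged unless `merge = FALSE`. With `window_bp = 50` and
#' `min_samples = 2` this reproduces the consensus peak universe used for
#' allelic-imbalance testing.
#'
#' @param peaksets List of per-sample `GRanges`.
#' @param window_bp Window width in bp.
#' @param min_samples Minimum number of distinct samples per window.
#' @param merge Merge adjacent retained windows into maximal runs?
#' @return Sorted `GRanges` of retained (merged) windows.
#' @export
windowConsensus <- function(peaksets, window_bp = 50, min_samples = 2,
                            merge = TRUE) {
  stopifnot(window_bp >= 1)
  peaksets <- peaksets[vapply(peaksets, length, integer(1)) > 0]
  if (length(peaksets) < min_samples) return(GenomicRanges::GRanges())
  # snap each sample's reduced peaks outward to window boundaries; then a
  # window has >= k overlapping samples iff its bases have coverage >= k
  snapped <- lapply(peaksets, function(g) {
    g <- GenomicRanges::reduce(g)
    s <- BiocGenerics::start(g) - 1L          # back to 0-based
    e <- BiocGenerics::end(g)                 # half-open end
    s2 <- (s %/% window_bp) * window_bp
    e2 <- ((e + window_bp - 1L) %/% window_bp) * window_bp
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                           IRanges::IRanges(s2 + 1L, e2))
  })
  out <- coverageRegions(snapped, min_cover = min_samples)
  if (!merge && length(out)) {
    out <- unlist(GenomicRanges::tile(out, width = window_bp))
  }
  out
}
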