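# GWAS risk-SNP annotation: SNP density in peak sets, permutation
# enrichment against sampled background peaks, allele-specific
# expression, the AI-to-ASE linkage table, and the genotype-stratified
# signal test.

.asSnpGRanges <- function(snps) {
  if (methods::is(snps, "GRanges")) return(snps)
  GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, width = 1))
}

#' SNP density per base pair of a peak set
#'
#' Number of SNPs overlapping the peaks divided by the number of base
#' pairs covered (union of the peaks, double-counting removed).
#'
#' @param snps `GRanges` of width-1 SNP positions, or a `data.frame`
#'   with `chrom` and `pos`.
#' @param peaks `GRanges`.
#' @return Density in SNPs per bp.
#' @export
snpDensity <- function(snps, peaks) {
  gr <- .asSnpGRanges(snps)
  merged <- GenomicRanges::reduce(peaks)
  bp <- sum(GenomicRanges::width(merged))
  if (bp == 0) stop("peak set covers zero base pairs")
  sum(suppressWarnings(IRanges::overlapsAny(gr, merged))) / bp
}

#' Permutation enrichment of SNPs in a target peak set
#'
#' Compares the observed SNP density of the target peaks with densities
#' of `n_iter` random peak sets of the same size sampled without
#' replacement from the universe. In matched mode sampling is stratified
#' by chromosome and target-width size bin (deciles of target widths);
#' an exhausted bin falls back to the nearest size bin on the same
#' chromosome with a warning. The fold is observed density over the mean
#' background density and the empiric one-sided p-value uses the add-one
#' convention `(1 + b) / (1 + n_iter)`, so it is never smaller than
#' `1 / (n_iter + 1)`.
#'
#' @param snps SNP positions (`GRanges` or `data.frame`).
#' @param target_peaks `GRanges` of target (e.g. imbalanced) peaks.
#' @param universe_peaks `GRanges` of all candidate peaks.
#' @param n_iter Number of background iterations (default 10000).
#' @param matched Match background peaks by chromosome and size bin?
#' @param seed Optional seed (local to this call).
#' @return List with `observed_density`, `background_densities`, `fold`
#'   and `empiric_p`.
#' @export
permutationEnrichment <- function(snps, target_peaks, universe_peaks,
                                  n_iter = 10000, matched = FALSE,
                                  seed = NULL) {
  if (n_iter < 100) stop("n_iter must be at least 100")
  run <- function() {
    gr <- .asSnpGRanges(snps)
    observed <- snpDensity(gr, target_peaks)
    u_counts <- suppressWarnings(
      GenomicRanges::countOverlaps(universe_peaks, gr))
    u_width <- GenomicRanges::width(universe_peaks)
    n_t <- length(target_peaks)
    if (matched) {
      t_width <- GenomicRanges::width(target_peaks)
      brk <- unique(quantile(t_width, probs = seq(0, 1, 0.1)))
      bin_of <- function(w) pmax(1L, findInterval(w, brk,
                                                  rightmost.closed = TRUE))
      t_bin <- paste(as.character(GenomicRanges::seqnames(target_peaks)),
                     bin_of(t_width))
      u_bin_chr <- as.character(GenomicRanges::seqnames(universe_peaks))
      u_bin_sz <- bin_of(u_width)
      need <- table(t_bin)
      pools <- lapply(names(need), function(b) {
        parts <- strsplit(b, " ")[[1]]
        chr <- parts[1]; sz <- as.integer(parts[2])
        pool <- which(u_bin_chr == chr & u_bin_sz == sz)
        if (length(pool) < need[[b]]) {
          warning("size bin exhausted on ", chr,
                  "; falling back to nearest size bin")
          cand <- which(u_bin_chr == chr)
          pool <- cand[order(abs(u_bin_sz[cand] - sz))][
            seq_len(min(length(cand), max(need[[b]], length(pool))))]
        }
        pool
      })
      draws <- vapply(seq_len(n_iter), function(i) {
        sel <- unlist(lapply(seq_along(pools), function(j)
          sample(pools[[j]], min(need[[j]], length(pools[[j]])))))
        sum(u_counts[sel]) / sum(u_width[sel])
      }, numeric(1))
    } else {
      draws <- vapply(seq_len(n_iter), function(i) {
        sel <- sample.int(length(universe_peaks), n_t)
        sum(u_counts[sel]) / sum(u_width[sel])
      }, numeric(1))
    }
    fold <- observed / mean(draws)
    p <- (1 + sum(draws >= observed)) / (1 + n_iter)
    list(observed_density = observed, background_densities = draws,
         fold = fold, empiric_p = p)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Allele-specific expression calls per gene
#'
#' Two-sided binomial test of each gene's summed haplotype-1 fraction
#' against 0.5, Benjamini-Hochberg adjusted; ASE is called below
#' `alpha` (adjusted). Genes under `min_reads` total reads are excluded.
#'
#' @param ase_counts `data.frame` with `gene`, `hap1_reads`,
#'   `hap2_reads`.
#' @param min_reads Minimum total reads per gene (default 10).
#' @param alpha Adjusted-P threshold (default 0.01).
#' @return `DataFrame` with per-gene `pvalue`, `padj`, `ase`.
#' @export
aseGeneTest <- function(ase_counts, min_reads = 10, alpha = 0.01) {
  tot <- ase_counts$hap1_reads + ase_counts$hap2_reads
  keep <- tot >= min_reads & tot > 0
  d <- ase_counts[keep, ]
  p <- vapply(seq_len(nrow(d)), function(i)
    binom.test(d$hap1_reads[i], d$hap1_reads[i] + d$hap2_reads[i],
               0.5)$p.value, numeric(1))
  padj <- p.adjust(p, "BH")
  S4Vectors::DataFrame(gene = d$gene, hap1_reads = d$hap1_reads,
                       hap2_reads = d$hap2_reads, pvalue = p,
                       padj = padj, ase = padj < alpha)
}

#' Enrichment statistics of a 2 x 2 contingency table
#'
#' Row proportions, odds ratio (cross-product; `Inf` flagged for empty
#' cells) and the two-sided Fisher exact p-value (minimum-likelihood
#' method), with a chi-square cross-check.
#'
#' @param tab 2 x 2 matrix: rows = classes, columns = (in-category,
#'   not-in-category).
#' @return List with `prop1`, `prop2`, `odds_ratio`, `fisher_p`,
#'   `chisq_p`.
#' @export
contingencyStats <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  prop1 <- tab[1, 1] / sum(tab[1, ])
  prop2 <- tab[2, 1] / sum(tab[2, ])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(prop1 = prop1, prop2 = prop2, odds_ratio = or,
       fisher_p = fisher.test(tab)$p.value,
       chisq_p = suppressWarnings(stats::chisq.test(tab)$p.value))
}

#' Link chromatin allelic imbalance to allele-specific expression
#'
#' Classified SNPs (imbalanced vs balanced, each retained only with at
#' least `min_reads` reads) are marked "near ASE" when an ASE gene's TSS
#' lies within `window_bp`; the 2 x 2 table of class by proximity is
#' summarized by [contingencyStats()].
#'
#' @param snps `data.frame` with `chrom`, `pos`, logical `imbalanced`,
#'   and optionally `reads`.
#' @param ase_genes Character vector of genes with ASE.
#' @param tss Width-1 `GRanges` with a `gene` column.
#' @param window_bp Linkage window (default 50000).
#' @param min_reads Read filter applied when a `reads` column is present
#'   (default 50).
#' @return List with the `table`, proportions, `odds_ratio`, `fisher_p`.
#' @export
linkAiToAse <- function(snps, ase_genes, tss, window_bp = 50000,
                        min_reads = 50) {
  if (!is.null(snps$reads)) snps <- snps[snps$reads >= min_reads, ]
  if (!any(snps$imbalanced) || all(snps$imbalanced))
    stop("need both imbalanced and balanced SNPs")
  gr <- .asSnpGRanges(snps)
  ase_tss <- tss[tss$gene %in% ase_genes]
  near <- suppressWarnings(IRanges::overlapsAny(gr, ase_tss + window_bp))
  tab <- matrix(c(sum(snps$imbalanced & near),
                  sum(snps$imbalanced & !near),
                  sum(!snps$imbalanced & near),
                  sum(!snps$imbalanced & !near)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("imbalanced", "balanced"),
                                c("near_ase", "not_near")))
  stats <- contingencyStats(tab)
  c(list(table = tab), stats)
}

#' Genotype-stratified signal association (Kruskal-Wallis)
#'
#' Tests whether a per-sample signal (RPKM scale) differs across allele
#' dosage groups, with the tie-corrected Kruskal-Wallis H referred to
#' chi-square on (groups - 1) df. Identical values across all samples
#' yield H = 0 and p = 1.
#'
#' @param signal Numeric per-sample signal.
#' @param genotypes Per-sample allele dosage (0/1/2) or any grouping.
#' @return List with `H`, `df`, `pvalue`.
#' @export
genotypeSignalTest <- function(signal, genotypes) {
  g <- factor(genotypes)
  if (nlevels(g) < 2) stop("need at least 2 genotype groups")
  if (length(unique(signal)) == 1)
    return(list(H = 0, df = nlevels(g) - 1L, pvalue = 1))
  kt <- kruskal.test(signal, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       pvalue = kt$p.value)
}
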