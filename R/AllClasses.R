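#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges
NULL

#' Simulation configuration for a synthetic RCC cohort
#'
#' `SimConfig` captures every knob of the synthetic multi-histology cohort
#' generator: cohort layout, planted histology-specific peak effects,
#' master-TF planting, beta-binomial allelic-imbalance parameters and
#' GWAS-SNP enrichment. Defaults describe a desk-scale cohort of three
#' histologies (clear cell, papillary and chromophobe RCC) with six
#' samples each, 2,000 enhancer peaks, 300 transcription factors and 500
#' SNP-bearing peaks.
#'
#' @slot n_samples_per_histology Named integer, samples per histology
#'   (names `ccRCC`, `pRCC`, `chRCC`).
#' @slot n_peaks Number of peaks in the count universe.
#' @slot frac_specific Fraction of peaks planted histology-specific,
#'   split equally across the three histologies.
#' @slot log2fc_planted Planted one-vs-rest log2 fold change for specific
#'   peaks.
#' @slot nb_dispersion Negative-binomial dispersion of peak counts.
#' @slot n_tfs Number of transcription factors.
#' @slot n_master_tfs_per_histology Planted master TFs per histology.
#' @slot pi_imbalanced Planted mean allelic ratio for imbalanced peaks.
#' @slot rho_true Planted per-individual beta-binomial overdispersion.
#' @slot read_depth_snp Mean read depth per heterozygous SNP.
#' @slot n_snp_peaks Number of SNP-bearing peaks (subset of common peaks).
#' @slot frac_imbalanced Fraction of SNP-bearing peaks planted imbalanced.
#' @slot n_individuals_per_group Genotyped individuals per group (ccRCC
#'   and pRCC) in the allelic data.
#' @slot n_gwas_snps Number of GWAS catalog SNPs.
#' @slot gwas_enrichment_fold Planted fold enrichment of GWAS SNPs in
#'   imbalanced peaks relative to the background peak density.
#' @slot seed Integer random seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @export
setClass("SimConfig", representation(
  n_samples_per_histology = "integer",
  n_peaks = "integer",
  frac_specific = "numeric",
  log2fc_planted = "numeric",
  nb_dispersion = "numeric",
  n_tfs = "integer",
  n_master_tfs_per_histology = "integer",
  pi_imbalanced = "numeric",
  rho_true = "numeric",
  read_depth_snp = "numeric",
  n_snp_peaks = "integer",
  frac_imbalanced = "numeric",
  n_individuals_per_group = "integer",
  n_gwas_snps = "integer",
  gwas_enrichment_fold = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  h <- object@n_samples_per_histology
  if (!identical(sort(names(h)), sort(c("ccRCC", "pRCC", "chRCC"))))
    msg <- c(msg, "n_samples_per_histology must be named ccRCC, pRCC, chRCC")
  counts <- c(h, object@n_peaks, object@n_tfs,
              object@n_master_tfs_per_histology, object@n_snp_peaks,
              object@n_individuals_per_group, object@n_gwas_snps)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  for (f in c("frac_specific", "frac_imbalanced"))
    if (slot(object, f) <= 0 || slot(object, f) >= 1)
      msg <- c(msg, paste(f, "must lie in (0, 1)"))
  if (object@pi_imbalanced <= 0 || object@pi_imbalanced >= 1)
    msg <- c(msg, "pi_imbalanced must lie in (0, 1)")
  if (object@rho_true <= 0 || object@rho_true > 0.2)
    msg <- c(msg, "rho_true must lie in (0, 0.2]")
  if (3L * object@n_master_tfs_per_histology > object@n_tfs)
    msg <- c(msg, "more planted master TFs than TFs")
  if (object@n_snp_peaks > object@n_peaks)
    msg <- c(msg, "n_snp_peaks exceeds n_peaks")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class Constructor with desk-scale defaults.
#' @param n_samples_per_histology,n_peaks,frac_specific,log2fc_planted,nb_dispersion,n_tfs,n_master_tfs_per_histology,pi_imbalanced,rho_true,read_depth_snp,n_snp_peaks,frac_imbalanced,n_individuals_per_group,n_gwas_snps,gwas_enrichment_fold,seed
#'   See the slot documentation.
#' @return A validated `SimConfig`.
#' @export
SimConfig <- function(n_samples_per_histology = c(ccRCC = 6L, pRCC = 6L,
                                                  chRCC = 6L),
                      n_peaks = 2000L,
                      frac_specific = 0.15,
                      log2fc_planted = 4,
                      nb_dispersion = 0.05,
                      n_tfs = 300L,
                      n_master_tfs_per_histology = 5L,
                      pi_imbalanced = 0.7,
                      rho_true = 0.05,
                      read_depth_snp = 30,
                      n_snp_peaks = 500L,
                      frac_imbalanced = 0.2,
                      n_individuals_per_group = 10L,
                      n_gwas_snps = 300L,
                      gwas_enrichment_fold = 10,
                      seed = 1L) {
  new("SimConfig",
      n_samples_per_histology =
        setNames(as.integer(n_samples_per_histology),
                 names(n_samples_per_histology)),
      n_peaks = as.integer(n_peaks),
      frac_specific = frac_specific,
      log2fc_planted = log2fc_planted,
      nb_dispersion = nb_dispersion,
      n_tfs = as.integer(n_tfs),
      n_master_tfs_per_histology = as.integer(n_master_tfs_per_histology),
      pi_imbalanced = pi_imbalanced,
      rho_true = rho_true,
      read_depth_snp = read_depth_snp,
      n_snp_peaks = as.integer(n_snp_peaks),
      frac_imbalanced = frac_imbalanced,
      n_individuals_per_group = as.integer(n_individuals_per_group),
      n_gwas_snps = as.integer(n_gwas_snps),
      gwas_enrichment_fold = gwas_enrichment_fold,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  h <- object@n_samples_per_histology
  cat("SimConfig:",
      paste(sprintf("%s=%d", names(h), h), collapse = ", "), "samples;",
      object@n_peaks, "peaks (", round(100 * object@frac_specific),
      "% specific, log2FC", object@log2fc_planted, ");",
      object@n_tfs, "TFs (", 3L * object@n_master_tfs_per_histology,
      "masters );", object@n_snp_peaks, "SNP peaks ( pi =",
      object@pi_imbalanced, ", rho =", object@rho_true, "); seed",
      object@seed, "\n")
})

#' Synthetic RCC cohort with known ground truth
#'
#' Container produced by [simulateCohort()]. Every downstream analysis in
#' the package — differential peak calling, ATAC consensus building,
#' master-TF nomination, allelic-imbalance testing and GWAS enrichment —
#' can be run against its components, and the planted truth needed to
#' score recovery is in `simTruth()`.
#'
#' @slot config The generating [SimConfig-class].
#' @slot genome Named integer vector of chromosome lengths.
#' @slot peakSets Per-sample H3K27ac peak calls (list of `GRanges` with
#'   `score`).
#' @slot counts `SummarizedExperiment` of peak read counts (peaks x
#'   samples) with `histology` and `libsize` in `colData`.
#' @slot expression `SummarizedExperiment` of TF expression (FPKM).
#' @slot tfs Character vector of TF symbols.
#' @slot panCancerMeans TF x tumor-type matrix of mean expression used by
#'   the specificity (CaCTS-style) scoring.
#' @slot sePeakSets Per-sample enhancer peaks with `signal` for
#'   super-enhancer analysis.
#' @slot atacPeakSets Per-sample ATAC peak calls with `score` (-log10 P).
#' @slot tss `GRanges` of width-1 transcription start sites with `gene`
#'   and `strand`.
#' @slot pwms Named list of 4 x w column-stochastic position weight
#'   matrices.
#' @slot locusSequences `DNAStringSet` of TF-locus sequences with planted
#'   motif occurrences.
#' @slot locusRanges `GRanges` giving the genomic span of each locus
#'   sequence.
#' @slot allelic `data.frame` of phased heterozygous-SNP read counts.
#' @slot cnSegments `data.frame` of per-individual copy-number segments.
#' @slot gwas `data.frame` GWAS catalog (snp_id, chrom, pos, pheno,
#'   sig_flag).
#' @slot repeats `GRanges` repeat-element track.
#' @slot aseCounts `data.frame` of per-gene haplotype RNA read counts.
#' @slot truth List of planted ground truth (see [simTruth()]).
#' @export
setClass("RccCohort", representation(
  config = "SimConfig",
  genome = "integer",
  peakSets = "list",
  counts = "RangedSummarizedExperiment",
  expression = "SummarizedExperiment",
  tfs = "character",
  panCancerMeans = "matrix",
  sePeakSets = "list",
  atacPeakSets = "list",
  tss = "GRanges",
  pwms = "list",
  locusSequences = "DNAStringSet",
  locusRanges = "GRanges",
  allelic = "data.frame",
  cnSegments = "data.frame",
  gwas = "data.frame",
  repeats = "GRanges",
  aseCounts = "data.frame",
  truth = "list"
))

setMethod("show", "RccCohort", function(object) {
  cat("RccCohort:", length(object@peakSets), "samples,",
      nrow(object@counts), "peaks,", length(object@tfs), "TFs,",
      length(unique(object@allelic$individual)), "genotyped individuals,",
      nrow(object@gwas), "GWAS SNPs\n")
  cat("  truth:", sum(object@truth$specific_peak_labels != "common"),
      "specific peaks,", sum(!is.na(object@truth$master_tf_labels)),
      "master TFs,", sum(object@truth$ai_peaks$imbalanced),
      "imbalanced peaks\n")
})

#' @rdname RccCohort-class
#' @param object,x An `RccCohort`.
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname RccCohort-class
#' @export
setMethod("simTruth", "RccCohort", function(x) x@truth)

#' @rdname RccCohort-class
#' @export
setGeneric("peakSets", function(x) standardGeneric("peakSets"))
#' @rdname RccCohort-class
#' @export
setMethod("peakSets", "RccCohort", function(x) x@peakSets)

#' @rdname RccCohort-class
#' @export
setGeneric("peakCounts", function(x) standardGeneric("peakCounts"))
#' @rdname RccCohort-class
#' @export
setMethod("peakCounts", "RccCohort", function(x) x@counts)

#' @rdname RccCohort-class
#' @export
setGeneric("tfExpression", function(x) standardGeneric("tfExpression"))
#' @rdname RccCohort-class
#' @export
setMethod("tfExpression", "RccCohort", function(x) x@expression)

#' @rdname RccCohort-class
#' @export
setGeneric("allelicCounts", function(x) standardGeneric("allelicCounts"))
#' @rdname RccCohort-class
#' @export
setMethod("allelicCounts", "RccCohort", function(x) x@allelic)

#' @rdname RccCohort-class
#' @export
setGeneric("gwasCatalog", function(x) standardGeneric("gwasCatalog"))
#' @rdname RccCohort-class
#' @export
setMethod("gwasCatalog", "RccCohort", function(x) x@gwas)
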