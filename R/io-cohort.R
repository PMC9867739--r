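# Disk round-trip for the synthetic cohort: every artifact is written in
# the same standard plain-text formats the readers consume, plus a truth
# JSON and a YAML configuration.

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [SimConfig()] arguments.
#' @return A validated [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$n_samples_per_histology))
    args$n_samples_per_histology <- unlist(args$n_samples_per_histology)
  do.call(SimConfig, args)
}

#' Write a simulation configuration as YAML
#'
#' @param config A [SimConfig-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSimConfig <- function(config, path) {
  slots <- methods::slotNames("SimConfig")
  x <- lapply(slots, function(s) {
    v <- methods::slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(x) <- slots
  yaml::write_yaml(x, path)
  invisible(path)
}

.writeNarrowPeak <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = paste0("pk", seq_along(gr)),
                   score = round(pmin(1000, gr$score * 10)),
                   strand = ".",
                   signal = gr$score,
                   pval = gr$score,
                   qval = -1,
                   summit = GenomicRanges::width(gr) %/% 2L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export a synthetic cohort to standard formats
#'
#' Writes per-sample peak calls as narrowPeak, count/expression matrices
#' and label sidecars as TSV, the TF list as plain text, PWMs in MEME
#' minimal format, locus sequences as FASTA, TSS/repeat tracks as BED,
#' allelic counts / copy-number segments / GWAS catalog / ASE counts as
#' TSV, the ground truth as JSON, the configuration as YAML and the
#' genome as a chromosome-sizes file.
#'
#' @param cohort An [RccCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "atac"), showWarnings = FALSE)
  for (s in names(cohort@peakSets))
    .writeNarrowPeak(cohort@peakSets[[s]],
                     file.path(dir, "peaks", paste0(s, ".narrowPeak")))
  for (s in names(cohort@atacPeakSets))
    .writeNarrowPeak(cohort@atacPeakSets[[s]],
                     file.path(dir, "atac", paste0(s, ".narrowPeak")))

  cm <- SummarizedExperiment::assay(cohort@counts)
  write.table(data.frame(peak_id = rownames(cm), cm,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- SummarizedExperiment::colData(cohort@counts)
  write.table(data.frame(sample = rownames(cd),
                         histology = cd$histology,
                         libsize = cd$libsize),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  em <- SummarizedExperiment::assay(cohort@expression)
  write.table(data.frame(gene = rownames(em), em, check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(cohort@tfs, file.path(dir, "tfs.txt"))
  write.table(data.frame(tf = rownames(cohort@panCancerMeans),
                         cohort@panCancerMeans, check.names = FALSE),
              file.path(dir, "pan_cancer_means.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  writeMemePwms(cohort@pwms, file.path(dir, "motifs.meme"))
  Biostrings::writeXStringSet(cohort@locusSequences,
                              file.path(dir, "locus_sequences.fa"))
  tss <- cohort@tss
  write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(tss)),
                         start = GenomicRanges::start(tss) - 1L,
                         end = GenomicRanges::end(tss),
                         gene = tss$gene, score = 0,
                         strand = as.character(BiocGenerics::strand(tss))),
              file.path(dir, "tss.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(cohort@repeats, file.path(dir, "repeats.bed"))

  write.table(cohort@allelic, file.path(dir, "allelic_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort@cnSegments, file.path(dir, "cn_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort@gwas, file.path(dir, "gwas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort@aseCounts, file.path(dir, "ase_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  writeSimConfig(cohort@config, file.path(dir, "config.yaml"))
  write.table(data.frame(names(cohort@genome), unname(cohort@genome)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
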