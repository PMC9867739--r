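# Core regulatory circuitry: MEME-format PWM I/O, log-odds motif
# scanning restricted to open chromatin, the mutual-motif auto-regulatory
# TF graph, maximal-clique enumeration and the clique enrichment score.

#' Read PWMs from a MEME minimal motif file
#'
#' Parses `MOTIF` blocks with their letter-probability matrices into
#' column-stochastic 4 x w matrices (rows A, C, G, T).
#'
#' @param path Path to a MEME minimal format file.
#' @return Named list of PWM matrices.
#' @export
readMemePwms <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  pwms <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1]]), numeric(4)))
    pwm <- t(m)
    rownames(pwm) <- c("A", "C", "G", "T")
    pwms[[name]] <- pwm
  }
  pwms
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms Named list of 4 x w column-stochastic matrices.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMemePwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (nm in names(pwms)) {
    pwm <- pwms[[nm]]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(pwm))), con)
    writeLines(apply(pwm, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# best log-odds score (uniform background, both strands) of a PWM on a
# sequence given as integer codes 1..4; NA codes poison their windows
.pwmBestScore <- function(codes, logodds) {
  w <- ncol(logodds)
  L <- length(codes) - w + 1L
  if (L < 1L) return(-Inf)
  score <- function(cd) {
    total <- numeric(L)
    for (j in seq_len(w)) {
      v <- logodds[, j][cd[j:(j + L - 1L)]]
      v[is.na(v)] <- NA_real_
      total <- total + v
    }
    max(total, na.rm = !all(is.na(total)))
  }
  fwd <- score(codes)
  rev_codes <- 5L - rev(codes)
  max(fwd, score(rev_codes), na.rm = TRUE)
}

#' Scan sequences for PWM occurrences
#'
#' Log-odds scan against a uniform background over both strands. A
#' sequence carries a hit for a PWM when its best window score reaches
#' the threshold, expressed by default as a fraction of the PWM's maximum
#' attainable score. Windows containing non-ACGT symbols are skipped with
#' a warning.
#'
#' @param pwms Named list of column-stochastic PWMs.
#' @param sequences Named character vector or `DNAStringSet`.
#' @param threshold Hit threshold.
#' @param relative When `TRUE` (default) `threshold` is a fraction of
#'   each PWM's maximum score; otherwise an absolute log-odds score.
#' @return Logical matrix, PWMs x sequences.
#' @export
scanMotifs <- function(pwms, sequences, threshold = 0.9, relative = TRUE) {
  seqs <- as.character(sequences)
  names(seqs) <- if (!is.null(names(sequences))) names(sequences)
                 else seq_along(seqs)
  codes <- lapply(seqs, function(s)
    match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T")))
  if (any(vapply(codes, anyNA, logical(1))))
    warning("non-ACGT symbols found; affected windows skipped")
  hits <- matrix(FALSE, nrow = length(pwms), ncol = length(seqs),
                 dimnames = list(names(pwms), names(seqs)))
  for (p in names(pwms)) {
    lo <- log2(pmax(pwms[[p]], 1e-9) / 0.25)
    cut <- if (relative) threshold * sum(apply(lo, 2, max)) else threshold
    hits[p, ] <- vapply(codes, function(cd)
      .pwmBestScore(cd, lo) >= cut, logical(1))
  }
  hits
}

#' Build the auto-regulatory TF graph for one sample
#'
#' Nodes are TFs that are expressed, associated with a super-enhancer in
#' the sample, and self-regulating (their own motif occurs in the open
#' part of their own SE region). The motif search for TF `b`'s region is
#' restricted to the intersection of the SE with open chromatin when an
#' ATAC consensus is supplied. An undirected edge joins `a` and `b` when
#' each TF's motif occurs in the other's region (mutual regulation).
#'
#' @param se_calls [callSuperenhancers()] output with `assigned_gene` for
#'   one sample.
#' @param expressed_tfs TF symbols considered expressed in the sample.
#' @param pwms Named PWM list (per TF).
#' @param sequences `DNAStringSet` (or named character) of TF locus
#'   sequences, named by TF.
#' @param seq_ranges `GRanges`, named by TF, giving each sequence's
#'   genomic span.
#' @param atac Optional `GRanges` of open-chromatin consensus; motif
#'   scanning is confined to SE intersected with it.
#' @param threshold Relative motif-score threshold (see [scanMotifs()]).
#' @return An undirected `igraph` whose vertices are the self-regulating
#'   TFs.
#' @export
buildCliqueGraph <- function(se_calls, expressed_tfs, pwms, sequences,
                             seq_ranges, atac = NULL, threshold = 0.9) {
  supers <- se_calls[se_calls$is_super & !is.na(se_calls$assigned_gene)]
  cand <- intersect(intersect(unique(supers$assigned_gene), expressed_tfs),
                    intersect(names(pwms), names(seq_ranges)))
  if (!length(cand))
    return(igraph::make_empty_graph(0, directed = FALSE))
  # open scan region per candidate TF, as sequence-local substrings
  region_seq <- setNames(character(length(cand)), cand)
  seqs <- as.character(sequences)
  for (tf in cand) {
    se <- supers[supers$assigned_gene == tf]
    scan <- GenomicRanges::intersect(se, seq_ranges[tf],
                                     ignore.strand = TRUE)
    if (!is.null(atac))
      scan <- GenomicRanges::intersect(scan, atac, ignore.strand = TRUE)
    if (!length(scan)) { region_seq[tf] <- ""; next }
    off <- GenomicRanges::start(seq_ranges[tf])
    # segments are joined with an N spacer wide enough that no motif
    # window can straddle a junction
    region_seq[tf] <- paste(substring(seqs[[tf]],
                                      GenomicRanges::start(scan) - off + 1L,
                                      GenomicRanges::end(scan) - off + 1L),
                            collapse = strrep("N", 30L))
  }
  nonempty <- cand[nzchar(region_seq[cand])]
  if (!length(nonempty))
    return(igraph::make_empty_graph(0, directed = FALSE))
  hits <- suppressWarnings(
    scanMotifs(pwms[nonempty], region_seq[nonempty],
               threshold = threshold))
  selfreg <- nonempty[diag(hits[nonempty, nonempty, drop = FALSE])]
  adj <- hits[selfreg, selfreg, drop = FALSE] &
    t(hits[selfreg, selfreg, drop = FALSE])
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Enumerate maximal cliques
#'
#' Maximal cliques of at least two TFs, via Bron-Kerbosch with pivoting.
#'
#' @param graph Undirected `igraph`.
#' @return List of character vectors of TF names (empty for an empty
#'   graph).
#' @export
enumerateCliques <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list())
  lapply(igraph::max_cliques(graph, min = 2),
         function(v) sort(names(v)))
}

#' Clique enrichment score
#'
#' For each TF, the exact fraction of the sample's cliques containing it;
#' 0 for every TF when there are no cliques.
#'
#' @param cliques List of cliques (character vectors).
#' @param tf_list TF universe.
#' @return Named numeric vector of CES values in \[0, 1\].
#' @export
cliqueEnrichmentScore <- function(cliques, tf_list) {
  ces <- setNames(numeric(length(tf_list)), tf_list)
  if (!length(cliques)) return(ces)
  tab <- table(unlist(cliques))
  present <- intersect(names(tab), tf_list)
  ces[present] <- as.numeric(tab[present]) / length(cliques)
  ces
}

#' Differential clique enrichment test
#'
#' One-sided Mann-Whitney U test per TF of whether its CES is greater in
#' the query histology than in the rest. TFs averaging below `min_ces`
#' in the query histology are excluded first; Benjamini-Hochberg across
#' tested TFs; pass at `fdr < fdr_max`.
#'
#' @param ces_matrix TF x sample CES matrix.
#' @param labels Histology per sample.
#' @param histology Query histology.
#' @param fdr_max FDR threshold (default 0.1, strict).
#' @param min_ces Minimum average query CES (default 0.05).
#' @return `DataFrame` with per-TF `pvalue`, `fdr`, `excluded`, `pass`.
#' @export
differentialCes <- function(ces_matrix, labels, histology, fdr_max = 0.1,
                            min_ces = 0.05) {
  g1 <- labels == histology
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need >= 2 samples per group")
  excluded <- rowMeans(ces_matrix[, g1, drop = FALSE]) < min_ces
  p <- rep(NA_real_, nrow(ces_matrix))
  for (i in which(!excluded))
    p[i] <- .rankSumOneSided(ces_matrix[i, g1], ces_matrix[i, !g1],
                             "greater")
  fdr <- rep(NA_real_, length(p))
  fdr[!excluded] <- p.adjust(p[!excluded], "BH")
  S4Vectors::DataFrame(tf = rownames(ces_matrix), pvalue = p, fdr = fdr,
                       excluded = excluded,
                       pass = !excluded & !is.na(fdr) & fdr < fdr_max)
}
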