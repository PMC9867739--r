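---
title: "Methods and design notes for rccRegulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rccRegulome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rccRegulome` charts histology-specific regulatory landscapes across the
three major renal cell carcinoma subtypes (clear cell, papillary,
chromophobe) and tests inherited risk variation for regulatory effects
via chromatin allelic imbalance. This vignette records the statistical
models, the tunable parameters and their defaults, the design decisions
taken where the methodology left genuine choices, what the synthetic
cohort generator emulates, and the package's known limitations. Every
empirical number mentioned here is one the test suite or
`scripts/acceptance.R` computes.

## Coordinates and interval algebra

All coordinates live in `GRanges` (1-based, closed). BED-family input
(0-based, half-open) is converted at the reader boundary, which makes
half-open semantics automatic: two peaks overlap iff they share at least
one nucleotide, and touching BED intervals do not overlap. Multi-sample
consensus regions (`coverageRegions`) count *distinct samples* per base
(each sample's peaks are reduced first), and break peaks at coverage
transitions. The allelic-imbalance peak universe (`windowConsensus`)
tiles the genome into 50-bp half-open windows, keeps windows overlapped
by peaks from two or more samples, and merges adjacent retained windows;
merging is a package choice and can be disabled (`merge = FALSE`),
which returns the raw retained windows instead.

## Differential enhancer calling

Counts are scaled to reads per million of each sample's mapped reads and
quantile-normalized (`limma::normalizeQuantiles`, ties averaged within
their rank range; with heavily tied integer columns the post-
normalization distributions agree only up to tie-averaging, exactly on
tie-free data). The one-vs-rest test is a two-group negative-binomial
Wald test written for this package rather than a wrapper around an
external differential-expression engine: per-peak dispersion is
estimated by method of moments from pooled within-group variances,
shrunk in log space (equal weights) toward a fitted mean–dispersion
trend `a0 + a1/mu`, floored at 1e-8 and capped at 10; the Wald statistic
is the log2 fold change of group means (pseudocount 1) over its
delta-method standard error `sqrt(1/(n1 m1) + disp/n1 + 1/(n2 m2) +
disp/n2)/ln 2`, referred two-sided to the standard normal.
Exact numeric agreement with any specific external implementation is not
a contract of this module; its contracts are type-I control (the suite
checks the null rejection rate at alpha = 0.05 within binomial error
over 2,000 null peaks) and planted-truth recovery. All-zero peaks get
`NA` and are excluded from the Benjamini–Hochberg denominator.

Labeling uses strict inequalities (P~adj~ < 0.001, log2FC > 3, the
operational thresholds); a peak passing in several histologies is
assigned to the one with the largest fold change — conflicts are
vanishingly rare under one-vs-rest tests but the rule makes the output a
partition. Sample QC is Spearman correlation with average-linkage
clustering on `1 - rho`; constant samples get correlation 0 with a
warning.

## Master-TF nomination

**Differential expression.** One-sided Wilcoxon rank-sum (query
greater), exact by full enumeration of group splits whenever both groups
have at most 8 samples (average ranks, so ties are handled exactly;
`wilcox.test`'s normal approximation with continuity correction
otherwise). TFs whose best per-histology mean is under 10 FPKM are
excluded before testing. The printed pass rule combines FDR < 0.1,
log2FC ≥ 1 and a 10-TPM minimum; we read the TPM minimum as an
additional filter (columns rescaled to sum 1e6) and apply both. log2FC
is the log of the ratio of group means with a 1-FPKM pseudocount
(log-of-means; mean-of-logs is the other defensible reading but is
unstable at zeros).

**Specificity score.** Per-type mean expression is shifted so the
global minimum is zero; zero means are replaced by 1e-17; each TF's
profile is normalized to sum 1 and compared with the one-hot profile of
the query type by base-2 Jensen–Shannon divergence. The score is
`1 - sqrt(JSD)`: a perfectly query-specific TF has divergence 0 and
score 1, so "high-specificity" ranking is by the score, not by the raw
divergence (which would be 0 for the most specific TF — the
transformation resolves that ambiguity). Candidates are the
intersection of the top 5 % by score and the top 5 % by query-type mean
expression, ties at either quantile boundary included.

**Super-enhancer rank.** Peaks gapped by less than 12,500 bp are
stitched (default; TSS exclusion available but off, since the source
method's run parameters are not stated — both are configurable). The
elbow follows the ROSE convention: with ranks and signals rescaled to
[0, 1], the cutoff is the curve point whose slope-1 tangent leaves the
fewest points below it (ties broken toward the higher cutoff, the
conservative side); regions strictly above the cutoff signal are
super-enhancers, and rank 1 is the highest signal. Each region is
assigned to the gene whose TSS is nearest its midpoint (ties toward the
smaller coordinate). The TF × sample matrix holds the minimum rank of
the TF's SEs, with absent TFs filled by the maximum SE rank observed in
any sample; TFs averaging worse than rank 1000 are excluded, and the
one-sided test (query ranks lower) passes at FDR ≤ 0.10.

**Clique enrichment.** Nodes are TFs that are expressed (≥ 10 FPKM by
default), SE-associated, and self-regulating — their own motif occurs in
the open part of their own SE region (the self-regulation requirement
follows core-regulatory-circuitry convention). Motif occurrence is a
log-odds PWM scan against a uniform background on both strands, with the
hit threshold expressed as a fraction (default 0.9) of the PWM's maximum
attainable score; windows containing non-ACGT symbols are skipped.
Edges are mutual occurrences; maximal cliques (size ≥ 2) come from
igraph's Bron–Kerbosch with pivoting, which the suite checks against
exhaustive subset enumeration on every graph with up to six nodes. CES
is the exact fraction of cliques containing the TF; the differential
test excludes TFs averaging CES < 0.05 in the query histology and passes
at FDR < 0.1.

**Consensus.** A master TF must be significantly differentially
expressed *and* pass at least one of the three orthogonal analyses.

## Chromatin allelic imbalance

Reads are modeled as `hap1 | total ~ BetaBin(pi, rho)` with
`alpha = pi (1 - rho)/rho`, `beta = (1 - pi)(1 - rho)/rho`; `rho = 0`
is the binomial limit, and the log-pmf (via log-gamma) matches a
Beta-mixture quadrature oracle to 1e-8 across a 100-point grid in the
tests.

`rho` is estimated per individual within copy-number strata (deciles of
the individual's copy-number level; equal levels always share a
stratum), anchored at `pi = 0.5`: joint (`pi`, `rho`) estimation per
stratum is unstable at realistic read depths, and the null anchoring
makes the estimate conservative. Strata with fewer than 50 usable SNPs
(≥ 5 reads) inherit the individual's global estimate; estimates are
capped at 0.2. Because imbalanced SNPs also enter this null-anchored
fit, `rho` is mildly overestimated when imbalance is common — on the
synthetic cohort (20 % of SNP-bearing peaks imbalanced at `pi = 0.7`)
the median estimate is ~0.07 against a planted 0.05, a deliberate
conservatism that costs a little power rather than inflating type I.

Per SNP, phased counts across individuals are tested by the LRT of
`pi = 0.5` against a free `pi` (bounded search on [0.005, 0.995],
tolerance 1e-6), 1 df; differential imbalance between groups is the LRT
of shared-`pi` against per-group `pi`, 1 df. The testing unit is the
SNP (counts per individual at that SNP), aggregated to peaks by
Bonferroni over the peak's SNPs and the most significant corrected
value; q-values across peaks are Benjamini–Hochberg (equivalent to
Storey's estimator with pi0 = 1 — conservative and reproducible, where a
data-dependent pi0 would not be), with imbalance at q < 0.05.
Group-specific peaks require (1) imbalance in the group, (2) significant
differential imbalance, and (3) no imbalance in the other group alone;
peaks imbalanced in both groups are "shared".

## GWAS enrichment and ASE linkage

Enrichment compares the SNP density (SNPs per covered bp, union
semantics) of the target peaks with random peak sets of the same size
drawn without replacement from the universe; matched mode stratifies by
chromosome and decile-of-target-width size bins, falling back to the
nearest size bin with a warning when a bin is exhausted. The empiric
one-sided p uses the add-one convention `(1 + b)/(1 + N)`, so it can
never be zero. Background densities use per-peak count/width sums
(identical to union semantics whenever the sampled peaks are disjoint,
as consensus peak sets are). ASE is a two-sided binomial test per gene
against 0.5 with BH adjustment (ASE at adjusted p < 0.01; a
beta-binomial variant for overdispersed RNA is a natural extension, see
limitations). The AI–ASE linkage table uses a 50-kb TSS window and a
50-read filter, and reports both proportions, the cross-product odds
ratio and the two-sided Fisher exact p (minimum-likelihood method) with
a chi-square cross-check.

## The synthetic cohort

`simulateCohort` emulates a desk-scale multi-histology cohort on a
four-chromosome toy genome (three 10-Mb chromosomes carry the 2,000-peak
enhancer universe, SNPs and the GWAS catalog; one 30-Mb chromosome
carries TF and decoy gene loci for the SE and clique analyses).
Defaults describe the study conditions the recovery tests run under: 6
samples per histology; 15 % of peaks histology-specific at a planted
log2 fold change of 4 with NB dispersion 0.05 (a planted effect exactly
at the calling threshold of 3 would, by symmetry of the estimator, fail
the strict fold-change cut about half the time regardless of sequencing
power, so the planted effect sits above the threshold, as real
subtype-defining enhancers do); 300 TFs with 5 planted masters per
histology at ≥ 10 FPKM in their histology and ~2 FPKM elsewhere, wired
into mutual-motif cliques via planted 12-mer consensus sites within
open chromatin at their loci; 500 SNP-bearing peaks of which 20 % are
imbalanced at `pi = 0.7` (30 % ccRCC-only, 30 % pRCC-only, 40 % shared)
with `rho = 0.05`, 10 genotyped individuals per group at mean depth 30.

GWAS SNPs are planted so that the density in imbalanced peaks is the
configured fold (default 10) times the *universe-wide* peak density —
the exact background the permutation estimator measures — which makes
the planted fold recoverable; planting relative to non-imbalanced peaks
alone would attenuate every estimate by `(A+B)/(fold·A + B)` for
imbalanced/background footprints `A`/`B`. Residual attenuation (the
recovered fold is typically 8–9) comes from 50-bp consensus-window
padding of discovered peaks and from imbalanced peaks being legitimate
members of the sampling universe.

The generator does **not** emulate read-level artifacts (mapping bias,
GC effects), linkage disequilibrium, realistic genomic sequence
composition, overlapping genes, or histology-correlated library
composition. Passing recovery tests therefore demonstrates the
statistical machinery is correct and calibrated under its model
assumptions — not that upstream read processing issues (handled in
practice by WASP-style filtering and careful peak calling) are absorbed.

## Numerical choices and problem sizes

One-dimensional optimizations use `stats::optimize` (golden
section/parabolic), tolerance 1e-6, bounds [1e-6, 0.2] for `rho` and
[0.005, 0.995] for `pi`; LRT statistics are floored at 0. Exact
rank-sum enumeration is used up to 8 samples per group (`combn` over all
splits). Quantile normalization delegates to limma; cliques to igraph;
all other statistics are base R. The test suite and acceptance script
size their simulations for a single CPU: 2,000-peak null matrices,
10,000 null SNP-peaks for the LRT type-I check in the suite (2,000 in
the acceptance script), 100–200 replicates per `pi`-recovery point,
400–2,000 permutation iterations. The full suite runs in about three
minutes; the acceptance script in about one.

## Known limitations

* The NB Wald test is a deliberately compact re-implementation; it does
  not provide outlier replacement, Cook's filtering, or shrunken fold
  changes.
* `rho` estimation is null-anchored and therefore conservative when a
  large fraction of SNPs is truly imbalanced (see above).
* The ASE test is binomial; RNA overdispersion beyond haplotype effects
  will inflate ASE calls at very high depth.
* The permutation estimator's universe includes the targets (as in the
  source procedure); for targets covering a large fraction of the
  universe the fold is intrinsically attenuated toward 1.
* LD-score-regression-based enrichment, fine-mapping, and eQTL
  integration are out of scope; the permutation estimator is the
  implemented enrichment path.
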