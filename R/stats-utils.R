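# One-sided Wilcoxon / Mann-Whitney rank-sum p-value: exact permutation
# enumeration (average ranks, so ties are handled) when both groups have
# at most `exact_max` samples, normal approximation with continuity and
# tie correction otherwise.
.rankSumOneSided <- function(x, y, alternative = c("greater", "less"),
                             exact_max = 8) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  if (max(n1, n2) <= exact_max) {
    splits <- combn(n1 + n2, n1)
    stat <- colSums(matrix(r[splits], nrow = n1))
    if (alternative == "greater") mean(stat >= obs)
    else mean(stat <= obs)
  } else {
    suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value)
  }
}
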