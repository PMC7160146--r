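#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the observed genotype counts of a biallelic
#' variant: given the allele-count margins, the probability of every possible
#' heterozygote count is evaluated (via the stable ratio recurrence between
#' adjacent heterozygote counts) and the p-value is the sum of probabilities
#' no larger than that of the observed table — the standard exact HWE test,
#' not the mid-p variant. The test is symmetric in allele relabelling.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative integers,
#'   at least one genotype observed).
#' @return Exact p-value in (0, 1]; monomorphic tables give 1.
#' @export
#' @examples
#' hwe_exact_test(57, 14, 50)   # strong heterozygote deficit
#' hwe_exact_test(25, 50, 25)   # perfect HWE proportions
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0L) abort("at least one genotype must be observed")
  # rare allele count (symmetry in allele relabelling)
  n_a <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_a == 0L) return(1)

  # heterozygote counts compatible with the margins share the parity of n_a
  # (n_a <= n always holds once the rarer allele is used)
  h_vals <- seq.int(n_a %% 2L, n_a, by = 2L)
  probs <- numeric(length(h_vals))
  probs[1L] <- 1
  for (k in seq_along(h_vals)[-1L]) {
    h <- h_vals[k - 1L]
    n_aa <- (n_a - h) / 2           # rare homozygotes at h
    n_bb <- n - n_aa - h            # common homozygotes at h
    # P(h + 2) / P(h)
    probs[k] <- probs[k - 1L] * 4 * n_aa * n_bb / ((h + 2) * (h + 1))
    if (probs[k] > 1e280) {  # keep the running product finite at large n
      probs[1:k] <- probs[1:k] / 1e280
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  if (is.na(p_obs)) abort("observed heterozygote count incompatible with margins")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
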