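#' Analytic case-control power under the additive risk model
#'
#' Computes power to detect a risk variant in a case-control sample under
#' the additive genotypic-relative-risk model: penetrances proportional to
#' (1, grr, 2 grr - 1) scaled so the population risk equals the prevalence
#' `prevalence_k`; expected risk-allele frequencies in cases and controls by
#' Bayes' rule; and a two-sided normal test comparing the two expected
#' frequencies with per-subject sample sizes and unpooled variance (the
#' parameterisation of classic genetic power calculators for
#' population-based case-control designs).
#'
#' @param maf Risk-allele frequency in (0, 0.5].
#' @param grr Genotypic relative risk (>= 1; the per-allele risk ratio on
#'   the penetrance scale).
#' @param prevalence_k Lifetime risk (default 0.01).
#' @param alpha Type-I error level (two-sided).
#' @param n_cases,n_controls Sample sizes.
#' @return Power in [0, 1]; `grr = 1` returns `alpha` (the null identity).
#' @export
#' @examples
#' cc_power(maf = 0.25, grr = 2, alpha = 5e-8,
#'          n_cases = 1162, n_controls = 936)
cc_power <- function(maf, grr, prevalence_k = 0.01, alpha,
                     n_cases, n_controls) {
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5]")
  if (grr < 1) abort("`grr` must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  fr <- expected_cc_freqs(maf, grr, prevalence_k)
  if (grr == 1) return(alpha)
  d <- fr$p_case - fr$p_control
  s1 <- sqrt(fr$p_case * (1 - fr$p_case) / n_cases +
               fr$p_control * (1 - fr$p_control) / n_controls)
  q <- qnorm(1 - alpha / 2)
  # two-sided rejection; the lower tail is negligible for grr > 1
  pnorm(d / s1 - q) + pnorm(-d / s1 - q)
}

# Penetrances under the additive model scaled to population risk K, and the
# implied expected case/control risk-allele frequencies.
expected_cc_freqs <- function(maf, grr, K) {
  p <- maf
  q <- 1 - p
  gf <- c(q^2, 2 * p * q, p^2)
  fmult <- c(1, grr, 2 * grr - 1)
  f <- fmult * K / sum(fmult * gf)
  if (f[3] > 1) {
    abort("implied homozygote penetrance exceeds 1 (grr too large for K, maf)")
  }
  list(
    penetrance = f,
    p_case = (f[2] * p * q + f[3] * p^2) / K,
    p_control = ((1 - f[2]) * p * q + (1 - f[3]) * p^2) / (1 - K)
  )
}

#' Minimal detectable genotypic relative risk
#'
#' Smallest `grr` at which [cc_power()] reaches `target_power`, found by
#' bisection to a tolerance of 1e-4 on the relative risk. Conventionally
#' reported rounded to one decimal.
#'
#' @inheritParams cc_power
#' @param target_power Desired power (default 0.80), must exceed `alpha`.
#' @return The minimal detectable genotypic relative risk (unrounded).
#' @export
#' @examples
#' round(min_detectable_grr(maf = 0.25, alpha = 5e-8,
#'                          n_cases = 1162, n_controls = 936), 1)
min_detectable_grr <- function(maf, prevalence_k = 0.01, alpha,
                               n_cases, n_controls, target_power = 0.8) {
  if (target_power <= alpha || target_power >= 1) {
    abort("`target_power` must lie in (alpha, 1)")
  }
  # largest grr with a valid penetrance vector: f2 = 1 is linear in grr
  p <- maf
  q <- 1 - p
  denom <- 2 * (prevalence_k - p^2 - p * q)
  up <- if (denom <= 0) 1e6 else {
    g_max <- (q^2 + prevalence_k - p^2) / denom
    if (g_max <= 1) abort("no valid relative risk for this K and maf")
    g_max * (1 - 1e-9)
  }
  pw <- function(g) cc_power(maf, g, prevalence_k, alpha, n_cases, n_controls)
  if (pw(up) < target_power) {
    abort("target power unattainable within the valid penetrance range")
  }
  lo <- 1
  hi <- up
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided Fisher exact p-value with the standard probability-mass
#' ordering: the sum of hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome), or a length-4 vector filled by row.
#' @return Two-sided p-value; degenerate margins give 1.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(17, 21, 7, 36), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  tab <- as_2x2(table)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  fisher.test(tab)$p.value
}

#' Odds ratio with Woolf confidence interval for a 2x2 table
#'
#' `OR = ad / bc` with a 95% Woolf (log) interval
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell invokes
#' the Haldane continuity correction (0.5 added to every cell).
#'
#' @inheritParams fisher_exact_2x2
#' @return Tibble (`odds_ratio`, `ci_lower`, `ci_upper`, `corrected`).
#' @export
odds_ratio_2x2 <- function(table) {
  tab <- as_2x2(table)
  corrected <- any(tab == 0L)
  t2 <- tab + if (corrected) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  tibble::tibble(
    odds_ratio = or,
    ci_lower = exp(log(or) - 1.96 * se),
    ci_upper = exp(log(or) + 1.96 * se),
    corrected = corrected
  )
}

as_2x2 <- function(table) {
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table))) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != floor(table))) {
    abort("cell counts must be non-negative integers")
  }
  table
}
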