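#' Method-of-moments pairwise relatedness (pi-hat)
#'
#' Estimates pairwise genome-wide relatedness from identity-by-state counts
#' on common biallelic variants, in the classic method-of-moments style:
#' observed IBS0/IBS1/IBS2 counts per pair are equated with their
#' expectations given the allele frequencies under IBD states 0/1/2, giving
#' P(IBD = k) and `pi_hat = P(IBD=2) + P(IBD=1)/2`. Small excursions outside
#' [0, 1] are an expected property of the moment estimator and are not
#' clipped. Pairs with missing genotypes use expectations scaled by the
#' fraction of mutually called variants.
#'
#' @param geno Genotype matrix, variants in rows and samples in columns
#'   (dosages 0/1/2, `NA` missing). Variants should be common (MAF >= 0.05)
#'   and LD-thinned.
#' @param maf_min Variants below this MAF are dropped before estimation.
#' @return A symmetric n x n matrix of pi-hat values (self-pairs ~ 1), with
#'   attribute `unstable = TRUE` and a warning when fewer than 50 variants
#'   are available.
#' @export
estimate_relatedness <- function(geno, maf_min = 0.05) {
  af <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= maf_min
  g <- geno[keep, , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2
  m <- nrow(g)
  unstable <- FALSE
  if (m < 50L) {
    warn("fewer than 50 variants for relatedness estimation; result unstable")
    unstable <- TRUE
  }
  n <- ncol(g)
  called <- !is.na(g)
  i0 <- (g == 0L) & called
  i1 <- (g == 1L) & called
  i2 <- (g == 2L) & called
  i0[is.na(i0)] <- FALSE; i1[is.na(i1)] <- FALSE; i2[is.na(i2)] <- FALSE
  m0 <- matrix(as.numeric(i0), m, n)
  m1 <- matrix(as.numeric(i1), m, n)
  m2 <- matrix(as.numeric(i2), m, n)
  mc <- matrix(as.numeric(called), m, n)

  ibs0 <- crossprod(m0, m2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- crossprod(m0) + crossprod(m1) + crossprod(m2)
  valid <- crossprod(mc)
  ibs1 <- valid - ibs0 - ibs2

  q <- 1 - p
  # expected per-variant IBS probabilities under each IBD state, summed
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p * q)
  e2_ibd1 <- sum(1 - 2 * p * q)

  sc <- valid / m  # pairwise completeness scaling of the expectations
  p_ibd0 <- ibs0 / (e0_ibd0 * sc)
  p_ibd1 <- (ibs1 - p_ibd0 * e1_ibd0 * sc) / (e1_ibd1 * sc)
  p_ibd2 <- (ibs2 - p_ibd0 * e2_ibd0 * sc - p_ibd1 * e2_ibd1 * sc) / valid
  pihat <- p_ibd2 + p_ibd1 / 2
  dimnames(pihat) <- list(colnames(geno), colnames(geno))
  attr(pihat, "unstable") <- unstable
  pihat
}

#' Prune related samples
#'
#' Greedy pruning of the relatedness graph: while any pair exceeds the
#' threshold, the member involved in the most over-threshold pairs is
#' removed; ties are broken by higher overall genotype missingness, then by
#' lexicographic sample id. No remaining pair exceeds the threshold.
#'
#' @param pihat Symmetric matrix from [estimate_relatedness()].
#' @param threshold Pi-hat above which a pair is considered related.
#' @param missingness Optional named per-sample missingness used in
#'   tie-breaking.
#' @return Character vector of kept sample ids.
#' @export
prune_related <- function(pihat, threshold = 0.2, missingness = NULL) {
  ids <- colnames(pihat) %||% as.character(seq_len(ncol(pihat)))
  dimnames(pihat) <- list(ids, ids)
  if (is.null(missingness)) missingness <- setNames(rep(0, length(ids)), ids)
  keep <- ids
  repeat {
    sub <- pihat[keep, keep, drop = FALSE]
    diag(sub) <- 0
    deg <- rowSums(sub > threshold)
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    cand <- keep[worst]
    cand <- cand[order(-missingness[cand], cand)]
    keep <- setdiff(keep, cand[1L])
  }
  keep
}
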