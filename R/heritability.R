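#' Genetic relationship matrix from standardized genotypes
#'
#' GCTA-style GRM: `A_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))` over variants i. Residual missing genotypes are
#' mean-imputed per variant before standardization. Under HWE with
#' independent samples the diagonal averages ~1.
#'
#' @param geno Genotype matrix, samples in rows and variants in columns
#'   (dosages 0/1/2, `NA` tolerated).
#' @param mafs Optional per-variant allele frequencies; estimated from the
#'   data when `NULL`.
#' @return A list of class `grm_matrix`: `A` (n x n), `m` (variant count),
#'   `sample_ids`.
#' @export
compute_grm <- function(geno, mafs = NULL) {
  n <- nrow(geno)
  p <- if (is.null(mafs)) colMeans(geno, na.rm = TRUE) / 2 else mafs
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic variant in GRM input (allele frequency 0 or 1)")
  }
  z <- sweep(geno, 2, 2 * p)
  z[is.na(z)] <- 0  # mean imputation after centring
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(z) / ncol(geno)
  ids <- rownames(geno) %||% sprintf("S%05d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, m = ncol(geno), sample_ids = ids),
            class = "grm_matrix")
}

#' Windowed LD scores
#'
#' `score_i = sum of r^2 between variant i and every variant within the
#' physical window` (the variant itself included, so scores are >= 1), with
#' no r^2 threshold. Computed per chromosome in blocks.
#'
#' @param geno Genotype matrix, samples in rows, variants in columns.
#' @param positions Per-variant base positions (must be sorted increasing
#'   within chromosome).
#' @param chrom Optional per-variant chromosome (single chromosome assumed
#'   when `NULL`).
#' @param window_kb Window half-width in kilobases (default 10000).
#' @return Numeric vector of LD scores.
#' @export
ld_scores <- function(geno, positions, chrom = NULL, window_kb = 10000) {
  m <- ncol(geno)
  if (length(positions) != m) abort("`positions` must match variant count")
  if (is.null(chrom)) chrom <- rep("chr1", m)
  out <- numeric(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- positions[idx]
    if (is.unsorted(pos)) abort("positions must be sorted within chromosome")
    z <- scale(geno[, idx, drop = FALSE])
    n <- nrow(z)
    window <- window_kb * 1000
    block <- 512L
    mm <- length(idx)
    for (s in seq(1L, mm, by = block)) {
      e <- min(s + block - 1L, mm)
      lo <- findInterval(pos[s] - window, pos) + 1L
      hi <- findInterval(pos[e] + window, pos)
      r <- crossprod(z[, s:e, drop = FALSE], z[, lo:hi, drop = FALSE]) /
        (n - 1)
      r2 <- r^2
      for (k in s:e) {
        keep <- abs(pos[lo:hi] - pos[k]) <= window
        out[idx[k]] <- sum(r2[k - s + 1L, keep])
      }
    }
  }
  out
}

#' MAF x LD bin assignment for GREML-LDMS
#'
#' Partitions variants into seven MAF bins with boundaries
#' 0.0007, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5 (left-open, right-closed;
#' MAF exactly 0.0007 falls in bin 1) and splits each MAF bin at its median
#' LD score: low LD strictly below the median, high LD at or above it — 14
#' bins in total. Variants below the MAF floor are excluded with a warning;
#' empty bins are dropped with a warning.
#'
#' @param mafs Per-variant minor allele frequencies in (0, 0.5].
#' @param ld_scores Per-variant LD scores (same length).
#' @return Tibble (`variant`, `maf`, `ld_score`, `maf_bin`, `ld_bin`,
#'   `bin`), `bin` being e.g. `"maf2_lowLD"`; excluded variants get `NA`.
#' @export
assign_bins <- function(mafs, ld_scores) {
  if (length(mafs) != length(ld_scores)) {
    abort("`mafs` and `ld_scores` must have the same length")
  }
  breaks <- c(0.0007, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5)
  below <- mafs < breaks[1]
  if (any(below)) {
    warn(paste0(sum(below), " variants below the MAF floor (0.0007) excluded"))
  }
  maf_bin <- as.integer(cut(mafs, breaks, labels = FALSE,
                            include.lowest = TRUE))
  maf_bin[below] <- NA_integer_
  ld_bin <- rep(NA_character_, length(mafs))
  for (b in sort(unique(maf_bin[!is.na(maf_bin)]))) {
    idx <- which(maf_bin == b)
    med <- median(ld_scores[idx])
    ld_bin[idx] <- ifelse(ld_scores[idx] >= med, "highLD", "lowLD")
  }
  out <- tibble::tibble(
    variant = seq_along(mafs), maf = mafs, ld_score = ld_scores,
    maf_bin = maf_bin, ld_bin = ld_bin,
    bin = ifelse(is.na(maf_bin), NA_character_,
                 paste0("maf", maf_bin, "_", ld_bin))
  )
  occupied <- table(out$bin)
  expected <- length(unique(out$maf_bin[!is.na(out$maf_bin)])) * 2
  if (length(occupied) < expected) {
    warn("some MAF x LD bins are empty and were dropped")
  }
  out
}

#' Observed-scale to liability-scale heritability
#'
#' Closed-form transformation for case-control ascertainment:
#' `h2_liability = h2_observed * K^2 (1 - K)^2 / (z^2 P (1 - P))`, where
#' `K` is the population prevalence, `P` the sample case proportion, and
#' `z` the standard-normal density at the liability threshold
#' `qnorm(1 - K)`.
#'
#' @param h2_obs Observed-scale heritability.
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @return Liability-scale heritability.
#' @export
#' @examples
#' observed_to_liability(0.8, K = 0.01, P = 0.558)
observed_to_liability <- function(h2_obs, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) {
    abort("`K` and `P` must lie in (0, 1)")
  }
  z <- dnorm(qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}
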