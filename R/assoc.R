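#' Single-variant logistic association scan
#'
#' Additive-model logistic regression of case/control status on genotype
#' dosage (0/1/2) per variant, two-sided Wald p-values, restricted to
#' variants with minor allele frequency above `maf_min` (default 0.01).
#' Without covariates the likelihood depends on the genotype-by-phenotype
#' 3x2 table only, so fits are Newton iterations vectorised across variants
#' on aggregated tables (identical estimates to a per-variant `glm` fit);
#' with covariates each variant is fitted individually.
#'
#' @param x An [rv_cohort()], or a genotype matrix (variants x samples).
#' @param phenotype Required when `x` is a matrix: 0/1 vector per sample.
#' @param covariates Optional tibble/matrix of per-sample covariates.
#' @param maf_min MAF cutoff; variants at or below it (and monomorphic
#'   variants) are excluded.
#' @return Tibble: `variant_id`, `maf`, `beta`, `se`, `odds_ratio`, `z`,
#'   `p` (two-sided), `converged`.
#' @export
single_variant_assoc <- function(x, phenotype = NULL, covariates = NULL,
                                 maf_min = 0.01) {
  if (inherits(x, "rv_cohort")) {
    geno <- x$geno
    phenotype <- x$samples$phenotype
    ids <- x$variants$variant_id
  } else {
    geno <- x
    if (is.null(phenotype)) abort("`phenotype` required for matrix input")
    ids <- rownames(geno) %||% sprintf("v%07d", seq_len(nrow(geno)))
  }
  af <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf > maf_min & maf > 0
  geno <- geno[keep, , drop = FALSE]
  ids <- ids[keep]
  maf <- maf[keep]
  if (!nrow(geno)) {
    return(tibble::tibble(variant_id = character(), maf = numeric(),
                          beta = numeric(), se = numeric(),
                          odds_ratio = numeric(), z = numeric(),
                          p = numeric(), converged = logical()))
  }
  if (is.null(covariates)) {
    res <- logistic_scan_tables(geno, phenotype)
  } else {
    cv <- as.matrix(covariates)
    res <- purrr::map_dfr(seq_len(nrow(geno)), function(i) {
      g <- geno[i, ]
      ok <- !is.na(g)
      X <- cbind(1, cv[ok, , drop = FALSE], g[ok])
      fit <- suppressWarnings(glm.fit(X, phenotype[ok],
                                      family = binomial()))
      j <- ncol(X)
      b <- coef(fit)[j]
      se <- glmfit_se(fit)[j]
      tibble::tibble(beta = unname(b), se = unname(se),
                     converged = isTRUE(fit$converged) & is.finite(se))
    })
  }
  tibble::tibble(
    variant_id = ids, maf = maf,
    beta = res$beta, se = res$se,
    odds_ratio = exp(res$beta),
    z = res$beta / res$se,
    p = 2 * pnorm(abs(res$beta / res$se), lower.tail = FALSE),
    converged = res$converged
  )
}

# Newton-Raphson logistic fits (intercept + dosage) vectorised across
# variants on the 3x2 genotype-by-phenotype tables (sufficient statistics).
logistic_scan_tables <- function(geno, y) {
  rownames(geno) <- NULL
  case <- y == 1L
  n11 <- rowSums(geno[, case, drop = FALSE] == 1L, na.rm = TRUE)
  n21 <- rowSums(geno[, case, drop = FALSE] == 2L, na.rm = TRUE)
  n01 <- rowSums(!is.na(geno[, case, drop = FALSE])) - n11 - n21
  n10 <- rowSums(geno[, !case, drop = FALSE] == 1L, na.rm = TRUE)
  n20 <- rowSums(geno[, !case, drop = FALSE] == 2L, na.rm = TRUE)
  n00 <- rowSums(!is.na(geno[, !case, drop = FALSE])) - n10 - n20
  m <- nrow(geno)
  tot <- cbind(n00 + n01, n10 + n11, n20 + n21)   # per genotype class
  cas <- cbind(n01, n11, n21)
  gval <- c(0, 1, 2)
  a <- rep(log(mean(y) / (1 - mean(y))), m)
  b <- rep(0, m)
  converged <- rep(FALSE, m)
  for (it in 1:50) {
    eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
    mu <- cbind(plogis(eta0), plogis(eta1), plogis(eta2))
    w <- tot * mu * (1 - mu)
    # gradient
    ga <- rowSums(cas - tot * mu)
    gb <- rowSums((cas - tot * mu) *
                    matrix(gval, m, 3, byrow = TRUE))
    # Hessian entries
    haa <- rowSums(w)
    hab <- rowSums(w * matrix(gval, m, 3, byrow = TRUE))
    hbb <- rowSums(w * matrix(gval^2, m, 3, byrow = TRUE))
    det <- haa * hbb - hab^2
    det[det <= 0 | !is.finite(det)] <- NA
    da <- (hbb * ga - hab * gb) / det
    db <- (haa * gb - hab * ga) / det
    da[is.na(da)] <- 0
    db[is.na(db)] <- 0
    # damped step for stability
    step <- pmax(abs(da), abs(db))
    damp <- ifelse(step > 5, 5 / step, 1)
    a <- a + damp * da
    b <- b + damp * db
    newly <- abs(da) < 1e-10 & abs(db) < 1e-10
    converged <- converged | newly
    if (all(converged)) break
  }
  # standard errors from the final observed information
  eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
  mu <- cbind(plogis(eta0), plogis(eta1), plogis(eta2))
  w <- tot * mu * (1 - mu)
  haa <- rowSums(w)
  hab <- rowSums(w * matrix(gval, m, 3, byrow = TRUE))
  hbb <- rowSums(w * matrix(gval^2, m, 3, byrow = TRUE))
  det <- haa * hbb - hab^2
  se <- sqrt(haa / det)
  bad <- !is.finite(se) | abs(b) > 20
  tibble::tibble(beta = b, se = se,
                 converged = converged & !bad)
}

#' Genomic inflation factor (lambda GC)
#'
#' Median of the 1-df chi-square statistics implied by the p-values divided
#' by the null median 0.4549364.
#'
#' @param p_values Numeric vector of two-sided association p-values (at
#'   least 100).
#' @return Lambda GC.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L) abort("need at least 100 tests for lambda GC")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}
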