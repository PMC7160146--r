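#' Select principal components predicting phenotype
#'
#' Tests each PC as the sole predictor of case/control status in a logistic
#' model and returns those with two-sided Wald p below `alpha` (default
#' 0.01) — the empirical covariate-selection rule for sequence-variant
#' burden models.
#'
#' @param data Tibble with a `phenotype` column (0/1) and the PC columns.
#' @param pcs Character vector of PC column names.
#' @param alpha Two-sided significance threshold.
#' @return Tibble (`pc`, `estimate`, `p_value`, `selected`).
#' @export
select_covariates_phenotype <- function(data, pcs = grep("^PC", names(data),
                                                         value = TRUE),
                                        alpha = 0.01) {
  if (length(unique(data$phenotype)) < 2L) {
    abort("phenotype is constant; cannot select covariates")
  }
  if (!length(pcs)) abort("no PC columns supplied")
  purrr::map_dfr(pcs, function(pc) {
    fit <- glm(data$phenotype ~ data[[pc]], family = binomial())
    sm <- summary(fit)$coefficients
    tibble::tibble(pc = pc, estimate = sm[2, 1], p_value = sm[2, 4])
  }) |>
    dplyr::mutate(selected = .data$p_value < alpha)
}

#' Select principal components predicting genome-wide SV count
#'
#' Multiple linear regression of the per-sample genome-wide ultra-rare SV
#' count on sex, mean coverage and the leading PCs; PCs significant at
#' two-sided p < `alpha` (default 0.05) are returned — the covariate rule
#' for SV burden models.
#'
#' @param data Tibble with `global_count`, `sex`, `mean_coverage` and PC
#'   columns.
#' @param pcs PC column names (default `PC1`-`PC3` if present).
#' @param alpha Significance threshold.
#' @return Tibble (`pc`, `estimate`, `p_value`, `selected`).
#' @export
select_covariates_svcount <- function(data,
                                      pcs = intersect(c("PC1", "PC2", "PC3"),
                                                      names(data)),
                                      alpha = 0.05) {
  if (!length(pcs)) abort("no PC columns supplied")
  rhs <- c("sex", "mean_coverage", pcs)
  X <- stats::model.matrix(
    as.formula(paste("~", paste(rhs, collapse = "+"))), data)
  if (qr(X)$rank < ncol(X)) {
    abort(paste0("rank-deficient design; check collinearity among: ",
                 paste(rhs, collapse = ", ")))
  }
  fit <- lm(as.formula(paste("global_count ~",
                             paste(rhs, collapse = "+"))), data = data)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    pc = pcs,
    estimate = sm[pcs, 1],
    p_value = sm[pcs, 4],
    selected = sm[pcs, 4] < alpha
  )
}

#' Logistic burden test of ultra-rare variant counts
#'
#' Fits the case-control logistic burden model: phenotype regressed on the
#' per-sample count of qualifying variants in the target annotation, plus
#' covariates (and, for SV-style models, the genome-wide count). The odds
#' ratio measures the increase in disease odds per unit increase in burden;
#' the asymptotic p-value is one-sided for case excess (upper tail of the
#' Wald z). Optionally appends a permutation empirical p-value
#' ([permutation_pvalue()]).
#'
#' @param data Tibble with `phenotype` (0/1) and the model columns.
#' @param target Column name of the target-annotation count (default
#'   `"count"`).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param global Optional column name of the genome-wide count covariate.
#' @param n_permutations Number of phenotype-label permutations (0 = skip).
#' @param seed Seed for the permutation stream.
#' @return An object of class `burden_fit`; see [tidy.burden_fit()] /
#'   [glance.burden_fit()]. Key fields: `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_one_sided`, `p_empirical`, `converged`, `separation`.
#' @export
fit_logistic_burden <- function(data, target = "count",
                                covariates = character(),
                                global = NULL,
                                n_permutations = 0, seed = 1L) {
  data <- tibble::as_tibble(data)
  need <- c("phenotype", target, covariates, global)
  if (!all(need %in% names(data))) {
    abort(paste0("missing columns: ",
                 paste(setdiff(need, names(data)), collapse = ", ")))
  }
  if (sum(data$phenotype == 1L) < 10L || sum(data$phenotype == 0L) < 10L) {
    abort("need at least 10 cases and 10 controls")
  }
  if (any(data[[target]] < 0)) abort("target counts must be non-negative")
  rhs <- c(covariates, global, target)
  X <- stats::model.matrix(
    as.formula(paste("~", paste(rhs, collapse = "+"))), data)
  y <- data$phenotype
  j <- ncol(X)  # target term is last

  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- coef(fit)[j]
  se <- glmfit_se(fit)[j]
  zero_info <- var(data[[target]]) == 0
  separation <- is.finite(beta) && abs(beta) > 20
  converged <- isTRUE(fit$converged) && !zero_info && is.finite(se)
  z <- if (converged && !separation) beta / se else NA_real_
  out <- list(
    term = target,
    beta = unname(beta), se = unname(se),
    odds_ratio = unname(exp(beta)),
    ci_lower = unname(exp(beta - 1.96 * se)),
    ci_upper = unname(exp(beta + 1.96 * se)),
    z = unname(z),
    p_one_sided = if (!is.na(z)) pnorm(z, lower.tail = FALSE) else NA_real_,
    p_empirical = NA_real_,
    n_case = sum(y == 1L), n_control = sum(y == 0L),
    case_total = sum(data[[target]][y == 1L]),
    control_total = sum(data[[target]][y == 0L]),
    converged = converged, separation = separation,
    zero_information = zero_info,
    covariates = c(covariates, global),
    model = list(X = X, y = y, target_col = j,
                 coef_obs = unname(coef(fit))),
    n_permutations = 0L
  )
  class(out) <- "burden_fit"
  if (n_permutations > 0) {
    out$p_empirical <- permutation_pvalue(out, n_perm = n_permutations,
                                          seed = seed)
    out$n_permutations <- as.integer(n_permutations)
  }
  out
}

glmfit_se <- function(fit) {
  # Wald standard errors from the final IWLS qr decomposition
  R <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(R), error = function(e) {
    matrix(NA_real_, ncol(R), ncol(R))
  })
  se <- sqrt(diag(cov))
  # columns are pivoted in glm.fit's qr
  se[order(fit$qr$pivot)]
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit> OR = ", signif(x$odds_ratio, 4),
      " [", signif(x$ci_lower, 4), ", ", signif(x$ci_upper, 4), "], ",
      "one-sided P = ", signif(x$p_one_sided, 3), sep = "")
  if (!is.na(x$p_empirical)) {
    cat(", empirical P = ", signif(x$p_empirical, 3),
        " (", x$n_permutations, " permutations)", sep = "")
  }
  if (x$separation) cat("  [separation]")
  if (!x$converged) cat("  [not converged]")
  cat("\n")
  invisible(x)
}

#' Permutation empirical p-value for a burden fit
#'
#' Permutes the phenotype labels uniformly (covariates stay attached to the
#' samples), refits the model for each permutation and compares the Wald z
#' of the target term to the observed one:
#' `p = (1 + #\{z_perm >= z_obs\}) / (n_perm + 1)`. Non-convergent refits
#' (over 1% triggers a warning) are counted conservatively as at least as
#' extreme as observed. Fixed seed gives exactly reproducible p-values.
#'
#' @param fit A `burden_fit` from [fit_logistic_burden()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Empirical one-sided p-value.
#' @export
permutation_pvalue <- function(fit, n_perm = 10000, seed = 1L) {
  X <- fit$model$X
  y <- fit$model$y
  j <- fit$model$target_col
  z_obs <- fit$z
  if (is.na(z_obs)) z_obs <- -Inf  # degenerate observed fit: p ~ 1 unless
                                   # permutations also fail
  n_bad <- 0L
  with_seed(derive_seed(seed, "permutation"), {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      pf <- suppressWarnings(
        glm.fit(X, yp, family = binomial(),
                control = stats::glm.control(epsilon = 1e-7)))
      bet <- coef(pf)[j]
      se <- glmfit_se(pf)[j]
      if (!isTRUE(pf$converged) || !is.finite(bet) || !is.finite(se) ||
          abs(bet) > 20) {
        n_bad <- n_bad + 1L
        hits <- hits + 1L  # conservative
      } else if (bet / se >= z_obs) {
        hits <- hits + 1L
      }
    }
    if (n_bad > 0.01 * n_perm) {
      warn(paste0(n_bad, " of ", n_perm,
                  " permutation refits failed; counted as extreme"))
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Benjamini-Hochberg adjustment within test families
#'
#' Standard BH step-up adjusted p-values with running-minimum
#' monotonisation, computed separately within each declared family (e.g.
#' the sequence-variant family of 74 tests and the SV family of 29 tests).
#' Significance is flagged at adjusted p < 0.05.
#'
#' @param data Tibble with a p-value column and a family column, or a bare
#'   numeric vector of p-values.
#' @param p Column name of the raw p-values (default `"p"`).
#' @param family Column name of the family label (default `"family"`; a
#'   single implicit family is used for vector input or when absent).
#' @return The input tibble with `p_adjusted` and `significant` columns
#'   appended (or a numeric vector for vector input).
#' @export
bh_fdr <- function(data, p = "p", family = "family") {
  if (is.numeric(data)) {
    if (!length(data)) abort("empty test family")
    return(p.adjust(data, method = "BH"))
  }
  data <- tibble::as_tibble(data)
  if (!p %in% names(data)) abort(paste0("missing p-value column: ", p))
  if (!nrow(data)) abort("empty test family")
  fam <- if (family %in% names(data)) data[[family]] else
    rep("all", nrow(data))
  adj <- numeric(nrow(data))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    adj[idx] <- p.adjust(data[[p]][idx], method = "BH")
  }
  data$p_adjusted <- adj
  data$significant <- adj < 0.05
  data
}

#' Burden scan over annotations
#'
#' Runs [fit_logistic_burden()] for each annotation's per-sample counts and
#' collects the results into one tidy table with BH-FDR adjustment within
#' the declared family.
#'
#' @param counts Tibble with `sample_id`, `phenotype`, one count column per
#'   annotation (wide), or a list of per-annotation count tibbles from
#'   [count_per_sample()].
#' @param annotations Annotation (column) names to test.
#' @param covariates,global,n_permutations,seed Passed to the fitter.
#' @param family Family label stored with every test.
#' @return Tibble with one row per test: `annotation`, `family`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p`, `p_empirical`, `p_adjusted`,
#'   `significant`, flags.
#' @export
burden_scan <- function(counts, annotations, covariates = character(),
                        global = NULL, n_permutations = 0, seed = 1L,
                        family = "URV") {
  res <- purrr::map_dfr(annotations, function(ann) {
    fit <- fit_logistic_burden(counts, target = ann,
                               covariates = covariates, global = global,
                               n_permutations = n_permutations, seed = seed)
    tibble::tibble(
      annotation = ann, family = family,
      odds_ratio = fit$odds_ratio, ci_lower = fit$ci_lower,
      ci_upper = fit$ci_upper, p = fit$p_one_sided,
      p_empirical = fit$p_empirical,
      n_case = fit$n_case, n_control = fit$n_control,
      converged = fit$converged, separation = fit$separation
    )
  })
  res <- bh_fdr(res, p = "p", family = "family")
  class(res) <- c("burden_scan", class(res))
  res
}
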