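#' Quality-control thresholds
#'
#' Container for the genotype-, variant- and sample-level QC thresholds used
#' throughout the pipeline. Defaults follow deep case-control WGS practice:
#' genotypes with DP < 10 or GQ < 20 are set missing; variants are removed if
#' monomorphic, missing in > 2% of samples, differentially missing between
#' cases and controls (> 2% difference or Fisher p < 0.005), or out of
#' Hardy-Weinberg equilibrium at BH-FDR < 1e-6 in controls or < 1e-10 in
#' cases; relative pairs are pruned at pi-hat > 0.2 (0.05 for heritability);
#' samples with a total ultra-rare-variant count above `urv_outlier_threshold`
#' are dropped; SVs overlapping the blacklist union by more than 66% are
#' removed.
#'
#' The URV outlier threshold of 6000 is specific to cohorts averaging ~4250
#' URVs per sample; pass `urv_outlier_threshold = NULL` together with
#' `mean_urv` to rescale it proportionally (6000/4250 times the observed
#' mean).
#'
#' @param min_dp,min_gq Per-genotype depth / quality minima.
#' @param max_missing_per_variant Maximum per-variant missing rate.
#' @param max_diff_missing Maximum case-control missing-rate difference.
#' @param diff_missing_p Significance level of the differential-missingness
#'   Fisher test.
#' @param hwe_fdr_controls,hwe_fdr_cases BH-FDR thresholds on the exact HWE
#'   test within controls / cases.
#' @param relatedness_prune_burden,relatedness_prune_h2 Pi-hat pruning
#'   thresholds for burden testing and heritability estimation.
#' @param urv_outlier_threshold Per-sample total URV count above which a
#'   sample is pruned (strict inequality).
#' @param mean_urv Observed mean URV count used to rescale the outlier
#'   threshold when `urv_outlier_threshold` is `NULL`.
#' @param blacklist_overlap_max Maximum tolerated fraction of an SV covered
#'   by the blacklist union (strict inequality).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_dp = 10, min_gq = 20,
                          max_missing_per_variant = 0.02,
                          max_diff_missing = 0.02,
                          diff_missing_p = 0.005,
                          hwe_fdr_controls = 1e-6,
                          hwe_fdr_cases = 1e-10,
                          relatedness_prune_burden = 0.2,
                          relatedness_prune_h2 = 0.05,
                          urv_outlier_threshold = 6000,
                          mean_urv = NULL,
                          blacklist_overlap_max = 0.66) {
  if (is.null(urv_outlier_threshold)) {
    if (is.null(mean_urv)) abort("supply `mean_urv` to rescale the threshold")
    urv_outlier_threshold <- mean_urv * 6000 / 4250
  }
  for (p in c(max_missing_per_variant, max_diff_missing, diff_missing_p,
              hwe_fdr_controls, hwe_fdr_cases, blacklist_overlap_max)) {
    assert_prop(p, "qc proportion threshold")
  }
  if (min_dp <= 0 || min_gq <= 0 || urv_outlier_threshold <= 0) {
    abort("thresholds must be strictly positive")
  }
  structure(
    list(min_dp = min_dp, min_gq = min_gq,
         max_missing_per_variant = max_missing_per_variant,
         max_diff_missing = max_diff_missing,
         diff_missing_p = diff_missing_p,
         hwe_fdr_controls = hwe_fdr_controls,
         hwe_fdr_cases = hwe_fdr_cases,
         relatedness_prune_burden = relatedness_prune_burden,
         relatedness_prune_h2 = relatedness_prune_h2,
         urv_outlier_threshold = urv_outlier_threshold,
         blacklist_overlap_max = blacklist_overlap_max),
    class = "qc_thresholds"
  )
}

#' Mask low-quality genotypes
#'
#' Sets genotypes with DP below `min_dp` or GQ below `min_gq` to missing;
#' no other genotype is altered. Allele counts are recomputed afterwards.
#'
#' @param cohort An [rv_cohort()] carrying `dp` and `gq` matrices.
#' @param thresholds A [qc_thresholds()].
#' @return The cohort with failing genotypes set to `NA`.
#' @export
apply_genotype_qc <- function(cohort, thresholds = qc_thresholds()) {
  if (is.null(cohort$dp)) abort("cohort is missing the `dp` matrix")
  if (is.null(cohort$gq)) abort("cohort is missing the `gq` matrix")
  bad <- (cohort$dp < thresholds$min_dp) | (cohort$gq < thresholds$min_gq)
  cohort$geno[bad] <- NA_integer_
  recompute_ac(cohort)
}

#' Variant-level quality control
#'
#' Applies the variant filters in order: monomorphic sites; overall missing
#' rate above `max_missing_per_variant`; differential missingness between
#' cases and controls (rate difference above `max_diff_missing` or two-sided
#' Fisher exact p below `diff_missing_p` on the called/missing-by-phenotype
#' table); and Hardy-Weinberg disequilibrium, where exact HWE p-values are
#' computed separately in controls and in cases across all variants reaching
#' that filter, BH-adjusted within stratum, and removed below the respective
#' FDR thresholds. Genotype-level QC must already have been applied.
#'
#' @inheritParams apply_genotype_qc
#' @return A list with `cohort` (filtered) and `report`, a tibble of removed
#'   variants with a `reason` column plus per-filter before/after counts in
#'   the `counts` attribute.
#' @export
filter_variants <- function(cohort, thresholds = qc_thresholds()) {
  ph <- cohort$samples$phenotype
  if (!any(ph == 1L) || !any(ph == 0L)) {
    abort("cohort must contain both cases and controls")
  }
  g <- cohort$geno
  n_var <- nrow(g)
  case_idx <- which(ph == 1L)
  ctrl_idx <- which(ph == 0L)
  removed <- character(n_var)  # "" = kept; first failing filter recorded

  ac <- rowSums(g, na.rm = TRUE)
  called <- rowSums(!is.na(g))
  mono <- ac == 0L | ac == 2L * called
  removed[mono] <- "monomorphic"

  miss_rate <- 1 - called / ncol(g)
  f <- removed == "" & miss_rate > thresholds$max_missing_per_variant
  removed[f] <- "missing_rate"

  miss_case <- rowMeans(is.na(g[, case_idx, drop = FALSE]))
  miss_ctrl <- rowMeans(is.na(g[, ctrl_idx, drop = FALSE]))
  cand <- which(removed == "")
  diff_flag <- abs(miss_case[cand] - miss_ctrl[cand]) >
    thresholds$max_diff_missing
  # Fisher test on called/missing x case/control, only where any missingness
  has_miss <- miss_case[cand] > 0 | miss_ctrl[cand] > 0
  fisher_flag <- rep(FALSE, length(cand))
  n_case_s <- length(case_idx)
  n_ctrl_s <- length(ctrl_idx)
  for (k in which(has_miss & !diff_flag)) {
    i <- cand[k]
    p <- fisher2x2_p(round(miss_case[i] * n_case_s),
                     n_case_s - round(miss_case[i] * n_case_s),
                     round(miss_ctrl[i] * n_ctrl_s),
                     n_ctrl_s - round(miss_ctrl[i] * n_ctrl_s))
    fisher_flag[k] <- p < thresholds$diff_missing_p
  }
  removed[cand[diff_flag | fisher_flag]] <- "differential_missingness"

  # exact HWE within stratum, BH across variants entering this filter
  cand <- which(removed == "")
  if (length(cand)) {
    hwe_strat <- function(idx, sample_idx) {
      gg <- g[idx, sample_idx, drop = FALSE]
      n0 <- rowSums(gg == 0L, na.rm = TRUE)
      n1 <- rowSums(gg == 1L, na.rm = TRUE)
      n2 <- rowSums(gg == 2L, na.rm = TRUE)
      vapply(seq_along(idx),
             function(j) hwe_exact_test(n0[j], n1[j], n2[j]), 0)
    }
    p_ctrl <- hwe_strat(cand, ctrl_idx)
    p_case <- hwe_strat(cand, case_idx)
    bad_hwe <- p.adjust(p_ctrl, "BH") < thresholds$hwe_fdr_controls |
      p.adjust(p_case, "BH") < thresholds$hwe_fdr_cases
    removed[cand[bad_hwe]] <- "hwe"
  }

  keep <- removed == ""
  report <- tibble::tibble(
    variant_id = cohort$variants$variant_id[!keep],
    reason = removed[!keep]
  )
  counts <- tibble::tibble(
    filter = c("input", "monomorphic", "missing_rate",
               "differential_missingness", "hwe", "output"),
    n = c(n_var, sum(removed == "monomorphic"),
          sum(removed == "missing_rate"),
          sum(removed == "differential_missingness"),
          sum(removed == "hwe"), sum(keep))
  )
  attr(report, "counts") <- counts
  out <- cohort
  out$variants <- cohort$variants[keep, , drop = FALSE]
  out$geno <- cohort$geno[keep, , drop = FALSE]
  if (!is.null(out$dp)) out$dp <- cohort$dp[keep, , drop = FALSE]
  if (!is.null(out$gq)) out$gq <- cohort$gq[keep, , drop = FALSE]
  out <- recompute_ac(out)
  list(cohort = out, report = report)
}

#' Prune samples with outlier total URV counts
#'
#' Removes samples whose total ultra-rare-variant count strictly exceeds the
#' threshold (count = threshold is retained).
#'
#' @param urv_counts Named numeric vector (or tibble with `sample_id` and
#'   `urv_count`) of per-sample total URV counts.
#' @param threshold Count above which a sample is pruned.
#' @param phenotype Optional vector aligned with `urv_counts` for per-group
#'   removal logging.
#' @return A tibble (`sample_id`, `urv_count`, `kept`, and `phenotype` if
#'   supplied).
#' @export
prune_urv_outliers <- function(urv_counts, threshold = 6000,
                               phenotype = NULL) {
  if (is.data.frame(urv_counts)) {
    out <- tibble::as_tibble(urv_counts)
    if (!all(c("sample_id", "urv_count") %in% names(out))) {
      abort("tibble input needs `sample_id` and `urv_count`")
    }
  } else {
    out <- tibble::tibble(
      sample_id = names(urv_counts) %||% as.character(seq_along(urv_counts)),
      urv_count = as.numeric(urv_counts)
    )
  }
  out$kept <- out$urv_count <= threshold
  if (!is.null(phenotype)) out$phenotype <- phenotype
  out
}

#' Remove structural variants overlapping the blacklist
#'
#' An SV is removed iff the union of blacklist intervals covers strictly more
#' than `max_fraction` of its length (overlaps are unioned first, so two
#' disjoint blacklist hits of 40% and 30% remove the SV).
#'
#' @param svset An [sv_callset()].
#' @param blacklist Interval tibble (`chrom`, `start`, `end`), 0-based
#'   half-open, same coordinate system as the SVs.
#' @param max_fraction Maximum tolerated covered fraction (default 0.66).
#' @return The filtered call set; removed SV ids in the `removed` attribute.
#' @export
filter_sv_blacklist <- function(svset, blacklist, max_fraction = 0.66) {
  svs <- svset$svs
  if (nrow(svs) == 0L) return(svset)
  frac <- vapply(seq_len(nrow(svs)), function(i) {
    bl <- blacklist[blacklist$chrom == svs$chrom[i], , drop = FALSE]
    cov <- union_overlap_bases(svs$start[i], svs$end[i], bl$start, bl$end)
    cov / (svs$end[i] - svs$start[i])
  }, 0)
  keep <- frac <= max_fraction
  out <- svset
  out$svs <- svs[keep, , drop = FALSE]
  out$geno <- svset$geno[keep, , drop = FALSE]
  attr(out, "removed") <- svs$sv_id[!keep]
  out
}
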