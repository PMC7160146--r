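# Matrix-backed containers. Variant/sample metadata are tibbles; genotypes
# (and per-genotype DP/GQ for sequence variants) are integer matrices with
# variants in rows and samples in columns. All result-producing functions
# return plain tibbles.

#' Construct a case-control sequence-variant cohort
#'
#' @param variants Tibble with one row per SNV/indel site. Required columns:
#'   `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `variant_class`
#'   (`"SNV"` or `"indel"`), `cohort_ac`, `consequence_class`, plus one or
#'   more external allele-count columns prefixed `ext_ac_`.
#' @param samples Tibble with one row per sample: `sample_id`, `phenotype`
#'   (1 = case, 0 = control) and any covariate columns.
#' @param geno Integer matrix (variants x samples) of alternate-allele dosages
#'   0/1/2, `NA` for missing.
#' @param dp,gq Optional integer matrices of per-genotype sequencing depth and
#'   genotype quality, same shape as `geno`.
#'
#' @return An object of class `rv_cohort`.
#' @export
rv_cohort <- function(variants, samples, geno, dp = NULL, gq = NULL) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  need_v <- c("variant_id", "chrom", "pos", "ref", "alt", "variant_class",
              "cohort_ac", "consequence_class")
  if (!all(need_v %in% names(variants))) {
    abort(paste0("variants tibble is missing: ",
                 paste(setdiff(need_v, names(variants)), collapse = ", ")))
  }
  if (!any(startsWith(names(variants), "ext_ac_"))) {
    abort("variants tibble needs at least one `ext_ac_*` column")
  }
  if (!all(c("sample_id", "phenotype") %in% names(samples))) {
    abort("samples tibble needs `sample_id` and `phenotype` columns")
  }
  if (nrow(variants) != nrow(geno) || nrow(samples) != ncol(geno)) {
    abort("`geno` must be variants x samples")
  }
  for (m in list(dp, gq)) {
    if (!is.null(m) && !identical(dim(m), dim(geno))) {
      abort("`dp`/`gq` must match the dimensions of `geno`")
    }
  }
  rownames(geno) <- variants$variant_id
  colnames(geno) <- samples$sample_id
  obj <- structure(
    list(variants = variants, samples = samples, geno = geno,
         dp = dp, gq = gq),
    class = "rv_cohort"
  )
  recompute_ac(obj)
}

#' Recompute cohort allele counts from the genotype matrix
#'
#' Allele counts stored in the variant table are always derivable from the
#' genotype matrix; this re-derives them (e.g. after genotype-level QC
#' masking) so the conservation invariant holds.
#'
#' @param cohort An [rv_cohort()].
#' @return The cohort with `cohort_ac`, `n_called` and `maf` refreshed.
#' @export
recompute_ac <- function(cohort) {
  ac <- rowSums(cohort$geno, na.rm = TRUE)
  called <- rowSums(!is.na(cohort$geno))
  cohort$variants$cohort_ac <- as.integer(ac)
  cohort$variants$n_called <- as.integer(called)
  af <- ifelse(called > 0, ac / (2 * called), NA_real_)
  cohort$variants$maf <- pmin(af, 1 - af)
  cohort
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat("<rv_cohort> ", nrow(x$variants), " variants x ", nrow(x$samples),
      " samples (", sum(x$samples$phenotype == 1), " cases / ",
      sum(x$samples$phenotype == 0), " controls)\n", sep = "")
  invisible(x)
}

#' Construct a structural-variant call set
#'
#' @param svs Tibble with one row per SV site: `sv_id`, `chrom`, `start`,
#'   `end` (0-based half-open, `end > start`), `svtype` (one of DEL, DUP,
#'   INV, ALU, SVA, LINE1), `pop_db_max_overlap` (largest fraction of the SV
#'   covered by any same-type population-database variant) and `cohort_ac`.
#' @param samples Sample tibble as in [rv_cohort()].
#' @param geno Integer matrix (SVs x samples) of non-reference genotype
#'   dosages.
#'
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(svs, samples, geno) {
  svs <- tibble::as_tibble(svs)
  samples <- tibble::as_tibble(samples)
  need <- c("sv_id", "chrom", "start", "end", "svtype", "cohort_ac",
            "pop_db_max_overlap")
  if (!all(need %in% names(svs))) {
    abort(paste0("svs tibble is missing: ",
                 paste(setdiff(need, names(svs)), collapse = ", ")))
  }
  if (nrow(svs) > 0 && any(svs$end <= svs$start)) {
    abort("SV intervals must satisfy end > start")
  }
  allowed <- c("DEL", "DUP", "INV", "ALU", "SVA", "LINE1")
  if (!all(svs$svtype %in% allowed)) {
    abort("`svtype` must be one of DEL, DUP, INV, ALU, SVA, LINE1")
  }
  if (nrow(svs) != nrow(geno) || nrow(samples) != ncol(geno)) {
    abort("`geno` must be SVs x samples")
  }
  rownames(geno) <- svs$sv_id
  colnames(geno) <- samples$sample_id
  svs$cohort_ac <- as.integer(rowSums(geno, na.rm = TRUE))
  structure(list(svs = svs, samples = samples, geno = geno),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  tab <- table(x$svs$svtype)
  cat("<sv_callset> ", nrow(x$svs), " SVs (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ") x ",
      nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}
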