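#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration object consumed by the synthetic
#' cohort generators ([simulate_annotation_genome()], [simulate_snv_cohort()],
#' [simulate_sv_cohort()]). Defaults describe the study conditions the
#' generators emulate: a Swedish-scale case-control whole-genome cohort with
#' 1162 cases and 936 controls, SNV/indel singleton fractions of 45.43% and
#' 37.03%, a mean of ~4250 ultra-rare variants (URVs) per sample with a
#' heavy-count outlier tail, structural-variant site counts and median sizes
#' matching deep short-read calling (DEL 2592 bp, DUP 7179 bp, INV 3265 bp,
#' truncated to 500 bp - 1 Mb), and a liability-threshold phenotype at 1%
#' lifetime prevalence. The toy genome itself (number and length of
#' chromosomes) is freely scalable; tests and examples use much smaller
#' settings than the defaults.
#'
#' @param n_cases,n_controls Number of case / control samples (>= 2 each).
#' @param n_chromosomes Number of simulated autosomes.
#' @param chrom_length Length of each chromosome in bases; must be a multiple
#'   of `tad_bin_width`.
#' @param tad_bin_width Width of candidate TAD-boundary bins (bases).
#' @param tad_boundary_fraction Fraction of 40-kb bins flagged as TAD
#'   boundaries.
#' @param snv_singleton_fraction,indel_singleton_fraction Target fraction of
#'   SNV (indel) sites carried by exactly one heterozygous individual.
#' @param indel_fraction Fraction of SNV/indel sites that are indels.
#' @param mean_urv_per_sample Expected URV count per (non-outlier) sample.
#' @param external_absence_fraction Fraction of cohort singletons that are
#'   also absent (allele count 0) from the simulated external population
#'   cohorts, i.e. qualify as URVs.
#' @param outlier_fraction Fraction of samples with an inflated total URV
#'   count (the ancestry-heterogeneity proxy tail).
#' @param outlier_urv_multiplier Multiplier on the URV rate for outliers.
#' @param genotype_fail_fraction Fraction of called genotypes drawn with
#'   DP < 10 or GQ < 20 (fails genotype QC).
#' @param target_annotation Name of the annotation track that carries the
#'   embedded case/control burden effect.
#' @param annotation_burden_or Embedded odds ratio (>= 1) per unit count of
#'   target-annotation URVs; the case rate of target URVs is
#'   `annotation_burden_or` times the control rate.
#' @param target_urv_rate Mean number of target-annotation URVs per control
#'   sample.
#' @param sv_counts_per_type Named integer vector of SV site counts to
#'   simulate (DEL/DUP/INV).
#' @param sv_size_median_per_type Named vector of target (truncated) median
#'   SV sizes in bases.
#' @param sv_size_sdlog Log-scale standard deviation of the lognormal SV size
#'   distribution (shared across types; gives the long right tail).
#' @param sv_size_range Truncation bounds for DEL/DUP/INV sizes, in bases.
#' @param sv_ultra_rare_fraction Fraction of SV sites that are cohort
#'   singletons (allele count 1).
#' @param sv_pop_absent_fraction Fraction of SV sites absent from the
#'   simulated population databases (maximum overlap < 30%).
#' @param sv_target_rate Mean number per control sample of ultra-rare SVs that
#'   intersect >= 10% of a target-annotation element; case rate is
#'   `annotation_burden_or` times this.
#' @param h2_liability Narrow-sense heritability on the liability scale used
#'   by [simulate_liability_phenotype()].
#' @param prevalence_K Lifetime risk (population prevalence) in (0, 0.5).
#' @param seed Master integer seed; every generator stage derives a named
#'   substream from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, chrom_length = 2e6,
#'                   mean_urv_per_sample = 30)
#' cfg$n_cases
sim_config <- function(n_cases = 1162,
                       n_controls = 936,
                       n_chromosomes = 2,
                       chrom_length = 25e6,
                       tad_bin_width = 40000,
                       tad_boundary_fraction = 0.1,
                       snv_singleton_fraction = 0.4543,
                       indel_singleton_fraction = 0.3703,
                       indel_fraction = 0.12,
                       mean_urv_per_sample = 4250,
                       external_absence_fraction = 0.47,
                       outlier_fraction = 0.03,
                       outlier_urv_multiplier = 2,
                       genotype_fail_fraction = 0.01,
                       target_annotation = "tad_boundary",
                       annotation_burden_or = 1,
                       target_urv_rate = 5,
                       sv_counts_per_type = c(DEL = 17895, DUP = 4129, INV = 4458),
                       sv_size_median_per_type = c(DEL = 2592, DUP = 7179, INV = 3265),
                       sv_size_sdlog = 1.5,
                       sv_size_range = c(500, 1e6),
                       sv_ultra_rare_fraction = 0.35,
                       sv_pop_absent_fraction = 0.5,
                       sv_target_rate = 0.08,
                       h2_liability = 0.45,
                       prevalence_K = 0.01,
                       seed = 1L) {
  assert_count(n_cases, "n_cases", min = 2L)
  assert_count(n_controls, "n_controls", min = 2L)
  assert_count(n_chromosomes, "n_chromosomes", min = 1L)
  assert_count(chrom_length, "chrom_length", min = 1L)
  assert_count(tad_bin_width, "tad_bin_width", min = 1L)
  if (chrom_length %% tad_bin_width != 0) {
    abort("`chrom_length` must be divisible by `tad_bin_width`")
  }
  assert_prop(tad_boundary_fraction, "tad_boundary_fraction")
  assert_prop(snv_singleton_fraction, "snv_singleton_fraction")
  assert_prop(indel_singleton_fraction, "indel_singleton_fraction")
  assert_prop(indel_fraction, "indel_fraction")
  assert_prop(external_absence_fraction, "external_absence_fraction")
  assert_prop(outlier_fraction, "outlier_fraction")
  assert_prop(genotype_fail_fraction, "genotype_fail_fraction")
  assert_prop(sv_ultra_rare_fraction, "sv_ultra_rare_fraction")
  assert_prop(sv_pop_absent_fraction, "sv_pop_absent_fraction")
  assert_prop(h2_liability, "h2_liability")
  if (!is.numeric(annotation_burden_or) || annotation_burden_or < 1) {
    abort("`annotation_burden_or` must be >= 1")
  }
  if (!is.numeric(prevalence_K) || prevalence_K <= 0 || prevalence_K >= 0.5) {
    abort("`prevalence_K` must lie in (0, 0.5)")
  }
  if (mean_urv_per_sample <= 0 || target_urv_rate < 0 || sv_target_rate < 0) {
    abort("URV rates must be positive")
  }
  if (outlier_urv_multiplier < 1) {
    abort("`outlier_urv_multiplier` must be >= 1")
  }
  types <- c("DEL", "DUP", "INV")
  if (!all(types %in% names(sv_counts_per_type)) ||
      !all(types %in% names(sv_size_median_per_type))) {
    abort("SV count and size-median vectors must name DEL, DUP and INV")
  }
  if (any(sv_counts_per_type < 0)) abort("SV counts must be >= 0")
  if (length(sv_size_range) != 2L || sv_size_range[1] <= 0 ||
      sv_size_range[2] <= sv_size_range[1]) {
    abort("`sv_size_range` must be an increasing positive pair")
  }
  assert_count(seed, "seed")

  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.numeric(chrom_length),
      tad_bin_width = as.numeric(tad_bin_width),
      tad_boundary_fraction = tad_boundary_fraction,
      snv_singleton_fraction = snv_singleton_fraction,
      indel_singleton_fraction = indel_singleton_fraction,
      indel_fraction = indel_fraction,
      mean_urv_per_sample = mean_urv_per_sample,
      external_absence_fraction = external_absence_fraction,
      outlier_fraction = outlier_fraction,
      outlier_urv_multiplier = outlier_urv_multiplier,
      genotype_fail_fraction = genotype_fail_fraction,
      target_annotation = target_annotation,
      annotation_burden_or = annotation_burden_or,
      target_urv_rate = target_urv_rate,
      sv_counts_per_type = sv_counts_per_type[types],
      sv_size_median_per_type = sv_size_median_per_type[types],
      sv_size_sdlog = sv_size_sdlog,
      sv_size_range = as.numeric(sv_size_range),
      sv_ultra_rare_fraction = sv_ultra_rare_fraction,
      sv_pop_absent_fraction = sv_pop_absent_fraction,
      sv_target_rate = sv_target_rate,
      h2_liability = h2_liability,
      prevalence_K = prevalence_K,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cases, " cases / ", x$n_controls, " controls, ",
      x$n_chromosomes, " x ", format(x$chrom_length, big.mark = ","),
      " bp, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
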