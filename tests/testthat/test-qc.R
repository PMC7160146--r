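test_that("genotype QC masks exactly the DP/GQ failures", {
  v <- tibble::tibble(
    variant_id = c("a", "b"), chrom = "chr1", pos = c(10, 20),
    ref = "A", alt = "T", variant_class = "SNV", cohort_ac = 0L,
    ext_ac_gnomad = 0L, consequence_class = "noncoding"
  )
  s <- tibble::tibble(sample_id = c("s1", "s2"), phenotype = c(1L, 0L))
  geno <- matrix(c(1L, 1L, 1L, 1L), 2)
  dp <- matrix(c(9L, 10L, 35L, 12L), 2)    # s1/a fails DP
  gq <- matrix(c(99L, 20L, 19L, 80L), 2)   # s2/a fails GQ (dp/gq col-major)
  co <- rv_cohort(v, s, geno, dp = dp, gq = gq)
  out <- apply_genotype_qc(co)
  expect_true(is.na(out$geno[1, 1]))   # DP = 9 < 10 -> missing
  expect_false(is.na(out$geno[2, 1]))  # DP = 10, GQ = 20 boundary retained
  expect_true(is.na(out$geno[1, 2]))   # GQ = 19 -> missing
  expect_false(is.na(out$geno[2, 2]))
  expect_equal(out$variants$cohort_ac, c(0L, 2L))
  # all-pass input is untouched
  co2 <- co; co2$dp[] <- 30L; co2$gq[] <- 90L
  expect_equal(apply_genotype_qc(co2)$geno, co2$geno)
  co3 <- co; co3$dp <- NULL
  expect_error(apply_genotype_qc(co3), "dp")
})

test_that("masked fraction tracks the configured genotype failure rate", {
  co <- fixture_cohort()
  out <- apply_genotype_qc(co)
  frac <- mean(is.na(out$geno))
  expect_lt(abs(frac - small_config()$genotype_fail_fraction), 0.002)
})

test_that("exact HWE test matches the closed-form enumeration oracle", {
  # exhaustive over all tables with n <= 30
  for (n in c(2, 3, 7, 12, 30)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                   tolerance = 1e-12,
                   info = paste(n0, n1, n2))
    }
  }
  # random larger tables up to n = 200
  set.seed(99)
  for (i in 1:200) {
    n <- sample(31:200, 1)
    n0 <- sample(0:n, 1)
    n1 <- sample(0:(n - n0), 1)
    n2 <- n - n0 - n1
    expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-12, info = paste(n0, n1, n2))
  }
})

test_that("HWE test is symmetric in allele relabelling and handles edges", {
  expect_equal(hwe_exact_test(57, 14, 50), hwe_exact_test(50, 14, 57))
  expect_equal(hwe_exact_test(10, 0, 0), 1)   # monomorphic
  # heterozygotes only: matches the oracle's exact tail probability
  for (n in c(2, 5, 20)) {
    expect_equal(hwe_exact_test(0, n, 0), hwe_oracle(0, n, 0),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("variant filters remove by reason and reconcile counts", {
  set.seed(14)
  n <- 200
  s <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                      phenotype = rep(c(1L, 0L), each = n / 2))
  m <- 40
  geno <- matrix(rbinom(m * n, 2, 0.3), m, n)
  geno[1, ] <- 0L                               # monomorphic
  geno[2, sample.int(n, 10)] <- NA_integer_     # 5% missing overall
  geno[3, 1:3] <- NA_integer_    # 3% missing in cases, 0% in controls:
                                 # overall 1.5% passes, difference fails
  # engineered extreme HWE violation in controls: all heterozygous
  geno[4, (n / 2 + 1):n] <- 1L
  v <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:m), chrom = "chr1", pos = 1:m * 100,
    ref = "A", alt = "T", variant_class = "SNV", cohort_ac = 0L,
    ext_ac_gnomad = 0L, consequence_class = "noncoding"
  )
  co <- rv_cohort(v, s, geno)
  res <- filter_variants(co)
  reasons <- setNames(res$report$reason, res$report$variant_id)
  expect_equal(reasons[["v01"]], "monomorphic")
  expect_equal(reasons[["v02"]], "missing_rate")
  expect_equal(reasons[["v03"]], "differential_missingness")
  expect_equal(reasons[["v04"]], "hwe")
  counts <- attr(res$report, "counts")
  input <- counts$n[counts$filter == "input"]
  output <- counts$n[counts$filter == "output"]
  expect_equal(input - nrow(res$report), output)
  expect_equal(output, nrow(res$cohort$variants))
  # clean variant is retained
  expect_false("v05" %in% res$report$variant_id)
  expect_error(filter_variants(rv_cohort(v, dplyr::mutate(s, phenotype = 1L),
                                         geno)),
               "cases and controls")
})

test_that("variant filtering is idempotent", {
  co <- apply_genotype_qc(fixture_cohort())
  once <- filter_variants(co)
  twice <- filter_variants(once$cohort)
  expect_equal(nrow(twice$report), 0)
  expect_identical(once$cohort$variants$variant_id,
                   twice$cohort$variants$variant_id)
})

test_that("relatedness estimates identity, null pairs and parent-child", {
  set.seed(21)
  m <- 800
  p <- runif(m, 0.1, 0.5)
  n_bg <- 60
  G <- matrix(rbinom(m * n_bg, 2, rep(p, n_bg)), m, n_bg)
  shared <- rbinom(m, 1, p)                     # transmitted haplotype
  parent <- shared + rbinom(m, 1, p)
  child <- shared + rbinom(m, 1, p)
  G <- cbind(G, parent, child, dup = parent)
  colnames(G) <- c(sprintf("u%02d", 1:n_bg), "parent", "child", "dup")
  ph <- estimate_relatedness(G)
  expect_gte(ph["parent", "dup"], 0.95)              # duplicated sample
  expect_lt(abs(ph["parent", "child"] - 0.5), 0.05)  # parent-child
  off <- ph[sprintf("u%02d", 1:n_bg), sprintf("u%02d", 1:n_bg)]
  expect_lt(abs(mean(off[upper.tri(off)])), 0.02)    # unrelated ~ 0
  expect_true(all(abs(diag(ph) - 1) < 0.2))
  # pruning leaves no pair above threshold
  kept <- prune_related(ph, threshold = 0.2)
  sub <- ph[kept, kept]
  diag(sub) <- 0
  expect_true(all(sub <= 0.2))
  expect_true(length(kept) <= ncol(G) - 2)  # dup + one of parent/child gone
  expect_warning(estimate_relatedness(G[1:10, ]), "unstable")
})

test_that("URV outlier pruning is strict and recovers the outlier fraction", {
  out <- prune_urv_outliers(c(a = 5900, b = 6000, c = 6001), threshold = 6000)
  expect_equal(out$kept, c(TRUE, TRUE, FALSE))
  all_low <- prune_urv_outliers(c(10, 20), threshold = 6000)
  expect_true(all(all_low$kept))
  # generator truth: outlier_fraction at multiplier 2 is recovered
  cfg <- small_config(seed = 77, outlier_fraction = 0.05,
                      outlier_urv_multiplier = 2, mean_urv_per_sample = 60)
  co <- simulate_snv_cohort(cfg, fixture_tracks())
  urv <- count_per_sample(co, "genome_wide")
  thr <- qc_thresholds(urv_outlier_threshold = NULL,
                       mean_urv = cfg$mean_urv_per_sample)
  pruned <- prune_urv_outliers(
    tibble::tibble(sample_id = urv$sample_id, urv_count = urv$count),
    threshold = thr$urv_outlier_threshold
  )
  frac <- mean(!pruned$kept)
  n <- nrow(pruned)
  ci <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), ci + 0.01)
})

test_that("SV blacklist filter uses the 66% union rule", {
  s <- tibble::tibble(sample_id = c("s1", "s2"), phenotype = c(1L, 0L))
  svs <- tibble::tibble(
    sv_id = c("in_bl", "at_66", "split_70", "clear"),
    chrom = "chr1",
    start = c(1000, 2000, 3000, 50000),
    end = c(1100, 3000, 4000, 51000),
    svtype = "DEL", cohort_ac = 0L, pop_db_max_overlap = 0
  )
  geno <- matrix(1L, 4, 2)
  svset <- sv_callset(svs, s, geno)
  bl <- tibble::tibble(
    chrom = "chr1",
    start = c(900, 2000, 3000, 3600),
    end = c(1200, 2660, 3400, 3900)
  )
  out <- filter_sv_blacklist(svset, bl, max_fraction = 0.66)
  expect_setequal(attr(out, "removed"), c("in_bl", "split_70"))
  # fully covered -> removed; exactly 66% -> retained; union 40%+30% -> removed
  expect_setequal(out$svs$sv_id, c("at_66", "clear"))
})
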