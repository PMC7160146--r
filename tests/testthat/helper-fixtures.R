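# Shared small-scale fixtures, built once per test run. Sizes are chosen so
# the whole suite stays fast; rates and embedded effects keep the study
# structure (singleton fractions, outlier tail, liability threshold).

small_config <- function(seed = 101, ...) {
  args <- list(
    n_cases = 80, n_controls = 80, n_chromosomes = 2, chrom_length = 1e6,
    mean_urv_per_sample = 25, target_urv_rate = 4,
    sv_counts_per_type = c(DEL = 400, DUP = 150, INV = 120),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

fixture_env <- new.env()

fixture_tracks <- function() {
  if (is.null(fixture_env$tracks)) {
    fixture_env$tracks <- simulate_annotation_genome(small_config())
  }
  fixture_env$tracks
}

fixture_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- simulate_snv_cohort(small_config(), fixture_tracks())
  }
  fixture_env$cohort
}

fixture_svset <- function() {
  if (is.null(fixture_env$svset)) {
    fixture_env$svset <- simulate_sv_cohort(small_config(), fixture_tracks())
  }
  fixture_env$svset
}

# Hand-built minimal annotation_tracks for arithmetic-level tests: one 300-bp
# chromosome, CDTS bins and GERP segments set explicitly.
toy_tracks <- function(cdts_percentiles, gerp = NULL, chrom_length = NULL) {
  chrom_length <- chrom_length %||% (10 * length(cdts_percentiles))
  structure(list(
    chromosomes = tibble::tibble(chrom = "chr1", length = chrom_length),
    cdts = tibble::tibble(
      chrom = "chr1",
      start = (seq_along(cdts_percentiles) - 1) * 10,
      end = seq_along(cdts_percentiles) * 10,
      percentile = cdts_percentiles
    ),
    gerp = gerp %||% tibble::tibble(chrom = "chr1", start = 0,
                                    end = chrom_length, score = 0),
    annotations = list(),
    genes = tibble::tibble(), cds = tibble::tibble(),
    blacklist = tibble::tibble(chrom = character(), start = numeric(),
                               end = numeric())
  ), class = "annotation_tracks")
}

# Independent Fisher oracle: full enumeration over the hypergeometric
# support with probability-mass ordering.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  dens <- choose(m1, support) * choose(m2, k - support) / choose(m1 + m2, k)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

# Independent HWE oracle: direct closed-form table probabilities via
# choose() products (no recurrence), probability-mass ordering.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * min(n0, n2) + n1
  if (na == 0) return(1)
  h <- seq(na %% 2, na, by = 2)
  naa <- (na - h) / 2
  nbb <- n - naa - h
  logp <- lchoose(n, naa) + lchoose(n - naa, h) + h * log(2) -
    lchoose(2 * n, na)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n1, h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}
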