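#' Simulate a case-control SNV/indel cohort with embedded burden effects
#'
#' Generates a sequence-variant cohort with the statistical structure the
#' burden analysis assumes: cohort singletons at the configured SNV/indel
#' singleton fractions (each carried as a heterozygote by exactly one
#' sample), a configured fraction of singletons absent from simulated
#' external population cohorts (these are the ultra-rare variants, URVs),
#' per-genotype DP/GQ with a configured failure rate, consequence classes
#' assigned from the gene models, an outlier tail of samples with inflated
#' URV counts, pseudo-principal-component covariates (PC1 tracks outlier
#' status, PC2 weakly tracks phenotype, PC3 is noise), and URVs placed in the
#' target annotation at a case:control rate ratio equal to the configured
#' embedded odds ratio.
#'
#' @param config A [sim_config()].
#' @param tracks Output of [simulate_annotation_genome()] (must contain
#'   `config$target_annotation`).
#' @return An [rv_cohort()] with a `truth` attribute (embedded odds ratio per
#'   annotation, causal variant ids) for recovery testing.
#' @export
simulate_snv_cohort <- function(config, tracks) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  if (!inherits(tracks, "annotation_tracks")) {
    abort("`tracks` must come from simulate_annotation_genome()")
  }
  target <- config$target_annotation
  if (!target %in% names(tracks$annotations)) {
    abort(paste0("target annotation '", target, "' not present in tracks"))
  }
  with_seed(derive_seed(config$seed, "snv"), {
    n_case <- config$n_cases
    n_ctrl <- config$n_controls
    n <- n_case + n_ctrl
    phenotype <- c(rep(1L, n_case), rep(0L, n_ctrl))
    outlier <- runif(n) < config$outlier_fraction
    samples <- tibble::tibble(
      sample_id = sprintf("S%05d", seq_len(n)),
      phenotype = phenotype,
      sex = sample(1:2, n, replace = TRUE),
      mean_coverage = rnorm(n, 36.6, 2),
      urv_outlier = outlier,
      PC1 = as.numeric(scale(as.numeric(outlier))) * 1.2 + rnorm(n, 0, 0.6),
      PC2 = 0.35 * (phenotype - mean(phenotype)) + rnorm(n),
      PC3 = rnorm(n)
    )

    # per-sample URV counts: baseline (outside the target annotation) and
    # target-annotation counts with case rate = OR x control rate
    base_rate <- config$mean_urv_per_sample *
      ifelse(outlier, config$outlier_urv_multiplier, 1)
    n_base <- rpois(n, base_rate)
    t_rate <- config$target_urv_rate *
      ifelse(phenotype == 1L, config$annotation_burden_or, 1)
    n_target <- rpois(n, t_rate)

    s_urv <- sum(n_base) + sum(n_target)
    phi <- config$external_absence_fraction
    n_ext_single <- round(s_urv * (1 - phi) / max(phi, 1e-9))

    # carriers: URVs by per-sample counts, externally-seen singletons uniform
    carrier <- c(rep(seq_len(n), times = n_base),
                 rep(seq_len(n), times = n_target),
                 sample.int(n, n_ext_single, replace = TRUE))
    is_target <- c(rep(FALSE, sum(n_base)), rep(TRUE, sum(n_target)),
                   rep(FALSE, n_ext_single))
    ext_present <- c(rep(FALSE, sum(n_base) + sum(n_target)),
                     rep(TRUE, n_ext_single))
    s_all <- length(carrier)

    # split singletons into SNV/indel and size the non-singleton background
    # so realized singleton fractions hit the configured per-class targets
    is_indel_s <- runif(s_all) < config$indel_fraction
    s_snv <- sum(!is_indel_s)
    s_ind <- sum(is_indel_s)
    nb_snv <- max(0L, round(s_snv / config$snv_singleton_fraction) - s_snv)
    nb_ind <- max(0L, round(s_ind / config$indel_singleton_fraction) - s_ind)
    nb <- nb_snv + nb_ind

    m <- s_all + nb
    chrom <- sample(tracks$chromosomes$chrom, m, replace = TRUE)
    pos0 <- floor(runif(m, 0, config$chrom_length))  # 0-based, refined below

    # target URVs inside the target annotation, weighted by element width
    tg <- tracks$annotations[[target]]
    t_idx <- which(is_target)
    if (length(t_idx)) {
      if (nrow(tg) == 0L) abort("target annotation track is empty")
      w <- tg$end - tg$start
      el <- sample.int(nrow(tg), length(t_idx), replace = TRUE,
                       prob = w / sum(w))
      chrom[t_idx] <- tg$chrom[el]
      pos0[t_idx] <- floor(tg$start[el] + runif(length(t_idx)) * w[el])
    }
    # baseline URVs kept out of the target annotation so embedded target
    # counts are exactly the Poisson construction above
    b_idx <- which(!is_target & !ext_present)  # indices within the singletons
    pos0[b_idx] <- resample_outside(chrom[b_idx], pos0[b_idx], tg,
                                    config$chrom_length)

    variant_class <- character(m)
    variant_class[seq_len(s_all)] <- ifelse(is_indel_s, "indel", "SNV")
    variant_class[s_all + seq_len(nb)] <-
      rep(c("SNV", "indel"), times = c(nb_snv, nb_ind))

    # genotype matrix: singletons are heterozygous in exactly one sample
    geno <- matrix(0L, nrow = m, ncol = n)
    geno[cbind(seq_len(s_all), carrier)] <- 1L
    if (nb > 0L) {
      p_bg <- ifelse(runif(nb) < 0.7, runif(nb, 0.005, 0.05),
                     runif(nb, 0.05, 0.5))
      bg <- matrix(rbinom(nb * n, 2L, rep(p_bg, times = n)),
                   nrow = nb, ncol = n)
      low <- which(rowSums(bg) < 2L)
      for (i in low) {  # enforce AC >= 2 so singleton status is by design
        bg[i, ] <- 0L
        bg[i, sample.int(n, 2L)] <- 1L
      }
      geno[s_all + seq_len(nb), ] <- bg
    }

    # external population allele counts
    ext_ac <- integer(m)
    ext_ac[which(ext_present)] <- 1L + rpois(sum(ext_present), 2)
    if (nb > 0L) {
      # non-singleton sites are seen in a large external cohort at a rate
      # proportional to their cohort allele frequency
      af_bg <- rowMeans(geno[s_all + seq_len(nb), , drop = FALSE]) / 2
      ext_ac[s_all + seq_len(nb)] <- rpois(nb, af_bg * 10000)
    }

    # consequence classes from CDS overlap
    consequence <- rep("noncoding", m)
    vpos <- tibble::tibble(chrom = chrom, start = pos0, end = pos0 + 1)
    hits <- interval_overlap_pairs(vpos, tracks$cds)
    coding_idx <- unique(hits$query_idx)
    if (length(coding_idx)) {
      consequence[coding_idx] <- sample(
        c("synonymous", "missense_nondamaging", "missense_damaging", "LOF"),
        length(coding_idx), replace = TRUE,
        prob = c(0.25, 0.30, 0.20, 0.25)
      )
    }

    bases <- c("A", "C", "G", "T")
    ri <- sample.int(4L, m, replace = TRUE)
    ref <- bases[ri]
    alt <- bases[(ri - 1L + sample.int(3L, m, replace = TRUE)) %% 4L + 1L]
    ins <- variant_class == "indel"
    alt[ins] <- paste0(ref[ins],
                       bases[sample.int(4L, sum(ins), replace = TRUE)])

    # per-genotype DP/GQ with a configured QC-failure rate; passing cells
    # draw uniformly above the QC cut, failing cells below it
    nc <- m * n
    dp <- matrix(sample.int(51L, nc, replace = TRUE) + 9L, m, n)
    gq <- matrix(sample.int(80L, nc, replace = TRUE) + 19L, m, n)
    fail_idx <- which(runif(nc) < config$genotype_fail_fraction)
    if (length(fail_idx)) {
      low_dp <- runif(length(fail_idx)) < 0.5
      dp[fail_idx[low_dp]] <- sample.int(10L, sum(low_dp),
                                         replace = TRUE) - 1L
      gq[fail_idx[!low_dp]] <- sample.int(20L, sum(!low_dp),
                                          replace = TRUE) - 1L
    }

    variants <- tibble::tibble(
      variant_id = sprintf("v%07d", seq_len(m)),
      chrom = chrom, pos = as.numeric(pos0) + 1, ref = ref, alt = alt,
      variant_class = variant_class,
      cohort_ac = 0L,  # recomputed by the constructor
      ext_ac_gnomad = ext_ac,
      ext_ac_exac = ifelse(ext_ac > 0L, rpois(m, 1), 0L),
      consequence_class = consequence
    )
    cohort <- rv_cohort(variants, samples, geno, dp = dp, gq = gq)
    attr(cohort, "truth") <- list(
      embedded_or_per_annotation =
        setNames(config$annotation_burden_or, target),
      causal_variant_ids = variants$variant_id[which(is_target)],
      true_h2 = NA_real_
    )
    cohort
  })
}

# Move positions of baseline URVs off the target annotation (rejection
# sampling against the annotation intervals).
resample_outside <- function(chrom, pos0, track, chrom_length) {
  if (nrow(track) == 0L || length(pos0) == 0L) return(pos0)
  for (iter in 1:25) {
    vp <- tibble::tibble(chrom = chrom, start = pos0, end = pos0 + 1)
    inside <- unique(interval_overlap_pairs(vp, track)$query_idx)
    if (!length(inside)) break
    pos0[inside] <- floor(runif(length(inside), 0, chrom_length))
  }
  pos0
}

#' Simulate a structural-variant call set with an embedded TAD-boundary effect
#'
#' SV sites are drawn per type (DEL/DUP/INV) with lognormal sizes whose
#' truncated median matches the configured per-type median (truncation bounds
#' default to 500 bp - 1 Mb), uniform placement, a configured fraction of
#' cohort singletons and of population-database-absent sites, and an embedded
#' case enrichment: additional ultra-rare SVs that intersect >= 10% of a
#' target-annotation element are assigned to cases at
#' `annotation_burden_or` times the control rate.
#'
#' @inheritParams simulate_snv_cohort
#' @return An [sv_callset()] with a `truth` attribute.
#' @export
simulate_sv_cohort <- function(config, tracks) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  if (!inherits(tracks, "annotation_tracks")) {
    abort("`tracks` must come from simulate_annotation_genome()")
  }
  target <- config$target_annotation
  if (!target %in% names(tracks$annotations)) {
    abort(paste0("target annotation '", target, "' not present in tracks"))
  }
  with_seed(derive_seed(config$seed, "sv"), {
    n_case <- config$n_cases
    n_ctrl <- config$n_controls
    n <- n_case + n_ctrl
    phenotype <- c(rep(1L, n_case), rep(0L, n_ctrl))
    samples <- tibble::tibble(
      sample_id = sprintf("S%05d", seq_len(n)),
      phenotype = phenotype,
      sex = sample(1:2, n, replace = TRUE),
      mean_coverage = rnorm(n, 36.6, 2),
      PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n)
    )

    types <- names(config$sv_counts_per_type)
    recs <- purrr::map_dfr(types, function(tp) {
      k <- config$sv_counts_per_type[[tp]]
      if (k == 0L) {
        return(tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), svtype = character()))
      }
      size <- rlnorm_truncated(
        k, median_target = config$sv_size_median_per_type[[tp]],
        sdlog = config$sv_size_sdlog,
        lower = config$sv_size_range[1], upper = config$sv_size_range[2]
      )
      size <- pmin(size, config$chrom_length - 1)
      ch <- sample(tracks$chromosomes$chrom, k, replace = TRUE)
      st <- floor(runif(k, 0, config$chrom_length - size))
      tibble::tibble(chrom = ch, start = st, end = st + round(size),
                     svtype = tp)
    })
    m0 <- nrow(recs)
    ur <- runif(m0) < config$sv_ultra_rare_fraction
    absent <- runif(m0) < config$sv_pop_absent_fraction
    pop_ov <- ifelse(absent, runif(m0, 0, 0.299), runif(m0, 0.30, 1))

    geno <- matrix(0L, nrow = m0, ncol = n)
    if (any(ur)) {
      geno[cbind(which(ur), sample.int(n, sum(ur), replace = TRUE))] <- 1L
    }
    n_carr <- 2L + rpois(sum(!ur), 6)
    for (j in seq_along(which(!ur))) {
      i <- which(!ur)[j]
      geno[i, sample.int(n, min(n_carr[j], n))] <- 1L
    }

    # embedded TAD-affecting ultra-rare SVs (absent from population DBs)
    t_counts <- rpois(n, config$sv_target_rate *
                        ifelse(phenotype == 1L, config$annotation_burden_or, 1))
    tg <- tracks$annotations[[target]]
    n_t <- sum(t_counts)
    truth_ids <- character(0)
    if (n_t > 0L) {
      if (nrow(tg) == 0L) abort("target annotation track is empty")
      el <- sample.int(nrow(tg), n_t, replace = TRUE)
      w <- tg$end[el] - tg$start[el]
      size <- pmax(rlnorm_truncated(n_t, config$sv_size_median_per_type[["DEL"]],
                                    config$sv_size_sdlog,
                                    config$sv_size_range[1],
                                    config$sv_size_range[2]),
                   ceiling(0.12 * w))
      required <- ceiling(0.105 * w)
      off <- floor(runif(n_t, -(size - required), w - required))
      st <- pmax(0, tg$start[el] + off)
      en <- pmin(st + round(size), config$chrom_length)
      carrier <- rep(seq_len(n), times = t_counts)
      t_recs <- tibble::tibble(
        chrom = tg$chrom[el], start = st, end = en,
        svtype = sample(c("DEL", "DUP", "INV"), n_t, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
      )
      t_geno <- matrix(0L, nrow = n_t, ncol = n)
      t_geno[cbind(seq_len(n_t), carrier)] <- 1L
      recs <- dplyr::bind_rows(recs, t_recs)
      geno <- rbind(geno, t_geno)
      pop_ov <- c(pop_ov, runif(n_t, 0, 0.25))
      truth_ids <- sprintf("sv%06d", m0 + seq_len(n_t))
    }

    svs <- recs |>
      dplyr::mutate(
        sv_id = sprintf("sv%06d", dplyr::row_number()),
        cohort_ac = 0L,
        pop_db_max_overlap = pop_ov
      ) |>
      dplyr::select("sv_id", "chrom", "start", "end", "svtype",
                    "cohort_ac", "pop_db_max_overlap")
    out <- sv_callset(svs, samples, geno)
    attr(out, "truth") <- list(
      embedded_or_per_annotation =
        setNames(config$annotation_burden_or, target),
      causal_variant_ids = truth_ids,
      true_h2 = NA_real_
    )
    out
  })
}

# Lognormal sizes truncated to [lower, upper] whose *truncated* median equals
# `median_target`; the location parameter is solved by monotone root finding.
rlnorm_truncated <- function(n, median_target, sdlog, lower, upper) {
  if (median_target <= lower || median_target >= upper) {
    abort("target median must lie inside the truncation bounds")
  }
  f <- function(mu) {
    pl <- plnorm(lower, mu, sdlog)
    pu <- plnorm(upper, mu, sdlog)
    qlnorm(pl + 0.5 * (pu - pl), mu, sdlog) - median_target
  }
  mu <- uniroot(f, interval = log(median_target) + c(-6, 6), tol = 1e-8)$root
  pl <- plnorm(lower, mu, sdlog)
  pu <- plnorm(upper, mu, sdlog)
  qlnorm(pl + runif(n) * (pu - pl), mu, sdlog)
}

#' Simulate a liability-threshold phenotype from genotypes
#'
#' Draws per-variant additive effects with total genetic variance `h2` on the
#' standardized scale, adds a normal residual of variance `1 - h2`, and
#' labels as cases the samples whose liability exceeds the empirical
#' `(1 - K)` quantile of the realized liability distribution. Optional
#' case/control subsampling ("oversampling" of cases relative to the
#' population) returns an ascertained subset.
#'
#' @param geno Numeric genotype matrix, samples in rows, variants in columns,
#'   dosages 0/1/2 (no missing values).
#' @param h2 Liability-scale heritability in `[0, 1]`.
#' @param K Population prevalence (lifetime risk) in (0, 1).
#' @param seed Integer seed.
#' @param n_cases,n_controls Optional ascertained sample sizes; if given, a
#'   random subset of cases/controls of that size is flagged `selected`.
#' @return A list with `phenotype`, a tibble (`sample`, `liability`,
#'   `phenotype`, `selected`), and `truth` (true h2, per-variant effects,
#'   realized threshold).
#' @export
simulate_liability_phenotype <- function(geno, h2, K, seed = 1L,
                                         n_cases = NULL, n_controls = NULL) {
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) abort("`h2` must be in [0, 1]")
  if (K <= 0 || K >= 1) abort("`K` must be in (0, 1)")
  n <- nrow(geno)
  m <- ncol(geno)
  with_seed(derive_seed(seed, "liability"), {
    if (h2 > 0) {
      p <- colMeans(geno) / 2
      ok <- p > 0 & p < 1
      z <- sweep(geno[, ok, drop = FALSE], 2, 2 * p[ok])
      z <- sweep(z, 2, sqrt(2 * p[ok] * (1 - p[ok])), "/")
      beta <- rnorm(sum(ok), 0, sqrt(h2 / sum(ok)))
      g <- drop(z %*% beta)
    } else {
      g <- numeric(n)
    }
    liab <- g + rnorm(n, 0, sqrt(1 - h2))
    thr <- quantile(liab, 1 - K, names = FALSE, type = 7)
    pheno <- as.integer(liab > thr)
    selected <- rep(TRUE, n)
    if (!is.null(n_cases) || !is.null(n_controls)) {
      selected <- rep(FALSE, n)
      cs <- which(pheno == 1L)
      ct <- which(pheno == 0L)
      n_cases <- n_cases %||% length(cs)
      n_controls <- n_controls %||% length(ct)
      if (length(cs) < n_cases || length(ct) < n_controls) {
        abort("not enough cases/controls realized for requested ascertainment")
      }
      selected[sample(cs, n_cases)] <- TRUE
      selected[sample(ct, n_controls)] <- TRUE
    }
    ids <- rownames(geno) %||% sprintf("S%05d", seq_len(n))
    list(
      phenotype = tibble::tibble(
        sample = ids, liability = liab, phenotype = pheno,
        selected = selected
      ),
      truth = list(true_h2 = h2, genetic_values = g, threshold = thr)
    )
  })
}
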