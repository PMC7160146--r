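test_that("phenotype-predicting PCs are selected and null PCs are not", {
  set.seed(61)
  n <- 400
  d <- tibble::tibble(
    phenotype = rep(c(1L, 0L), each = n / 2),
    PC1 = rnorm(n),
    PC2 = rnorm(n)
  )
  d$PC2 <- d$phenotype + rnorm(n, 0, 0.5)  # near-perfect predictor
  sel <- select_covariates_phenotype(d, pcs = c("PC1", "PC2"))
  expect_true(sel$selected[sel$pc == "PC2"])
  expect_false(sel$selected[sel$pc == "PC1"])
  expect_error(
    select_covariates_phenotype(dplyr::mutate(d, phenotype = 1L)),
    "constant")
  # null selection rate ~ alpha: 20 null PCs over repeated draws
  set.seed(62)
  hits <- replicate(40, {
    dd <- tibble::as_tibble(setNames(
      as.data.frame(matrix(rnorm(200 * 20), 200)), paste0("PC", 1:20)))
    dd$phenotype <- rep(c(1L, 0L), each = 100)
    sum(select_covariates_phenotype(dd, pcs = paste0("PC", 1:20))$selected)
  })
  expect_lt(abs(mean(hits) - 0.2), 0.25)
})

test_that("SV-count covariate selection flags the driving PC", {
  set.seed(63)
  n <- 300
  d <- tibble::tibble(
    sex = sample(1:2, n, TRUE), mean_coverage = rnorm(n, 36, 2),
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n)
  )
  d$global_count <- rpois(n, exp(1.5 + 0.5 * d$PC1))
  sel <- select_covariates_svcount(d)
  expect_true(sel$selected[sel$pc == "PC1"])
  d2 <- dplyr::mutate(d, PC3 = PC2)
  expect_error(select_covariates_svcount(d2), "collinear")
})

test_that("logistic burden OR equals the contingency-table OR for a binary
           predictor", {
  set.seed(64)
  n <- 600
  ph <- rep(c(1L, 0L), each = n / 2)
  x <- rbinom(n, 1, ifelse(ph == 1, 0.3, 0.18))
  d <- tibble::tibble(phenotype = ph, count = x)
  fit <- fit_logistic_burden(d)
  a <- sum(ph == 1 & x == 1); b <- sum(ph == 1 & x == 0)
  c2 <- sum(ph == 0 & x == 1); d2 <- sum(ph == 0 & x == 0)
  expect_equal(fit$odds_ratio, (a * d2) / (b * c2), tolerance = 1e-6)
  expect_true(fit$ci_lower < fit$odds_ratio & fit$odds_ratio < fit$ci_upper)
  # degenerate target: zero information is flagged
  flat <- fit_logistic_burden(tibble::tibble(phenotype = ph, count = 2))
  expect_true(flat$zero_information)
  expect_error(fit_logistic_burden(d[1:12, ]), "at least 10")
})

test_that("embedded odds ratio is recovered by the burden model", {
  ors <- c()
  for (seed in 1:6) {
    cfg <- small_config(seed = 400 + seed, annotation_burden_or = 2,
                        mean_urv_per_sample = 15)
    co <- simulate_snv_cohort(cfg, fixture_tracks())
    cnt <- count_per_sample(co, "tad_boundary", tracks = fixture_tracks())
    fit <- fit_logistic_burden(cnt)
    ors <- c(ors, fit$odds_ratio)
  }
  # small-sample Monte-Carlo band around the embedded OR of 2
  expect_gt(mean(ors), 1.4)
  expect_lt(mean(ors), 2.8)
})

test_that("permutation p-values are deterministic, one-sided and match the
           asymptotic p for non-sparse counts", {
  set.seed(65)
  n <- 300
  d <- tibble::tibble(
    phenotype = rep(c(1L, 0L), each = n / 2),
    count = rpois(n, 5)
  )
  f1 <- fit_logistic_burden(d, n_permutations = 400, seed = 17)
  f2 <- fit_logistic_burden(d, n_permutations = 400, seed = 17)
  expect_identical(f1$p_empirical, f2$p_empirical)
  expect_lt(abs(f1$p_empirical - f1$p_one_sided), 0.1)
  # protective direction -> empirical p near 1
  dprot <- tibble::tibble(
    phenotype = rep(c(1L, 0L), each = n / 2),
    count = rpois(n, ifelse(rep(c(1L, 0L), each = n / 2) == 1, 2, 5))
  )
  fp <- fit_logistic_burden(dprot, n_permutations = 200, seed = 3)
  expect_gt(fp$p_empirical, 0.9)
})

test_that("BH adjustment matches a direct sort-based reference and is
           monotone", {
  bh_ref <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    cummin(m / (m:1) * p[o])[ro]
  }
  set.seed(66)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))
    expect_equal(bh_fdr(p), bh_ref(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(0.032), 0.032)  # single test: adjusted = raw
  # families adjusted independently
  d <- tibble::tibble(p = runif(20), family = rep(c("URV", "SV"), each = 10))
  adj <- bh_fdr(d)
  expect_equal(adj$p_adjusted[adj$family == "URV"],
               bh_ref(d$p[d$family == "URV"]))
  # monotone in rank after adjustment
  ord <- order(d$p[d$family == "SV"])
  expect_true(!is.unsorted(adj$p_adjusted[adj$family == "SV"][ord]))
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("single-variant scan matches glm, excludes by MAF, and is null
           calibrated", {
  set.seed(67)
  n <- 500; m <- 60
  p <- runif(m, 0.02, 0.5)
  G <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
  rownames(G) <- sprintf("v%03d", 1:m)
  y <- rbinom(n, 1, 0.5)
  res <- single_variant_assoc(G, y, maf_min = 0.01)
  for (id in sample(res$variant_id, 8)) {
    i <- match(id, rownames(G))
    ref <- glm(y ~ G[i, ], family = binomial(),
               control = stats::glm.control(epsilon = 1e-12))
    sm <- summary(ref)$coefficients
    j <- match(id, res$variant_id)
    expect_equal(unname(res$beta[j]), sm[2, 1], tolerance = 1e-6)
    expect_equal(unname(res$se[j]), sm[2, 2], tolerance = 1e-6)
  }
  # monomorphic and sub-MAF variants excluded
  G2 <- rbind(G, mono = 0L, rare = c(1L, rep(0L, n - 1)))
  res2 <- single_variant_assoc(G2, y)
  expect_false(any(c("mono", "rare") %in% res2$variant_id))
  # covariate path agrees with glm
  cv <- matrix(rnorm(n), ncol = 1)
  resc <- single_variant_assoc(G[1:5, ], y, covariates = cv)
  refc <- glm(y ~ cv + G[1, ], family = binomial())
  expect_equal(resc$beta[1], unname(coef(refc)[3]), tolerance = 1e-6)
  # engineered large frequency gap reaches genome-wide scale significance
  gcase <- rbinom(250, 2, 0.25); gctrl <- rbinom(250, 2, 0.10)
  Gbig <- matrix(c(gcase, gctrl), nrow = 1)
  ybig <- rep(c(1L, 0L), each = 250)
  rbig <- single_variant_assoc(Gbig, ybig)
  expect_lt(rbig$p, 1e-6)
})

test_that("genomic inflation is 1 for uniform p and detects inflation", {
  grid <- seq(1e-6, 1 - 1e-6, length.out = 10001)
  expect_lt(abs(genomic_inflation(grid) - 1), 0.01)
  expect_gt(genomic_inflation(grid / 10), 1)
  expect_error(genomic_inflation(runif(50)), "at least 100")
})

test_that("burden scan aggregates tests with per-family FDR", {
  co <- fixture_cohort()
  tr <- fixture_tracks()
  cnt <- count_per_sample(co, "tad_boundary", tracks = tr)
  names(cnt)[names(cnt) == "count"] <- "tad_boundary"
  cnt$atac <- count_per_sample(co, "atac", tracks = tr)$count
  cnt$total <- count_per_sample(co, "genome_wide")$count
  cnt$mean_coverage <- co$samples$mean_coverage
  res <- burden_scan(cnt, annotations = c("tad_boundary", "atac"),
                     covariates = c("mean_coverage", "total"),
                     family = "URV")
  expect_s3_class(res, "burden_scan")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted >= res$p))
  pl <- ggplot2::autoplot(res)
  expect_s3_class(pl, "ggplot")
})

test_that("tidiers return broom-shaped tibbles", {
  d <- tibble::tibble(phenotype = rep(c(1L, 0L), each = 50),
                      count = rpois(100, 3))
  fit <- fit_logistic_burden(d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "odds.ratio", "conf.low", "conf.high"))
  expect_equal(nrow(glance(fit)), 1)
})
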