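test_that("GRM matches hand arithmetic and identity/null structure", {
  # 3 samples x 2 variants worked by hand
  G <- matrix(c(0, 1, 2,
                1, 1, 0), nrow = 3)
  p <- colMeans(G) / 2            # 0.5, 1/3
  z <- sweep(G, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  by_hand <- tcrossprod(z) / 2
  grm <- compute_grm(G)
  expect_equal(grm$A, by_hand, ignore_attr = TRUE)
  expect_equal(grm$m, 2)
  expect_error(compute_grm(cbind(G, 0)), "monomorphic")
  # duplicated sample: off-diagonal ~ diagonal; independent samples ~ 0
  set.seed(81)
  m <- 4000
  H <- matrix(rbinom(50 * m, 2, rep(runif(m, 0.1, 0.5), each = 50)),
              nrow = 50)
  H <- rbind(H, H[1, ])
  A <- compute_grm(H)$A
  expect_lt(abs(A[51, 1] - (A[1, 1] + A[51, 51]) / 2), 0.1)
  off <- A[2:50, 2:50][upper.tri(A[2:50, 2:50])]
  expect_lt(abs(mean(off)), 2 / sqrt(m))
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
})

test_that("LD scores equal the naive windowed computation", {
  set.seed(82)
  n <- 150
  # block-correlated genotypes: blocks of 5 highly correlated variants
  blocks <- 40
  base <- matrix(rbinom(n * blocks, 2, 0.3), n, blocks)
  G <- do.call(cbind, lapply(seq_len(blocks), function(b) {
    sapply(1:5, function(k) {
      flip <- rbinom(n, 1, 0.05)
      ifelse(flip == 1, rbinom(n, 2, 0.3), base[, b])
    })
  }))
  m <- ncol(G)
  pos <- sort(sample.int(5e5, m))
  ls <- ld_scores(G, pos, window_kb = 50)
  z <- scale(G)
  R2 <- (crossprod(z) / (n - 1))^2
  naive <- sapply(seq_len(m), function(i) {
    sum(R2[i, abs(pos - pos[i]) <= 5e4])
  })
  expect_equal(ls, naive, tolerance = 1e-10)
  expect_true(all(ls >= 1 - 1e-9))   # self r^2 included
  # isolated variant scores exactly 1; perfect pair scores 2
  iso <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  iso[, 2] <- iso[, 1]
  expect_equal(ld_scores(iso, c(100, 200), window_kb = 1), c(2, 2))
  expect_equal(ld_scores(iso[, 1, drop = FALSE], 100, window_kb = 1), 1)
  expect_error(ld_scores(iso, c(200, 100)), "sorted")
})

test_that("MAF x LD bin assignment uses the stated boundaries and tie rule", {
  mafs <- c(0.0007, 0.0008, 0.001, 0.005, 0.05, 0.15, 0.25, 0.35, 0.45, 0.5)
  lds <- rep(1, length(mafs))
  expect_warning(bins <- assign_bins(c(mafs, 0.0001), c(lds, 1)),
                 "MAF floor")
  expect_true(is.na(bins$bin[11]))
  expect_equal(bins$maf_bin[1], 1)    # exactly 0.0007 -> bin 1
  expect_equal(bins$maf_bin[3], 1)    # 0.001 right-closed into bin 1
  expect_equal(bins$maf_bin[4], 2)
  expect_equal(bins$maf_bin[5], 3)    # maf 0.05 -> bin 3
  expect_equal(bins$maf_bin[6:10], c(4L, 5L, 6L, 7L, 7L))
  # identical LD scores: all assigned highLD (score >= median)
  expect_true(all(bins$ld_bin[!is.na(bins$ld_bin)] == "highLD"))
  # bin occupancy follows the bin widths for uniform MAF draws
  set.seed(83)
  mafu <- runif(20000, 0.0007, 0.5)
  ldsu <- runif(20000, 1, 10)
  suppressWarnings(bu <- assign_bins(mafu, ldsu))
  widths <- diff(c(0.0007, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5))
  occ <- as.numeric(table(bu$maf_bin)) / 20000
  expect_equal(occ, widths / sum(widths), tolerance = 0.02)
  # LD split is at the within-bin median
  for (b in unique(bu$maf_bin)) {
    idx <- bu$maf_bin == b
    expect_equal(mean(bu$ld_bin[idx] == "lowLD"), 0.5, tolerance = 0.01)
  }
})

test_that("REML recovers simulated variance components", {
  set.seed(84)
  n <- 500; m <- 1500
  G <- matrix(rbinom(n * m, 2, rep(runif(m, 0.05, 0.5), each = n)), nrow = n)
  grm <- compute_grm(G)
  # null phenotype: h2 within 2 SE of zero
  y0 <- rnorm(n)
  f0 <- reml_fit(y0, grm)
  expect_lt(f0$h2_observed, 2 * f0$h2_observed_se + 0.05)
  # h2 = 0.5 single component
  sim <- simulate_liability_phenotype(G, h2 = 0.5, K = 0.5, seed = 85)
  f1 <- reml_fit(sim$phenotype$liability, grm)
  expect_true(f1$converged)
  expect_lt(abs(f1$h2_observed - 0.5), 2 * f1$h2_observed_se)
  # eigen decomposition reuse gives the identical fit
  eg <- eigen(grm$A, symmetric = TRUE)
  f1b <- reml_fit(sim$phenotype$liability, grm, decomposition = eg)
  expect_equal(f1b$h2_observed, f1$h2_observed, tolerance = 1e-8)
})

test_that("two-component REML partitions variance and is order invariant", {
  set.seed(86)
  n <- 400; m <- 800
  G1 <- matrix(rbinom(n * m, 2, rep(runif(m, 0.05, 0.5), each = n)), nrow = n)
  G2 <- matrix(rbinom(n * m, 2, rep(runif(m, 0.05, 0.5), each = n)), nrow = n)
  std <- function(G) {
    p <- colMeans(G) / 2
    sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  }
  y <- drop(std(G1) %*% rnorm(m, 0, sqrt(0.3 / m)) +
              std(G2) %*% rnorm(m, 0, sqrt(0.1 / m))) +
    rnorm(n, 0, sqrt(0.6))
  ga <- compute_grm(G1); gb <- compute_grm(G2)
  fit <- reml_fit(y, list(a = ga, b = gb))
  td <- tidy(fit)
  expect_lt(abs(td$variance[td$component == "a"] - 0.3),
            2 * td$se[td$component == "a"])
  expect_lt(abs(td$variance[td$component == "b"] - 0.1),
            2 * td$se[td$component == "b"])
  swap <- reml_fit(y, list(b = gb, a = ga))
  expect_equal(sum(tidy(swap)$variance), sum(td$variance), tolerance = 1e-5)
  expect_error(reml_fit(y[1:10], list(a = ga)), "dimensions")
})

test_that("liability transformation matches its closed form and edge cases", {
  expect_equal(observed_to_liability(0, 0.01, 0.5), 0)
  # K = 0.01, P = 0.558: factor ~ 0.56
  fac <- observed_to_liability(1, 0.01, 0.558)
  expect_equal(fac, 0.56, tolerance = 0.01)
  # independent numeric evaluation: z via Richardson-extrapolated numeric
  # derivative of the normal CDF at the threshold
  K <- 0.013; P <- 0.41
  t <- qnorm(1 - K)
  h <- 1e-4
  d1 <- (pnorm(t + h) - pnorm(t - h)) / (2 * h)
  d2 <- (pnorm(t + h / 2) - pnorm(t - h / 2)) / h
  z_num <- (4 * d2 - d1) / 3
  ref <- K^2 * (1 - K)^2 / (z_num^2 * P * (1 - P))
  expect_equal(observed_to_liability(1, K, P), ref, tolerance = 1e-10)
  # K = P reduces to the non-ascertained correction K(1-K)/z^2
  zz <- dnorm(qnorm(1 - 0.1))
  expect_equal(observed_to_liability(1, 0.1, 0.1), 0.1 * 0.9 / zz^2,
               tolerance = 1e-12)
  expect_error(observed_to_liability(0.5, 0, 0.5), "K")
})

test_that("ascertained GREML with liability transform recovers h2 at reduced
           scale", {
  set.seed(87)
  n_pop <- 3000; m <- 1200; K <- 0.2
  G <- matrix(rbinom(n_pop * m, 2, rep(runif(m, 0.1, 0.5), each = n_pop)),
              nrow = n_pop)
  sim <- simulate_liability_phenotype(G, h2 = 0.5, K = K, seed = 88,
                                      n_cases = 300, n_controls = 300)
  sel <- which(sim$phenotype$selected)
  grm <- compute_grm(G[sel, ])
  fit <- reml_fit(sim$phenotype$phenotype[sel], grm, K = K)
  expect_true(is.finite(fit$h2_liability))
  expect_equal(fit$P, 0.5)
  # loose recovery check at this scale: point estimate within 3 SE
  expect_lt(abs(fit$h2_liability - 0.5), 3 * fit$h2_liability_se + 0.1)
})
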