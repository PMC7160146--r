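test_that("reciprocal overlap arithmetic and symmetry", {
  expect_equal(reciprocal_overlap(c(100, 200), c(100, 200)),
               c(frac_a = 1, frac_b = 1))
  expect_equal(reciprocal_overlap(c(100, 200), c(150, 250)),
               c(frac_a = 0.5, frac_b = 0.5))
  ab <- reciprocal_overlap(c(0, 1000), c(400, 500))
  expect_equal(unname(ab), c(0.1, 1.0))
  expect_false(all(ab >= 0.5))  # fails the reciprocal-0.5 predicate
  ba <- reciprocal_overlap(c(400, 500), c(0, 1000))
  expect_equal(unname(ba), rev(unname(ab)))
  expect_equal(
    unname(reciprocal_overlap(list(chrom = "chr1", start = 0, end = 10),
                              list(chrom = "chr2", start = 0, end = 10))),
    c(0, 0))
})

test_that("callset matching equals the naive all-pairs oracle", {
  naive_match <- function(a, b, t) {
    cand <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j] || a$sample_id[i] != b$sample_id[j] ||
          a$svtype[i] != b$svtype[j]) next
      w <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      fa <- w / (a$end[i] - a$start[i])
      fb <- w / (b$end[j] - b$start[j])
      if (fa >= t && fb >= t) {
        cand[[length(cand) + 1]] <- data.frame(
          i = i, j = j, score = min(fa, fb),
          a_start = a$start[i], a_len = a$end[i] - a$start[i])
      }
    }
    if (!length(cand)) return(data.frame(i = integer(), j = integer()))
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, cand$a_start, cand$a_len, cand$i,
                       cand$j), ]
    ua <- logical(nrow(a)); ub <- logical(nrow(b)); sel <- integer(0)
    for (k in seq_len(nrow(cand))) {
      if (!ua[cand$i[k]] && !ub[cand$j[k]]) {
        sel <- c(sel, k); ua[cand$i[k]] <- TRUE; ub[cand$j[k]] <- TRUE
      }
    }
    cand[sel, c("i", "j")]
  }
  rand_set <- function(n, seed) {
    set.seed(seed)
    st <- sample.int(50000, n, replace = TRUE)
    tibble::tibble(
      sv_id = sprintf("x%04d", seq_len(n)), chrom = "chr1",
      start = st, end = st + sample.int(3000, n, replace = TRUE),
      sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
      svtype = sample(c("DEL", "DUP"), n, replace = TRUE)
    )
  }
  a <- rand_set(500, 1)
  b <- rand_set(500, 2)
  got <- match_callsets(a, b, threshold = 0.5)
  oracle <- naive_match(a, b, 0.5)
  expect_equal(nrow(got$pairs), nrow(oracle))
  expect_setequal(paste(got$pairs$id_a, got$pairs$id_b),
                  paste(a$sv_id[oracle$i], b$sv_id[oracle$j]))
  # invariance to input row order
  perm <- sample(nrow(a))
  got2 <- match_callsets(a[perm, ], b, threshold = 0.5)
  expect_setequal(paste(got$pairs$id_a, got$pairs$id_b),
                  paste(got2$pairs$id_a, got2$pairs$id_b))
  # disjoint sets -> all unmatched
  far <- dplyr::mutate(b, start = start + 10^7, end = end + 10^7)
  none <- match_callsets(a, far)
  expect_equal(nrow(none$pairs), 0)
  expect_setequal(none$unmatched_a, a$sv_id)
})

test_that("nested candidates resolve to the single reciprocal pair", {
  a <- tibble::tibble(sv_id = "a1", chrom = "chr1", start = 1000, end = 2000,
                      sample_id = "s1", svtype = "DEL")
  b <- tibble::tibble(sv_id = c("small", "good"), chrom = "chr1",
                      start = c(1400, 950), end = c(1500, 2100),
                      sample_id = "s1", svtype = "DEL")
  got <- match_callsets(a, b, threshold = 0.5)
  expect_equal(got$pairs$id_b, "good")
  expect_equal(got$unmatched_b, "small")
})

test_that("population absence is type-stratified with a strict 30% bound", {
  pop <- tibble::tibble(
    chrom = "chr1", start = c(0, 5000), end = c(300, 5300),
    svtype = c("DEL", "DUP")
  )
  sv <- list(chrom = "chr1", start = 0, end = 1000, svtype = "DEL")
  # population DEL covers exactly 30% of the query -> NOT absent
  expect_false(population_absence(sv, pop))
  # covers 29.9% -> absent
  sv2 <- list(chrom = "chr1", start = 0, end = 1004, svtype = "DEL")
  expect_true(population_absence(sv2, pop))
  # full overlap by a different svtype is ignored
  sv3 <- list(chrom = "chr1", start = 5000, end = 5300, svtype = "DEL")
  expect_true(population_absence(sv3, pop))
  # no overlapping population SV at all
  sv4 <- list(chrom = "chr2", start = 0, end = 100, svtype = "DEL")
  expect_true(population_absence(sv4, pop))
})

test_that("element overlap fraction uses the element as denominator", {
  expect_equal(element_overlap_fraction(c(0, 4000), c(0, 40000)), 0.1)
  expect_equal(element_overlap_fraction(c(0, 100), c(0, 100)), 1)
  expect_equal(element_overlap_fraction(c(0, 100), c(500, 600)), 0)
})

test_that("genotype concordance classes, filters and simulated error rate", {
  set.seed(4)
  a <- matrix(rbinom(100 * 100, 2, 0.3), 100)
  expect_equal(genotype_concordance(a, a)$rate, rep(1, 4))
  # one het <-> hom-alt swap among het sites
  b <- a
  het <- which(b == 1L)[1]
  b[het] <- 2L
  res <- genotype_concordance(a, b)
  n_het <- sum(b == 1L)
  expect_equal(res$rate[res$class == "het"], (n_het - 0) / n_het)
  n_hom <- res$n_compared[res$class == "hom_alt"]
  expect_equal(res$n_matched[res$class == "hom_alt"], n_hom - 1)
  # DP/GQ exclusion is counted separately
  dp <- matrix(30L, 100, 100); dp[1:5] <- 5L
  res2 <- genotype_concordance(a, b, dp_a = dp)
  expect_equal(attr(res2, "excluded"), 5)
  # simulated 0.1% discordance -> overall rate ~ 0.999
  big_a <- matrix(rbinom(300 * 500, 2, 0.3), 300)
  big_b <- big_a
  flip <- runif(length(big_a)) < 0.001
  big_b[flip] <- (big_a[flip] + 1L) %% 3L
  overall <- genotype_concordance(big_a, big_b)
  r <- overall$rate[overall$class == "overall"]
  expect_lt(abs(r - 0.999), 3 * sqrt(0.001 * 0.999 / length(big_a)))
  # empty comparison flagged
  expect_warning(
    empty <- genotype_concordance(matrix(NA_integer_, 2, 2),
                                  matrix(NA_integer_, 2, 2)),
    "no comparable")
  expect_true(all(is.na(empty$rate)))
})

test_that("indexed overlap queries agree with a naive scan", {
  set.seed(10)
  n <- 2000
  q <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample.int(1e5, n, TRUE))
  q$end <- q$start + sample.int(500, n, TRUE)
  s <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample.int(1e5, n, TRUE))
  s$end <- s$start + sample.int(500, n, TRUE)
  got <- ravburden:::interval_overlap_pairs(q, s)
  key_got <- sort(paste(got$query_idx, got$subject_idx))
  naive <- character(0)
  for (ch in c("chr1", "chr2")) {
    qi <- which(q$chrom == ch); si <- which(s$chrom == ch)
    for (i in qi) {
      hit <- si[s$start[si] < q$end[i] & s$end[si] > q$start[i]]
      if (length(hit)) naive <- c(naive, paste(i, hit))
    }
  }
  expect_equal(key_got, sort(naive))
})
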