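# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All simulation entry points route their
# randomness through this so that identical configs give identical output.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Named substreams derived from a single master seed; keeps every stage's
# randomness independent and reproducible. Result stays below 2^31.
derive_seed <- function(seed, stream) {
  offs <- c(
    genome = 11L, snv = 23L, sv = 37L, liability = 53L,
    phenotype = 67L, permutation = 83L, misc = 97L
  )
  if (!stream %in% names(offs)) {
    abort(paste0("unknown RNG substream: ", stream))
  }
  as.integer((as.double(seed) * 1103L + offs[[stream]]) %% 2147483629)
}

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] using the
# probability-mass ordering (same convention as stats::fisher.test), via
# direct hypergeometric enumeration — avoids fisher.test overhead inside
# per-variant loops.
fisher2x2_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  dens <- dhyper(support, m1, m2, k)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

assert_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single proportion in [0, 1]"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(x)
}

# Intersection width of [s1, e1) and [s2, e2); vectorised.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Total number of bases of [start, end) covered by the union of the
# (possibly overlapping) intervals in `track` on the same chromosome.
union_overlap_bases <- function(start, end, track_start, track_end) {
  if (length(track_start) == 0L) {
    return(0)
  }
  s <- pmax(track_start, start)
  e <- pmin(track_end, end)
  keep <- e > s
  if (!any(keep)) {
    return(0)
  }
  s <- s[keep]
  e <- e[keep]
  o <- order(s, e)
  s <- s[o]
  e <- e[o]
  covered <- 0
  cur_s <- s[1L]
  cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]
      cur_e <- e[i]
    }
  }
  covered + (cur_e - cur_s)
}

# IRanges-backed overlap query between two interval tibbles (chrom/start/end,
# 0-based half-open). Returns a tibble of (query_idx, subject_idx).
interval_overlap_pairs <- function(query, subject) {
  stopifnot(all(c("chrom", "start", "end") %in% names(query)),
            all(c("chrom", "start", "end") %in% names(subject)))
  out <- vector("list", 0L)
  chroms <- intersect(unique(query$chrom), unique(subject$chrom))
  for (ch in chroms) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        query_idx = qi[S4Vectors::from(hits)],
        subject_idx = si[S4Vectors::to(hits)]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(query_idx = integer(), subject_idx = integer())
}
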