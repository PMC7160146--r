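# Interval arithmetic: reciprocal overlap, callset matching, population
# absence, element overlap and genotype concordance. All intervals are
# 0-based half-open.

#' Reciprocal overlap of two intervals
#'
#' @param a,b Lists/one-row data frames with `chrom`, `start`, `end`
#'   (0-based half-open), or numeric `c(start, end)` pairs assumed to share a
#'   chromosome.
#' @return Named numeric vector `c(frac_a, frac_b)` where
#'   `frac_a = |a∩b| / |a|`. Intervals on different chromosomes give
#'   `c(0, 0)`. The reciprocal-overlap-at-t predicate is
#'   `frac_a >= t && frac_b >= t`.
#' @export
#' @examples
#' reciprocal_overlap(c(100, 200), c(150, 250))  # 0.5, 0.5
reciprocal_overlap <- function(a, b) {
  ai <- as_interval(a)
  bi <- as_interval(b)
  if (!is.na(ai$chrom) && !is.na(bi$chrom) && ai$chrom != bi$chrom) {
    return(c(frac_a = 0, frac_b = 0))
  }
  w <- overlap_width(ai$start, ai$end, bi$start, bi$end)
  c(frac_a = w / (ai$end - ai$start), frac_b = w / (bi$end - bi$start))
}

as_interval <- function(x) {
  if (is.numeric(x) && length(x) == 2L) {
    x <- list(chrom = NA_character_, start = x[1], end = x[2])
  }
  x <- as.list(x)
  if (is.null(x$chrom)) x$chrom <- NA_character_
  if (x$end <= x$start) abort("interval must satisfy end > start")
  x
}

#' Match two SV callsets by reciprocal overlap
#'
#' One-to-one matching within each (sample, svtype) stratum: candidate pairs
#' must reach the reciprocal-overlap threshold in both directions, and are
#' accepted greedily by descending overlap (the smaller of the two overlap
#' fractions), ties broken by leftmost start of the A-side interval, then by
#' shorter A-side length. Output is invariant to input row order.
#'
#' @param set_a,set_b Tibbles with `chrom`, `start`, `end`, `sample_id`,
#'   `svtype` and optionally an id column (`sv_id`; row index used otherwise).
#' @param threshold Reciprocal-overlap threshold (default 0.5; use 0.7 for
#'   call-merging semantics).
#' @return A list with `pairs` (tibble of matched id pairs and their overlap
#'   fractions) and `unmatched_a` / `unmatched_b` id vectors.
#' @export
match_callsets <- function(set_a, set_b, threshold = 0.5) {
  set_a <- normalize_callset(set_a, "a")
  set_b <- normalize_callset(set_b, "b")
  hits <- interval_overlap_pairs(set_a, set_b)
  if (nrow(hits)) {
    same <- set_a$sample_id[hits$query_idx] == set_b$sample_id[hits$subject_idx] &
      set_a$svtype[hits$query_idx] == set_b$svtype[hits$subject_idx]
    hits <- hits[same, , drop = FALSE]
  }
  pairs <- tibble::tibble(
    id_a = character(), id_b = character(),
    frac_a = numeric(), frac_b = numeric()
  )
  if (nrow(hits)) {
    ia <- hits$query_idx
    ib <- hits$subject_idx
    w <- overlap_width(set_a$start[ia], set_a$end[ia],
                       set_b$start[ib], set_b$end[ib])
    fa <- w / (set_a$end[ia] - set_a$start[ia])
    fb <- w / (set_b$end[ib] - set_b$start[ib])
    ok <- fa >= threshold & fb >= threshold
    cand <- tibble::tibble(
      ia = ia[ok], ib = ib[ok], frac_a = fa[ok], frac_b = fb[ok],
      score = pmin(fa[ok], fb[ok]),
      a_start = set_a$start[ia[ok]],
      a_len = set_a$end[ia[ok]] - set_a$start[ia[ok]]
    ) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$a_start, .data$a_len,
                     .data$ia, .data$ib)
    used_a <- logical(nrow(set_a))
    used_b <- logical(nrow(set_b))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
        sel[k] <- TRUE
        used_a[cand$ia[k]] <- TRUE
        used_b[cand$ib[k]] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    pairs <- tibble::tibble(
      id_a = set_a$.id[cand$ia], id_b = set_b$.id[cand$ib],
      frac_a = cand$frac_a, frac_b = cand$frac_b
    )
  }
  list(
    pairs = pairs,
    unmatched_a = setdiff(set_a$.id, pairs$id_a),
    unmatched_b = setdiff(set_b$.id, pairs$id_b)
  )
}

normalize_callset <- function(x, label) {
  x <- tibble::as_tibble(x)
  need <- c("chrom", "start", "end", "sample_id", "svtype")
  if (!all(need %in% names(x))) {
    abort(paste0("callset ", label, " is missing: ",
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  x$.id <- if ("sv_id" %in% names(x)) as.character(x$sv_id) else
    paste0(label, seq_len(nrow(x)))
  x
}

#' Population-database absence of a structural variant
#'
#' An SV counts as absent from the population databases iff every
#' population SV *of the same type* on the same chromosome covers strictly
#' less than `threshold` of the query SV (overlap fraction uses the query SV
#' length as denominator).
#'
#' @param sv One-row tibble/list with `chrom`, `start`, `end`, `svtype`.
#' @param population_svs Tibble of population SVs with the same columns.
#' @param threshold Overlap fraction at or above which the SV is considered
#'   present (default 0.30).
#' @return `TRUE` if absent.
#' @export
population_absence <- function(sv, population_svs, threshold = 0.30) {
  sv <- as.list(sv)
  pop <- population_svs[population_svs$chrom == sv$chrom &
                          population_svs$svtype == sv$svtype, , drop = FALSE]
  if (nrow(pop) == 0L) return(TRUE)
  w <- overlap_width(sv$start, sv$end, pop$start, pop$end)
  all(w / (sv$end - sv$start) < threshold)
}

#' Fraction of a functional element covered by an SV
#'
#' `|sv intersect element| / |element|` — the element length is the
#' denominator, so the >= 10% burden criterion asks that the SV cover at
#' least 10% of the element. Different chromosomes give 0.
#'
#' @param sv,element Interval specifications as in [reciprocal_overlap()].
#' @return Proportion in [0, 1].
#' @export
element_overlap_fraction <- function(sv, element) {
  s <- as_interval(sv)
  e <- as_interval(element)
  if (!is.na(s$chrom) && !is.na(e$chrom) && s$chrom != e$chrom) return(0)
  overlap_width(s$start, s$end, e$start, e$end) / (e$end - e$start)
}

#' Genotype concordance between two call sets
#'
#' Compares aligned genotype matrices (e.g. WGS vs exome sequencing on the
#' same samples and variants) and reports the overall concordance rate plus
#' per-class rates where the class (hom-ref / het / hom-alt) is defined by
#' the comparison set's genotype. Only genotypes passing the depth/quality
#' filter in the primary set are compared; excluded genotypes are counted
#' separately.
#'
#' @param gt_a,gt_b Integer genotype matrices of identical shape (variants x
#'   samples), dosages 0/1/2, `NA` missing. `gt_b` is the comparison
#'   (truth-side) set defining the genotype classes.
#' @param dp_a,gq_a Optional DP/GQ matrices for the primary set.
#' @param min_dp,min_gq Inclusion filter applied to the primary set.
#' @return A tibble with one row per class (`hom_ref`, `het`, `hom_alt`) and
#'   an `overall` row: matched / compared counts and the concordance rate.
#'   Attribute `excluded` counts genotypes dropped by the DP/GQ filter or
#'   missingness. A zero-denominator comparison is flagged with a warning.
#' @export
genotype_concordance <- function(gt_a, gt_b, dp_a = NULL, gq_a = NULL,
                                 min_dp = 10, min_gq = 20) {
  if (!identical(dim(gt_a), dim(gt_b))) {
    abort("genotype matrices must have identical dimensions")
  }
  pass <- !is.na(gt_a) & !is.na(gt_b)
  if (!is.null(dp_a)) pass <- pass & (dp_a >= min_dp)
  if (!is.null(gq_a)) pass <- pass & (gq_a >= min_gq)
  excluded <- sum(!pass)
  cls <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  rows <- purrr::map_dfr(names(cls), function(nm) {
    in_cls <- pass & (gt_b == cls[[nm]])
    in_cls[is.na(in_cls)] <- FALSE
    n_comp <- sum(in_cls)
    n_match <- sum(gt_a[in_cls] == gt_b[in_cls])
    tibble::tibble(class = nm, n_matched = n_match, n_compared = n_comp,
                   rate = if (n_comp > 0) n_match / n_comp else NA_real_)
  })
  n_comp <- sum(pass)
  overall <- tibble::tibble(
    class = "overall",
    n_matched = sum(gt_a[pass] == gt_b[pass]),
    n_compared = n_comp,
    rate = if (n_comp > 0) sum(gt_a[pass] == gt_b[pass]) / n_comp else NA_real_
  )
  if (n_comp == 0L) warn("no comparable genotypes; all rates are NA")
  out <- dplyr::bind_rows(rows, overall)
  attr(out, "excluded") <- excluded
  out
}
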