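#' Flag ultra-rare variants
#'
#' A sequence variant (SNV/indel) is ultra-rare iff its cohort allele count
#' is exactly 1 and it is absent (allele count 0) from every external
#' population source. A structural variant is ultra-rare iff it occurs once
#' in the cohort and is absent from the population databases (maximum
#' same-type overlap of the SV below 30%).
#'
#' @param x An [rv_cohort()], a variants tibble with `cohort_ac` and
#'   `ext_ac_*` columns, or an [sv_callset()].
#' @param required_sources For sequence variants, external source names that
#'   must be present (column `ext_ac_<source>`); defaults to all `ext_ac_*`
#'   columns found.
#' @param pop_absence_threshold SV population-overlap threshold (default 0.30).
#' @return Logical vector, one element per variant.
#' @export
flag_ultra_rare <- function(x, required_sources = NULL,
                            pop_absence_threshold = 0.30) {
  UseMethod("flag_ultra_rare")
}

#' @export
flag_ultra_rare.rv_cohort <- function(x, required_sources = NULL,
                                      pop_absence_threshold = 0.30) {
  flag_ultra_rare(x$variants, required_sources = required_sources)
}

#' @export
flag_ultra_rare.data.frame <- function(x, required_sources = NULL,
                                       pop_absence_threshold = 0.30) {
  ext_cols <- grep("^ext_ac_", names(x), value = TRUE)
  if (!is.null(required_sources)) {
    want <- paste0("ext_ac_", required_sources)
    missing_src <- setdiff(want, names(x))
    if (length(missing_src)) {
      abort(paste0("missing external allele-count sources: ",
                   paste(missing_src, collapse = ", ")))
    }
    ext_cols <- want
  }
  if (!length(ext_cols)) abort("no `ext_ac_*` columns present")
  ext <- as.matrix(x[, ext_cols, drop = FALSE])
  x$cohort_ac == 1L & rowSums(ext > 0L) == 0L
}

#' @export
flag_ultra_rare.sv_callset <- function(x, required_sources = NULL,
                                       pop_absence_threshold = 0.30) {
  x$svs$cohort_ac == 1L & x$svs$pop_db_max_overlap < pop_absence_threshold
}

#' Coding/noncoding classification of structural variants
#'
#' DEL, DUP and mobile-element insertions are coding iff they affect at
#' least one coding-sequence base. Inversions follow breakpoint logic: an
#' inversion is coding if (a) a breakpoint falls inside a coding exon, (b)
#' both breakpoints fall in different introns of the same gene with at least
#' one coding exon between them, or (c) one breakpoint is in an intron of a
#' gene and the other outside that gene. An inversion that inverts whole
#' gene(s) with both breakpoints intergenic is noncoding, as is one with
#' both breakpoints in the same intron.
#'
#' @param svs Tibble with `chrom`, `start`, `end`, `svtype` (0-based
#'   half-open; breakpoints at `start` and `end`).
#' @param genes,cds Gene-model tibbles as produced by
#'   [simulate_annotation_genome()] (`genes`: `gene_id`, `chrom`,
#'   `tx_start`, `tx_end`; `cds`: `gene_id`, `chrom`, `start`, `end`).
#' @return Logical vector: `TRUE` = coding.
#' @export
classify_sv_coding <- function(svs, genes, cds) {
  bad <- dplyr::inner_join(cds, genes, by = c("gene_id", "chrom")) |>
    dplyr::filter(.data$start < .data$tx_start | .data$end > .data$tx_end)
  if (nrow(bad)) {
    abort(paste0("malformed gene model: CDS outside transcript for ",
                 paste(unique(bad$gene_id), collapse = ", ")))
  }
  svs <- tibble::as_tibble(svs)
  n <- nrow(svs)
  if (n == 0L) return(logical(0))

  # non-INV: any CDS base affected
  cds_iv <- cds[, c("chrom", "start", "end")]
  hit_cds <- rep(FALSE, n)
  non_inv <- which(svs$svtype != "INV")
  if (length(non_inv)) {
    h <- interval_overlap_pairs(svs[non_inv, c("chrom", "start", "end")],
                                cds_iv)
    hit_cds[non_inv[unique(h$query_idx)]] <- TRUE
  }

  inv_idx <- which(svs$svtype == "INV")
  inv_coding <- logical(length(inv_idx))
  if (length(inv_idx)) {
    classify_point <- function(ch, p) {
      # genes containing the breakpoint
      gsel <- genes$chrom == ch & genes$tx_start <= p & p < genes$tx_end
      gids <- genes$gene_id[gsel]
      in_exon <- any(cds$chrom == ch & cds$start <= p & p < cds$end)
      list(genes = gids, in_exon = in_exon)
    }
    intron_id <- function(ch, p, gid) {
      # index of the intron of gene `gid` containing point p (NA if exonic
      # or outside); introns ordered by position
      ex <- cds[cds$gene_id == gid & cds$chrom == ch, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (any(ex$start <= p & p < ex$end)) return(NA_integer_)
      sum(ex$end <= p)  # 0 = before first exon, k = after exon k
    }
    for (j in seq_along(inv_idx)) {
      i <- inv_idx[j]
      b1 <- classify_point(svs$chrom[i], svs$start[i])
      b2 <- classify_point(svs$chrom[i], svs$end[i])
      if (b1$in_exon || b2$in_exon) {
        inv_coding[j] <- TRUE
        next
      }
      shared <- intersect(b1$genes, b2$genes)
      if (length(shared)) {
        # both breakpoints inside the same gene, neither exonic: coding iff
        # they sit in different introns with >= 1 coding exon between them
        for (gid in shared) {
          i1 <- intron_id(svs$chrom[i], svs$start[i], gid)
          i2 <- intron_id(svs$chrom[i], svs$end[i], gid)
          if (!is.na(i1) && !is.na(i2) && i1 != i2) {
            inv_coding[j] <- TRUE
            break
          }
        }
      } else if (length(b1$genes) || length(b2$genes)) {
        # one breakpoint intronic in a gene the other breakpoint is outside
        inv_coding[j] <- TRUE
      }
      # both breakpoints intergenic: noncoding even if genes are spanned
    }
  }
  out <- hit_cds
  out[inv_idx] <- inv_coding
  out
}

#' Sequence-constraint mask (CDTS / GERP)
#'
#' A site or interval is constrained iff the mean CDTS percentile over the
#' spanned 10-bp bins is below `cdts_max` (default 1%) OR the GERP score
#' over the span reaches `gerp_min` (default 4, boundary inclusive). For
#' multi-base spans GERP is aggregated with `gerp_agg` (maximum by default,
#' conservative toward inclusion; `"mean"` available).
#'
#' @param x Tibble of variants (`chrom`, `pos` 1-based, optionally `ref` for
#'   span length) or intervals (`chrom`, `start`, `end`, 0-based half-open).
#' @param tracks An `annotation_tracks` object (uses `cdts` and `gerp`).
#' @param cdts_max,gerp_min Thresholds.
#' @param gerp_agg `"max"` or `"mean"`.
#' @return Logical vector.
#' @export
constrained_mask <- function(x, tracks, cdts_max = 1, gerp_min = 4,
                             gerp_agg = c("max", "mean")) {
  gerp_agg <- match.arg(gerp_agg)
  x <- tibble::as_tibble(x)
  if (!"start" %in% names(x)) {
    if (!"pos" %in% names(x)) abort("supply `pos` or `start`/`end`")
    width <- if ("ref" %in% names(x)) nchar(x$ref) else 1L
    x$start <- x$pos - 1
    x$end <- x$start + width
  }
  lens <- setNames(tracks$chromosomes$length, tracks$chromosomes$chrom)
  if (any(!x$chrom %in% names(lens)) ||
      any(x$start < 0 | x$end > lens[x$chrom])) {
    abort("position outside constraint-track coverage")
  }
  # CDTS bins are a regular 10-bp partition: direct index arithmetic
  ord <- order(tracks$cdts$chrom, tracks$cdts$start)
  cdts_by_chrom <- split(tracks$cdts$percentile[ord], tracks$cdts$chrom[ord])
  cdts_mean <- vapply(seq_len(nrow(x)), function(i) {
    v <- cdts_by_chrom[[x$chrom[i]]]
    b <- (floor(x$start[i] / 10):floor((x$end[i] - 1) / 10)) + 1L
    mean(v[b])
  }, 0)

  hits <- interval_overlap_pairs(x[, c("chrom", "start", "end")],
                                 tracks$gerp)
  agg_fun <- if (gerp_agg == "max") max else mean
  gerp_val <- rep(-Inf, nrow(x))
  if (nrow(hits)) {
    agg <- tapply(tracks$gerp$score[hits$subject_idx], hits$query_idx,
                  agg_fun)
    gerp_val[as.integer(names(agg))] <- agg
  }
  cdts_mean < cdts_max | gerp_val >= gerp_min
}

#' Promoter intervals (2 kb upstream of each TSS)
#'
#' One strand-aware 2-kb interval upstream of each annotated transcription
#' start site, clipped at chromosome edges.
#'
#' @param genes Gene-model tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @param width Promoter width in bases (default 2000).
#' @param chrom_lengths Optional named vector for right-edge clipping.
#' @return Interval tibble (`gene_id`, `chrom`, `start`, `end`), 0-based
#'   half-open.
#' @export
promoter_intervals <- function(genes, width = 2000, chrom_lengths = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - width, genes$tss)
  end <- ifelse(plus, genes$tss, genes$tss + width)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[genes$chrom])
  tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = as.numeric(start), end = as.numeric(end)) |>
    dplyr::filter(.data$end > .data$start)
}

#' Extended gene-region intervals
#'
#' One interval per gene spanning from `upstream` bases upstream of the most
#' distal transcription start site to `downstream` bases downstream of the
#' most distal transcription end site (strand-aware; this is the only
#' geometry that yields an interval containing the gene). Defaults 35 kb /
#' 10 kb.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`).
#' @param upstream,downstream Flank widths in bases.
#' @param chrom_lengths Optional named vector for clipping.
#' @return Interval tibble, 0-based half-open.
#' @export
gene_region_intervals <- function(genes, upstream = 35000,
                                  downstream = 10000,
                                  chrom_lengths = NULL) {
  if (nrow(genes) == 0L) abort("empty gene model")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tx_start - upstream,
                  genes$tx_start - downstream)
  end <- ifelse(plus, genes$tx_end + downstream, genes$tx_end + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[genes$chrom])
  tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = as.numeric(start), end = as.numeric(end))
}

#' Per-sample qualifying-variant counts in an annotation
#'
#' Counts, for every sample, the carried variants that qualify for a burden
#' test: sequence variants count when their position lies inside the
#' annotation; structural variants count when they cover at least
#' `min_element_overlap` (default 10%) of at least one annotation element.
#' By default only ultra-rare variants are counted.
#'
#' @param x An [rv_cohort()] or [sv_callset()].
#' @param annotation Annotation name looked up in `tracks$annotations`, or an
#'   interval tibble (`chrom`, `start`, `end`). Use `"genome_wide"` for no
#'   positional restriction.
#' @param tracks Required when `annotation` (or `constrained`) is a name.
#' @param urv_only Count ultra-rare variants only (default `TRUE`).
#' @param consequence Optional consequence-class filter for sequence
#'   variants (e.g. `"LOF"`).
#' @param constrained Restrict sequence variants to constrained sites
#'   (CDTS/GERP via [constrained_mask()]).
#' @param min_element_overlap SV qualification threshold on the element
#'   overlap fraction.
#' @return Tibble (`sample_id`, `phenotype`, `count`).
#' @export
count_per_sample <- function(x, annotation, tracks = NULL, urv_only = TRUE,
                             consequence = NULL, constrained = FALSE,
                             min_element_overlap = 0.10) {
  ann <- resolve_annotation(annotation, tracks)
  if (inherits(x, "rv_cohort")) {
    sel <- rep(TRUE, nrow(x$variants))
    if (urv_only) sel <- sel & flag_ultra_rare(x)
    if (!is.null(consequence)) {
      sel <- sel & x$variants$consequence_class %in% consequence
    }
    if (constrained) {
      if (is.null(tracks)) abort("`tracks` needed for the constrained mask")
      sel <- sel & constrained_mask(x$variants, tracks)
    }
    if (!is.null(ann)) {
      vpos <- tibble::tibble(chrom = x$variants$chrom,
                             start = x$variants$pos - 1,
                             end = x$variants$pos - 1 + 1)
      inside <- rep(FALSE, nrow(vpos))
      inside[unique(interval_overlap_pairs(vpos, ann)$query_idx)] <- TRUE
      sel <- sel & inside
    }
    counts <- colSums(x$geno[sel, , drop = FALSE] > 0L, na.rm = TRUE)
  } else if (inherits(x, "sv_callset")) {
    sel <- rep(TRUE, nrow(x$svs))
    if (urv_only) sel <- sel & flag_ultra_rare(x)
    if (!is.null(ann)) {
      qual <- rep(FALSE, nrow(x$svs))
      h <- interval_overlap_pairs(x$svs[, c("chrom", "start", "end")], ann)
      if (nrow(h)) {
        w <- overlap_width(x$svs$start[h$query_idx], x$svs$end[h$query_idx],
                           ann$start[h$subject_idx], ann$end[h$subject_idx])
        f <- w / (ann$end[h$subject_idx] - ann$start[h$subject_idx])
        qual[unique(h$query_idx[f >= min_element_overlap])] <- TRUE
      }
      sel <- sel & qual
    }
    counts <- colSums(x$geno[sel, , drop = FALSE] > 0L, na.rm = TRUE)
  } else {
    abort("`x` must be an rv_cohort or sv_callset")
  }
  tibble::tibble(
    sample_id = x$samples$sample_id,
    phenotype = x$samples$phenotype,
    count = as.numeric(counts)
  )
}

resolve_annotation <- function(annotation, tracks) {
  if (is.character(annotation) && length(annotation) == 1L) {
    if (annotation == "genome_wide") return(NULL)
    if (is.null(tracks)) abort("`tracks` needed to look up annotation name")
    if (!annotation %in% names(tracks$annotations)) {
      abort(paste0("unknown annotation: ", annotation))
    }
    tracks$annotations[[annotation]]
  } else {
    tibble::as_tibble(annotation)
  }
}
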