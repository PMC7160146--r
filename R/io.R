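# File-format boundaries. VCF input/output goes through vcfR; interval
# tracks are exchanged as BED (0-based half-open; conversion from the
# 1-based VCF convention happens only here); SV call sets as BEDPE-style
# TSV.

#' Write a cohort to VCF
#'
#' Writes SNV/indel genotypes with per-genotype `GT:DP:GQ`. The file is
#' bgzip-compressed when the path ends in `.gz` (vcfR convention: output is
#' always gzip-written, name the file accordingly).
#'
#' @param cohort An [rv_cohort()].
#' @param path Output path (use a `.vcf.gz` extension).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  m <- nrow(v)
  n <- nrow(cohort$samples)
  fix <- cbind(
    CHROM = v$chrom, POS = as.character(as.integer(v$pos)),
    ID = v$variant_id, REF = v$ref, ALT = v$alt,
    QUAL = rep(".", m), FILTER = rep("PASS", m),
    INFO = paste0("AC=", v$cohort_ac)
  )
  gt_chr <- matrix(".", m, n)
  g <- cohort$geno
  gt_chr[] <- ifelse(is.na(g), "./.",
                     ifelse(g == 0L, "0/0", ifelse(g == 1L, "0/1", "1/1")))
  dp <- cohort$dp %||% matrix(".", m, n)
  gq <- cohort$gq %||% matrix(".", m, n)
  body <- matrix(paste(gt_chr, dp, gq, sep = ":"), m, n)
  colnames(body) <- cohort$samples$sample_id
  gt <- cbind(FORMAT = rep("GT:DP:GQ", m), body)
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
    meta = c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"),
    fix = fix, gt = gt
  )
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read a cohort from VCF
#'
#' Reads genotypes (`GT`), depth (`DP`) and quality (`GQ`) from a VCF
#' written by [write_cohort_vcf()] or any VCF with those FORMAT fields, and
#' rebuilds an [rv_cohort()]. Sample metadata (phenotype, covariates) is
#' supplied separately since VCF does not carry it.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param samples Tibble with `sample_id`, `phenotype` and covariates; rows
#'   are matched to the VCF sample columns by `sample_id`.
#' @param variant_meta Optional tibble keyed by `variant_id` with extra
#'   variant columns (`variant_class`, `consequence_class`, `ext_ac_*`);
#'   defaults are filled in when absent.
#' @return An [rv_cohort()].
#' @export
read_cohort_vcf <- function(path, samples, variant_meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dose <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  dose[gt_raw %in% c("0/0", "0|0")] <- 0L
  dose[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt_raw %in% c("1/1", "1|1")] <- 2L
  samples <- tibble::as_tibble(samples)
  ord <- match(colnames(gt_raw), samples$sample_id)
  if (any(is.na(ord))) abort("VCF contains samples absent from `samples`")
  samples <- samples[ord, , drop = FALSE]
  variants <- tibble::tibble(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                        fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    variant_class = ifelse(nchar(fix[, "REF"]) == 1 &
                             nchar(fix[, "ALT"]) == 1, "SNV", "indel"),
    cohort_ac = 0L,
    consequence_class = "noncoding",
    ext_ac_gnomad = 0L
  )
  if (!is.null(variant_meta)) {
    variant_meta <- tibble::as_tibble(variant_meta)
    keep <- setdiff(names(variant_meta), "variant_id")
    variants <- variants[, setdiff(names(variants), keep), drop = FALSE]
    variants <- dplyr::left_join(variants, variant_meta, by = "variant_id")
  }
  mode(dp) <- "integer"
  mode(gq) <- "integer"
  rv_cohort(variants, samples, dose, dp = dp, gq = gq)
}

#' Write an interval track as BED
#'
#' Plain three-column (plus optional `name`) BED: 0-based half-open, the
#' package's internal interval convention.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (and optionally a
#'   name column given by `name`).
#' @param path Output path.
#' @param name Optional column written as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name = NULL) {
  out <- intervals[, c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if (!is.null(name)) out$name <- intervals[[name]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED interval track
#'
#' @param path BED path (first three columns chrom/start/end; a fourth
#'   column, if present, is kept as `name`).
#' @return Interval tibble, 0-based half-open.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  out <- tibble::tibble(chrom = as.character(x[[1]]),
                        start = as.numeric(x[[2]]),
                        end = as.numeric(x[[3]]))
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  out
}

#' Write / read a structural-variant call set as TSV
#'
#' BEDPE-style flat table: one row per SV and sample with a non-reference
#' genotype, columns `chrom`, `start`, `end`, `sv_id`, `svtype`,
#' `pop_db_max_overlap`, `sample_id`, `gt`.
#'
#' @param svset An [sv_callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_tsv <- function(svset, path) {
  idx <- which(svset$geno > 0L, arr.ind = TRUE)
  out <- tibble::tibble(
    chrom = svset$svs$chrom[idx[, 1]],
    start = svset$svs$start[idx[, 1]],
    end = svset$svs$end[idx[, 1]],
    sv_id = svset$svs$sv_id[idx[, 1]],
    svtype = svset$svs$svtype[idx[, 1]],
    pop_db_max_overlap = svset$svs$pop_db_max_overlap[idx[, 1]],
    sample_id = svset$samples$sample_id[idx[, 2]],
    gt = svset$geno[idx]
  ) |> dplyr::arrange(.data$chrom, .data$start, .data$sv_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @param samples Sample tibble (`sample_id`, `phenotype`, covariates) for
#'   rebuilding the call set, including non-carrier samples.
#' @return For `read_sv_tsv`, an [sv_callset()].
#' @export
read_sv_tsv <- function(path, samples) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- tibble::as_tibble(samples)
  svs <- x |>
    dplyr::distinct(.data$sv_id, .data$chrom, .data$start, .data$end,
                    .data$svtype, .data$pop_db_max_overlap) |>
    dplyr::mutate(cohort_ac = 0L)
  geno <- matrix(0L, nrow(svs), nrow(samples))
  ri <- match(x$sv_id, svs$sv_id)
  ci <- match(x$sample_id, samples$sample_id)
  if (any(is.na(ci))) abort("SV TSV contains samples absent from `samples`")
  geno[cbind(ri, ci)] <- as.integer(x$gt)
  sv_callset(svs, samples, geno)
}
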