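#' Simulate an annotated toy genome
#'
#' Generates the annotation scaffold the burden analysis consumes: contiguous
#' 40-kb candidate TAD bins with a configured subset flagged as boundaries,
#' interval tracks for open chromatin (ATAC) and epigenetic marks, a CDTS
#' constraint track of contiguous 10-bp bins with percentile values uniform on
#' (0, 100], a per-base GERP track encoded as run-length segments, gene models
#' (transcript extent, strand, TSS, coding exons, pLI and gene-set flags) and
#' a blacklist track. Identical configs (including seed) give identical
#' tracks.
#'
#' @param config A [sim_config()].
#' @return An object of class `annotation_tracks`: a list of tibbles
#'   (`chromosomes`, `tad_bins`, `cdts`, `gerp`, `genes`, `cds`, `blacklist`)
#'   plus `annotations`, a named list of interval tibbles usable as burden
#'   targets (includes `tad_boundary`, `atac`, `ctcf`, `h3k27ac`).
#' @export
#' @examples
#' tr <- simulate_annotation_genome(sim_config(chrom_length = 2e6))
#' names(tr$annotations)
simulate_annotation_genome <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- tibble::tibble(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      length = config$chrom_length
    )

    # candidate TAD bins tile each chromosome exactly
    n_bins <- as.integer(config$chrom_length / config$tad_bin_width)
    tad_bins <- tidyr::crossing(chrom = chroms$chrom,
                                bin = seq_len(n_bins) - 1L) |>
      dplyr::mutate(
        start = .data$bin * config$tad_bin_width,
        end = .data$start + config$tad_bin_width
      ) |>
      dplyr::select("chrom", "start", "end")
    n_boundary <- round(nrow(tad_bins) * config$tad_boundary_fraction)
    is_b <- rep(FALSE, nrow(tad_bins))
    is_b[sample.int(nrow(tad_bins), n_boundary)] <- TRUE
    tad_bins$is_boundary <- is_b

    # CDTS: contiguous 10-bp bins, percentile uniform on (0, 100]
    n_cdts <- as.integer(ceiling(config$chrom_length / 10))
    cdts <- tidyr::crossing(chrom = chroms$chrom,
                            bin = seq_len(n_cdts) - 1L) |>
      dplyr::mutate(
        start = .data$bin * 10,
        end = pmin(.data$start + 10, config$chrom_length),
        percentile = 100 * runif(dplyr::n(), min = .Machine$double.eps)
      ) |>
      dplyr::select("chrom", "start", "end", "percentile")

    # GERP: piecewise-constant per-base score; mostly neutral background with
    # scattered conserved elements
    gerp <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_seg <- max(10L, as.integer(config$chrom_length / 5000))
      cuts <- sort(sample.int(config$chrom_length - 1L, n_seg - 1L))
      starts <- c(0, cuts)
      ends <- c(cuts, config$chrom_length)
      conserved <- runif(n_seg) < 0.05
      score <- ifelse(conserved, runif(n_seg, 4, 6), rnorm(n_seg, 0, 1.5))
      tibble::tibble(chrom = ch, start = starts, end = ends, score = score)
    })

    # gene models: non-overlapping transcripts with 2-8 coding exons
    genes <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_genes <- max(2L, as.integer(config$chrom_length / 250000))
      slot <- config$chrom_length / n_genes
      width <- pmin(round(runif(n_genes, 5000, 0.6 * slot)), slot - 2000)
      tx_start <- round((seq_len(n_genes) - 1) * slot +
                          runif(n_genes, 0, slot - width - 1))
      tibble::tibble(
        chrom = ch,
        tx_start = tx_start,
        tx_end = tx_start + width,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        pli = stats::rbeta(n_genes, 0.4, 0.4)
      )
    })
    genes <- genes |>
      dplyr::mutate(
        gene_id = sprintf("G%04d", dplyr::row_number()),
        tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end),
        lof_intolerant = .data$pli > 0.9,
        ndd_risk = .data$lof_intolerant & runif(dplyr::n()) < 0.2
      ) |>
      dplyr::select("gene_id", "chrom", "strand", "tx_start", "tx_end",
                    "tss", "pli", "lof_intolerant", "ndd_risk")

    cds <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      n_ex <- sample(2:8, 1L)
      w <- g$tx_end - g$tx_start
      # exon starts spread through the transcript; short coding exons
      ex_start <- g$tx_start + sort(sample.int(max(w - 200L, n_ex), n_ex))
      ex_len <- pmin(round(runif(n_ex, 80, 200)),
                     diff(c(ex_start, g$tx_end)))
      keep <- ex_len > 0
      tibble::tibble(
        gene_id = g$gene_id, chrom = g$chrom,
        start = ex_start[keep], end = (ex_start + ex_len)[keep],
        exon_rank = seq_len(sum(keep))
      )
    })

    # blacklist: a few percent of each chromosome in large blocks
    blacklist <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_bl <- max(1L, as.integer(config$chrom_length / 2e6))
      s <- sort(sample.int(config$chrom_length - 60000L, n_bl))
      tibble::tibble(chrom = ch, start = s,
                     end = pmin(s + round(runif(n_bl, 20000, 50000)),
                                config$chrom_length))
    })

    intervals_track <- function(n_per_mb, min_w, max_w) {
      purrr::map_dfr(chroms$chrom, function(ch) {
        n_iv <- max(1L, round(config$chrom_length / 1e6 * n_per_mb))
        s <- sort(sample.int(as.integer(config$chrom_length - max_w), n_iv))
        tibble::tibble(chrom = ch, start = s,
                       end = s + round(runif(n_iv, min_w, max_w)))
      })
    }

    annotations <- list(
      tad_boundary = tad_bins |>
        dplyr::filter(.data$is_boundary) |>
        dplyr::select("chrom", "start", "end"),
      atac = intervals_track(40, 200, 2000),
      ctcf = intervals_track(25, 150, 1000),
      h3k27ac = intervals_track(25, 500, 3000)
    )

    structure(
      list(chromosomes = chroms, tad_bins = tad_bins, cdts = cdts,
           gerp = gerp, genes = genes, cds = cds, blacklist = blacklist,
           annotations = annotations),
      class = "annotation_tracks"
    )
  })
}

#' @export
print.annotation_tracks <- function(x, ...) {
  cat("<annotation_tracks> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$genes), " genes, ", sum(x$tad_bins$is_boundary),
      " TAD boundaries, annotations: ",
      paste(names(x$annotations), collapse = ", "), "\n", sep = "")
  invisible(x)
}
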