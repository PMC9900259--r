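# Per-cluster coverage profiles over a region. "Linear" coverage counts
# properly paired reads; "circular" coverage counts circle-supporting reads
# (outward-facing discordant mates, plus split primaries when requested).
# Each qualifying read is counted once, in the bin holding its leftmost
# base inside the region, so bin sums conserve the read count.

region_bins <- function(region, bins) {
  span <- region$end - region$start
  nb <- min(bins, span)
  edges <- region$start + round(seq(0, span, length.out = nb + 1))
  tibble(bin = seq_len(nb), bin_start = head(edges, -1),
         bin_end = tail(edges, -1))
}

load_region_records <- function(bam, region, min_mapq) {
  which <- GenomicRanges::GRanges(
    region$chrom, IRanges::IRanges(region$start + 1, region$end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos"),
    tag = c("CB", "SA"),
    which = which,
    mapqFilter = min_mapq,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  tibble(
    read_id = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    start = res$pos - 1,
    end = res$pos - 1 + cigar_ref_width(res$cigar),
    mapq = res$mapq,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0, "-", "+"),
    mate_strand = ifelse(bitwAnd(res$flag, 32L) > 0, "-", "+"),
    proper = bitwAnd(res$flag, 2L) > 0,
    mate_chrom = as.character(res$mrnm),
    mate_pos = res$mpos - 1,
    barcode = as.character(res$tag$CB %||% rep(NA, n)),
    sa = as.character(res$tag$SA %||% rep(NA, n))
  )
}

profile_from_records <- function(rec, region, cells, bins, mode) {
  bin_tbl <- region_bins(region, bins)
  clusters <- unique(as.character(cells$cluster_id))
  rec <- filter(rec, !is.na(.data$barcode),
                .data$barcode %in% cells$barcode,
                .data$end > region$start, .data$start < region$end)
  rec$cluster_id <- as.character(
    cells$cluster_id[match(rec$barcode, cells$barcode)])
  nb <- nrow(bin_tbl)
  binwidth <- (region$end - region$start) / nb
  rec$bin <- pmin(nb, 1L + floor((pmax(rec$start, region$start) -
                                    region$start) / binwidth))
  counts <- rec |>
    count(.data$bin, .data$cluster_id, name = "count") |>
    tidyr::complete(bin = seq_len(nb), cluster_id = clusters,
                    fill = list(count = 0L))
  left_join(counts, bin_tbl, by = "bin") |>
    mutate(mode = mode) |>
    select("bin", "bin_start", "bin_end", "cluster_id", "count", "mode") |>
    arrange(.data$cluster_id, .data$bin)
}

#' Linear coverage profile of a region, per cell cluster
#'
#' Counts properly paired, non-duplicate, mapq-passing reads per bin,
#' aggregated by the cluster of the read's cell barcode. Reads whose
#' barcode is absent from the cell table are excluded.
#'
#' @param bam Indexed BAM path.
#' @param region One-row tibble or list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param cells Cell table with `barcode` and `cluster_id`.
#' @param bins Number of bins (default 200; capped at the region span).
#' @param min_mapq Mapping-quality floor (default 10).
#' @return Tibble: `bin`, `bin_start`, `bin_end`, `cluster_id`, `count`,
#'   `mode = "linear"`.
#' @export
linear_profile <- function(bam, region, cells, bins = 200, min_mapq = 10) {
  if (region$start < 0 || region$start >= region$end) {
    abort("invalid region")
  }
  rec <- load_region_records(bam, region, min_mapq)
  rec <- filter(rec, .data$proper)
  profile_from_records(rec, region, cells, bins, "linear")
}

#' Circular coverage profile of a region, per cell cluster
#'
#' Counts circle-supporting reads per bin and cluster: mates of
#' outward-facing (RF) discordant pairs, plus primaries of split (SA-tagged)
#' alignments when `include_split` is on.
#'
#' @inheritParams linear_profile
#' @param include_split Also count split-read primaries (default `FALSE`:
#'   discordantly mapped reads only).
#' @return Tibble as in [linear_profile()] with `mode = "circular"`.
#' @export
circular_profile <- function(bam, region, cells, bins = 200, min_mapq = 10,
                             include_split = FALSE) {
  rec <- load_region_records(bam, region, min_mapq)
  has_sa <- !is.na(rec$sa) & rec$sa != ""
  # outward orientation judged from this record and its mate fields
  same_chrom <- !is.na(rec$mate_chrom) & rec$mate_chrom == rec$chrom
  leftmost <- rec$start <= rec$mate_pos
  outward <- !rec$proper & same_chrom & rec$strand != rec$mate_strand &
    ((leftmost & rec$strand == "-") | (!leftmost & rec$strand == "+")) &
    !has_sa
  keep <- outward | (include_split & has_sa)
  profile_from_records(rec[keep, ], region, cells, bins, "circular")
}

#' Per-cell circular signal for one call, with group keys
#'
#' Slices one eccDNA call's row out of the count matrix and attaches the
#' grouping keys used by the group comparisons.
#'
#' @param mat An `ecc_matrix` from [build_matrix()].
#' @param call_id Row (call) identifier.
#' @param normalize Divide each cell's value by its total count over all
#'   calls (cells with zero totals stay zero). Default `FALSE` (raw
#'   circle-supporting read counts).
#' @return Tibble: `barcode`, `value`, plus any of `cluster_id`,
#'   `condition`, `malignancy`, `sample_id` present in the cell table.
#' @export
per_cell_signal <- function(mat, call_id, normalize = FALSE) {
  stopifnot(inherits(mat, "ecc_matrix"))
  if (!call_id %in% rownames(mat$counts)) {
    abort(sprintf("unknown call_id: %s", call_id))
  }
  value <- as.numeric(mat$counts[call_id, ])
  if (normalize) {
    tot <- unname(Matrix::colSums(mat$counts))
    value <- ifelse(tot > 0, value / tot, 0)
  }
  out <- tibble(barcode = colnames(mat$counts), value = value)
  keys <- intersect(c("cluster_id", "condition", "malignancy", "sample_id"),
                    names(mat$col_meta))
  left_join(out, select(mat$col_meta, "barcode", dplyr::all_of(keys)),
            by = "barcode")
}
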