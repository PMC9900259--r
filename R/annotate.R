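FEATURE_LEVELS <- c("promoter", "first_exon", "other_exon", "first_intron",
                    "other_intron", "downstream", "distal_intergenic")
CRE_CLASSES <- c("prom", "enhP", "enhD", "K4m3", "CTCF")

#' Load gene models from a GTF/GFF file
#'
#' Assembles transcripts from exon features. Introns are derived as the
#' gaps between consecutive exons in transcription order; the first exon
#' and first intron are defined strand-aware (5' to 3').
#'
#' @param path GTF or GFF file with exon features carrying `transcript_id`
#'   (and optionally `gene_id`) attributes.
#' @return A list of class `gene_models` with `transcripts` (tibble:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`;
#'   0-based half-open, `tss` a 0-based position) and `exons` (tibble with
#'   `rank_tx`, the 1-based exon rank in transcription order).
#' @export
load_gene_models <- function(path) {
  empty_models <- structure(list(
    transcripts = tibble(transcript_id = character(), gene_id = character(),
                         chrom = character(), strand = character(),
                         start = numeric(), end = numeric(), tss = numeric()),
    exons = tibble(transcript_id = character(), chrom = character(),
                   strand = character(), start = numeric(), end = numeric(),
                   rank_tx = integer())
  ), class = "gene_models")
  content <- readLines(path, warn = FALSE)
  if (!any(nzchar(content) & !startsWith(content, "#"))) {
    return(empty_models)
  }
  gr <- rtracklayer::import(path)
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    return(empty_models)
  }
  tx_id <- ex$transcript_id
  if (is.null(tx_id) || anyNA(tx_id)) {
    abort("exon feature without a transcript_id attribute")
  }
  gene_id <- ex$gene_id %||% tx_id
  exons <- tibble(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex) - 1,
    end = BiocGenerics::end(ex)
  ) |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank_tx = if (dplyr::first(.data$strand) == "-") {
      rev(seq_len(n()))
    } else {
      seq_len(n())
    }) |>
    ungroup()
  transcripts <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = dplyr::first(.data$gene_id),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      start = min(.data$start),
      end = max(.data$end)
    ) |>
    mutate(tss = ifelse(.data$strand == "-", .data$end - 1, .data$start))
  structure(list(transcripts = transcripts,
                 exons = select(exons, -"gene_id")),
            class = "gene_models")
}

# per-category genomic footprints as GRanges (0-based half-open tibbles in,
# 1-based GRanges out)
category_footprints <- function(models, promoter_up, promoter_down,
                                downstream_bp) {
  tx <- models$transcripts
  ex <- models$exons
  minus <- tx$strand == "-"
  prom <- tibble(
    chrom = tx$chrom,
    start = pmax(0, ifelse(minus, tx$tss + 1 - promoter_down,
                           tx$tss - promoter_up)),
    end = ifelse(minus, tx$tss + 1 + promoter_up, tx$tss + promoter_down)
  )
  down <- tibble(
    chrom = tx$chrom,
    start = pmax(0, ifelse(minus, tx$start - downstream_bp, tx$end)),
    end = ifelse(minus, tx$start, tx$end + downstream_bp)
  )
  # introns: gaps between genomically consecutive exons; the intron's rank
  # in transcription order is the genomic gap index on +, reversed on -
  introns <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(next_start = dplyr::lead(.data$start), gap_idx = row_number(),
           n_gaps = n() - 1L) |>
    ungroup() |>
    filter(!is.na(.data$next_start), .data$next_start > .data$end) |>
    mutate(intron_rank = ifelse(.data$strand == "-",
                                .data$n_gaps - .data$gap_idx + 1L,
                                .data$gap_idx)) |>
    select("chrom", start = "end", end = "next_start", "intron_rank")
  first_intron <- filter(introns, .data$intron_rank == 1)
  other_intron <- filter(introns, .data$intron_rank > 1)
  first_exon <- filter(ex, .data$rank_tx == 1)
  other_exon <- filter(ex, .data$rank_tx > 1)
  to_gr <- function(x) {
    if (nrow(x) == 0) return(GenomicRanges::GRanges())
    as_granges0(x)
  }
  list(
    promoter = to_gr(prom),
    first_exon = to_gr(first_exon),
    other_exon = to_gr(other_exon),
    first_intron = to_gr(first_intron),
    other_intron = to_gr(other_intron),
    downstream = to_gr(down)
  )
}

#' Assign genomic feature categories to intervals
#'
#' Priority-overlap annotation: each interval receives the highest-priority
#' category it overlaps by at least one base, in the order promoter >
#' first exon > other exon > first intron > other intron > downstream >
#' distal intergenic. The promoter footprint is the strand-aware window
#' `[TSS - promoter_up, TSS + promoter_down)`.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param models A [load_gene_models()] object.
#' @param promoter_up,promoter_down Promoter window around the TSS (bp).
#' @param downstream_bp Extent of the downstream category past the gene
#'   end (bp).
#' @return A character vector of categories, one per interval row.
#' @export
annotate_interval <- function(intervals, models, promoter_up = 2000,
                              promoter_down = 200, downstream_bp = 3000) {
  check_interval_tbl(intervals, "intervals")
  fp <- category_footprints(models, promoter_up, promoter_down, downstream_bp)
  q <- as_granges0(intervals)
  out <- rep("distal_intergenic", nrow(intervals))
  assigned <- rep(FALSE, nrow(intervals))
  for (cat in names(fp)) {
    if (length(fp[[cat]]) == 0) next
    hit <- GenomicRanges::countOverlaps(q, fp[[cat]]) > 0
    out[hit & !assigned] <- cat
    assigned <- assigned | hit
  }
  out
}

#' Feature-category distribution of a region set
#'
#' @inheritParams annotate_interval
#' @param regions Tibble of regions (`chrom`, `start`, `end`).
#' @return A tibble with `feature`, `n`, `percent` (two decimals, summing
#'   to 100 within rounding); categories with zero regions are omitted.
#' @export
feature_distribution <- function(regions, models, promoter_up = 2000,
                                 promoter_down = 200, downstream_bp = 3000) {
  if (nrow(regions) == 0) abort("at least one region is required")
  cat <- annotate_interval(regions, models, promoter_up, promoter_down,
                           downstream_bp)
  tibble(feature = factor(cat, levels = FEATURE_LEVELS)) |>
    count(.data$feature, name = "n") |>
    mutate(percent = round(100 * .data$n / sum(.data$n), 2),
           feature = as.character(.data$feature))
}

#' Read candidate cis-regulatory elements from BED
#'
#' BED with the element class in the 4th (name) column; classes must come
#' from the closed vocabulary prom, enhP, enhD, K4m3, CTCF (promoter-like,
#' proximal/distal enhancer-like, DNase-H3K4me3, and CTCF-bound
#' signatures).
#'
#' @param path BED file path.
#' @return Tibble: `chrom`, `start`, `end`, `cre_class`.
#' @export
read_cre_bed <- function(path) {
  bed <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl0(bed)
  out$cre_class <- bed$name
  bad <- setdiff(unique(out$cre_class), CRE_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown cCRE class(es): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(CRE_CLASSES, collapse = ", ")))
  }
  out
}

#' Region-by-class cCRE overlap counts
#'
#' Counts, for every region and element class, the number of elements
#' overlapping the region by at least one base (half-open coordinates; an
#' element abutting the region end does not count).
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally
#'   `region_id`.
#' @param elements Tibble from [read_cre_bed()] (columns `chrom`, `start`,
#'   `end`, `cre_class`).
#' @return A tibble with `region_id` and one count column per class
#'   (all five classes always present).
#' @export
cre_overlap_matrix <- function(regions, elements) {
  check_interval_tbl(regions, "regions")
  ids <- regions[["region_id"]] %||%
    sprintf("region_%03d", seq_len(nrow(regions)))
  q <- as_granges0(regions)
  out <- tibble(region_id = ids)
  for (cl in CRE_CLASSES) {
    el <- filter(elements, .data$cre_class == cl)
    out[[cl]] <- if (nrow(el) == 0) {
      rep(0L, nrow(regions))
    } else {
      GenomicRanges::countOverlaps(q, as_granges0(el))
    }
  }
  out
}

#' Summarise cCRE overlap
#'
#' @param table A [cre_overlap_matrix()] table.
#' @return A one-row tibble: `n_with_any` (regions overlapping at least one
#'   element of any class), `n_total`, `percent` (two decimals).
#' @export
count_any_cre <- function(table) {
  counts <- as.matrix(table[, intersect(names(table), CRE_CLASSES)])
  n_with_any <- sum(rowSums(counts) >= 1)
  tibble(
    n_with_any = n_with_any,
    n_total = nrow(table),
    percent = round(100 * n_with_any / nrow(table), 2)
  )
}
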