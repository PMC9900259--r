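#' Parse eccDNA locus strings
#'
#' Parses locus strings of the form `"chr2:89823776-89842856"` into genomic
#' intervals. Published catalogues mix dash dialects; plain hyphen, en-dash
#' and the Unicode minus sign are all accepted, as are thousands separators
#' in the coordinates. Printed coordinates are treated as 1-based inclusive
#' and converted to the package's internal 0-based half-open convention.
#'
#' @param text Character vector of locus strings.
#' @return A tibble with one row per input: `chrom`, `printed_start`,
#'   `printed_end` (the coordinates as printed, 1-based inclusive), `start`,
#'   `end` (0-based half-open), and `source_text`.
#' @examples
#' parse_locus_string("chr2:89823776-89842856")
#' @export
parse_locus_string <- function(text) {
  stopifnot(is.character(text))
  norm <- text
  # dash dialects: hyphen-minus, en-dash (U+2013), minus sign (U+2212)
  norm <- gsub("–", "-", norm)
  norm <- gsub("−", "-", norm)
  norm <- gsub(",", "", norm)
  norm <- gsub("[[:space:]]", "", norm)
  m <- regexec("^([^:]+):([0-9]+)-([0-9]+)$", norm)
  parts <- regmatches(norm, m)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    abort(sprintf("cannot parse locus string: '%s'", text[bad[1]]))
  }
  chrom <- vapply(parts, `[`, "", 2)
  p_start <- as.numeric(vapply(parts, `[`, "", 3))
  p_end <- as.numeric(vapply(parts, `[`, "", 4))
  rev_ord <- which(p_start >= p_end)
  if (length(rev_ord) > 0) {
    abort(sprintf("locus start is not before end: '%s'", text[rev_ord[1]]))
  }
  tibble(
    chrom = chrom,
    printed_start = p_start,
    printed_end = p_end,
    start = p_start - 1,
    end = p_end,
    source_text = text
  )
}

#' Per-sample eccDNA catalogue from nine glioblastoma scATAC-seq samples
#'
#' Loads the packaged per-sample eccDNA catalogue: 116 locus records called
#' from nine adult and pediatric glioblastoma (GBM) samples profiled by
#' single-cell ATAC-seq, together with each sample's percentage of cells
#' harboring at least one eccDNA.
#'
#' @return A tibble with columns `sample_id`, `condition`
#'   (adult/pediatric), `sample_description`, `locus`, parsed coordinate
#'   columns (see [parse_locus_string()]), and `pct_cells_harboring`.
#' @export
gbm_eccdna_catalogue <- function() {
  path <- system.file("extdata", "gbm_eccdna_catalogue.tsv",
                      package = "sceccdna", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  parsed <- parse_locus_string(raw$locus)
  dplyr::bind_cols(
    raw[c("sample_id", "condition", "sample_description", "locus")],
    parsed[c("chrom", "printed_start", "printed_end", "start", "end")]
  ) |>
    mutate(pct_cells_harboring = as.numeric(raw$pct_cells_harboring))
}

#' Merge eccDNA records into common regions by transitive overlap
#'
#' Merges genomic intervals that overlap by at least one base (1-based
#' inclusive semantics: merely touching intervals do not merge) into
#' maximal transitively-connected regions, per chromosome. This is the
#' "union of overlapping eccDNAs across samples" operation that defines a
#' common eccDNA catalogue from per-sample call sets.
#'
#' @param records Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `sample_id` and any other per-record columns.
#' @return A tibble of merged regions, sorted by chromosome then start:
#'   `region_id`, `chrom`, `start`, `end`, `n_records`, `n_samples`
#'   (distinct contributing `sample_id`s, or `n_records` when no sample
#'   column is present), and a `members` list-column holding the input rows
#'   assigned to each region.
#' @export
merge_intervals <- function(records) {
  check_interval_tbl(records, "records")
  if (nrow(records) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  n_records = integer(), n_samples = integer(),
                  members = list()))
  }
  gr <- as_granges0(records)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  assign <- integer(nrow(records))
  assign[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  out <- granges_to_tbl0(red)
  members <- split(records, factor(assign, levels = seq_len(nrow(out))))
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, ]
  members <- members[ord]
  out$region_id <- sprintf("region_%03d", seq_len(nrow(out)))
  out$n_records <- unname(vapply(members, nrow, integer(1)))
  out$n_samples <- unname(vapply(members, function(m) {
    if ("sample_id" %in% names(m)) dplyr::n_distinct(m$sample_id) else nrow(m)
  }, integer(1)))
  out$members <- unname(members)
  select(out, "region_id", "chrom", "start", "end",
         "n_records", "n_samples", "members")
}

#' Build a common eccDNA catalogue across samples
#'
#' Pools per-sample eccDNA records, merges them with [merge_intervals()],
#' and optionally keeps only regions supported by at least `min_samples`
#' distinct samples.
#'
#' @param x Either a tibble of records (columns `sample_id`, `chrom`,
#'   `start`, `end`; or `sample_id` plus a `locus` string column), or a
#'   character vector of per-sample BED file paths (sample ids taken from
#'   file names).
#' @param min_samples Minimum number of distinct contributing samples a
#'   merged region must have to be retained (default 1, the plain union).
#' @return A list with `regions` (the merged-region tibble, `members`
#'   dropped) and `membership` (one row per contributing record with its
#'   `region_id` and `sample_id`).
#' @export
common_catalogue <- function(x, min_samples = 1) {
  if (is.character(x)) {
    if (length(x) == 0) abort("at least one input file is required")
    x <- map_dfr(x, function(p) {
      bed <- rtracklayer::import(p, format = "BED")
      granges_to_tbl0(bed) |>
        mutate(sample_id = sub("\\.(bed|tsv)$", "", basename(p)))
    })
  }
  if (nrow(x) == 0) abort("no records supplied")
  if (!"start" %in% names(x) && "locus" %in% names(x)) {
    x <- dplyr::bind_cols(
      select(x, -dplyr::any_of(c("chrom", "start", "end"))),
      parse_locus_string(x$locus)[c("chrom", "start", "end")]
    )
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample_1"
  merged <- merge_intervals(x)
  merged <- filter(merged, .data$n_samples >= min_samples)
  membership <- merged |>
    select("region_id", "members") |>
    tidyr::unnest("members")
  list(
    regions = select(merged, -"members"),
    membership = membership
  )
}

#' Span statistics for eccDNA records or regions
#'
#' Computes the minimum, maximum and median span. In `printed` mode the
#' span is the printed-coordinate difference `printed_end - printed_start`
#' (the arithmetic used when a catalogue reports its length range from
#' 1-based inclusive coordinates); in `internal` mode it is the half-open
#' width `end - start`, one base larger.
#'
#' @param x Tibble with `start`/`end` columns (0-based half-open).
#' @param coordinate_mode `"printed"` (default) or `"internal"`.
#' @return A one-row tibble: `n`, `min_span`, `max_span`, `median_span`.
#' @export
span_stats <- function(x, coordinate_mode = c("printed", "internal")) {
  coordinate_mode <- match.arg(coordinate_mode)
  if (nrow(x) == 0) abort("span_stats requires at least one record")
  check_interval_tbl(x, "records")
  span <- x$end - x$start
  if (coordinate_mode == "printed") span <- span - 1
  tibble(
    n = nrow(x),
    min_span = min(span),
    max_span = max(span),
    median_span = median(span)
  )
}
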