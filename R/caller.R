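#' Junction-caller parameters
#'
#' @param min_mapq Minimum mapping quality for any contributing alignment.
#' @param cluster_tolerance_bp Breakpoints within this distance (on both
#'   the left and right coordinate) are single-linkage clustered.
#' @param min_split Split-read support sufficient on its own for a pass.
#' @param min_split_with_disc Split support sufficient when combined with
#'   at least `min_disc` discordant pairs.
#' @param min_disc See `min_split_with_disc`.
#' @param max_span_bp Maximum candidate span; longer junction evidence is
#'   discarded at extraction (circle junctions join a locus end back to its
#'   own start, so Mb-scale spans are outside this caller's scope).
#' @param evenness_bins Number of equal bins for the evenness QC.
#' @param evenness_min_frac Minimum fraction of bins covered by at least
#'   one mapped read for a candidate to pass QC.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_mapq = 10, cluster_tolerance_bp = 10,
                          min_split = 2, min_split_with_disc = 1,
                          min_disc = 2, max_span_bp = 1e6,
                          evenness_bins = 20, evenness_min_frac = 0.8) {
  stopifnot(cluster_tolerance_bp >= 0, min_mapq >= 0, min_split >= 0,
            min_split_with_disc >= 0, min_disc >= 0, max_span_bp > 0,
            evenness_bins >= 2, evenness_min_frac >= 0,
            evenness_min_frac <= 1)
  structure(list(
    min_mapq = min_mapq, cluster_tolerance_bp = cluster_tolerance_bp,
    min_split = min_split, min_split_with_disc = min_split_with_disc,
    min_disc = min_disc, max_span_bp = max_span_bp,
    evenness_bins = as.integer(evenness_bins),
    evenness_min_frac = evenness_min_frac
  ), class = "caller_params")
}

#' Classify a read pair's orientation
#'
#' Canonical FR pairs (forward read leftmost, mates facing inward) are
#' concordant; RF pairs (reverse read leftmost, mates facing outward on the
#' reference) are the discordant signature of a pair straddling a circle
#' junction. Same-strand, inter-chromosomal or partially unmapped pairs are
#' `other`.
#'
#' @param r1,r2 One-row data frames (or lists) with fields `chrom`,
#'   `start` (0-based), `end`, `strand` (`"+"`/`"-"`), and optionally
#'   `mapped` (default `TRUE`).
#' @return `"concordant"`, `"discordant_outward"`, or `"other"`.
#' @export
classify_pair <- function(r1, r2) {
  mapped1 <- r1[["mapped"]] %||% TRUE
  mapped2 <- r2[["mapped"]] %||% TRUE
  if (!isTRUE(mapped1) || !isTRUE(mapped2)) return("other")
  if (r1$chrom != r2$chrom) return("other")
  if (r1$strand == r2$strand) return("other")
  left <- if (r1$start <= r2$start) r1 else r2
  right <- if (r1$start <= r2$start) r2 else r1
  if (left$strand == "+" && right$strand == "-") return("concordant")
  if (left$strand == "-" && right$strand == "+") return("discordant_outward")
  "other"
}

#' Derive junction evidence from a split alignment
#'
#' Given SA-linked primary/supplementary alignment summaries, emits one
#' junction evidence record per row when the pair of alignments is
#' consistent with a circle junction: same chromosome, same strand, both
#' above the mapping-quality floor, and a span within `max_span_bp`. The
#' junction's genomic interval is (leftmost alignment start, rightmost
#' alignment end) -- the read walks off the circle end back to its start.
#'
#' @param primary,supplementary Tibbles of equal height with columns
#'   `chrom`, `start` (0-based), `end`, `strand`, `mapq`, and (on
#'   `primary`) optional `barcode` and `read_id`.
#' @param params A [caller_params()].
#' @return A tibble of `JunctionEvidence` rows (possibly zero): `kind`,
#'   `chrom`, `left_bp`, `right_bp`, `barcode`, `mapq`, `read_id`.
#' @export
split_to_junction <- function(primary, supplementary, params = caller_params()) {
  stopifnot(nrow(primary) == nrow(supplementary))
  if (nrow(primary) == 0) return(empty_evidence())
  ok <- primary$chrom == supplementary$chrom &
    primary$strand == supplementary$strand &
    primary$mapq >= params$min_mapq &
    supplementary$mapq >= params$min_mapq
  left_bp <- pmin(primary$start, supplementary$start)
  right_bp <- pmax(primary$end, supplementary$end)
  ok <- ok & (right_bp - left_bp) <= params$max_span_bp & left_bp < right_bp
  tibble(
    kind = "split",
    chrom = primary$chrom[ok],
    left_bp = left_bp[ok],
    right_bp = right_bp[ok],
    barcode = (primary[["barcode"]] %||%
                 rep(NA_character_, nrow(primary)))[ok],
    mapq = pmin(primary$mapq, supplementary$mapq)[ok],
    read_id = (primary[["read_id"]] %||%
                 rep(NA_character_, nrow(primary)))[ok]
  )
}

empty_evidence <- function() {
  tibble(kind = character(), chrom = character(), left_bp = numeric(),
         right_bp = numeric(), barcode = character(), mapq = numeric(),
         read_id = character())
}

# reference width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Extract junction evidence from a BAM file
#'
#' Streams a coordinate-sorted, indexed BAM and yields junction evidence:
#' split-read evidence from SA-linked primary records (via
#' [split_to_junction()]) and discordant evidence from outward-facing (RF)
#' same-chromosome pairs. Duplicate-flagged and secondary records are
#' skipped; evidence below the mapping-quality floor is dropped; records
#' without a CB tag are retained with a missing barcode and counted.
#'
#' @param bam Path to an indexed BAM.
#' @param params A [caller_params()].
#' @return A list: `evidence` (tibble of junction evidence) and `counters`
#'   (named list of diagnostic counts).
#' @export
stream_evidence <- function(bam, params = caller_params()) {
  if (!file.exists(bam)) abort(sprintf("BAM not found: %s", bam))
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort(sprintf("BAM index (.bai) not found for %s", bam))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("CB", "SA"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_records <- length(res$qname)
  if (n_records == 0) {
    return(list(evidence = empty_evidence(), counters = list(
      n_records = 0L, n_secondary_or_dup = 0L, n_no_barcode = 0L,
      n_split_rejected = 0L, n_pairs_concordant = 0L, n_pairs_other = 0L)))
  }
  rec <- tibble(
    read_id = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    start = res$pos - 1,
    end = res$pos - 1 + cigar_ref_width(res$cigar),
    mapq = res$mapq,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0, "-", "+"),
    first_mate = bitwAnd(res$flag, 64L) > 0,
    secondary = bitwAnd(res$flag, 256L) > 0,
    dup = bitwAnd(res$flag, 1024L) > 0,
    supplementary = bitwAnd(res$flag, 2048L) > 0,
    barcode = as.character(res$tag$CB %||% rep(NA, n_records)),
    sa = as.character(res$tag$SA %||% rep(NA, n_records))
  )
  n_secondary_or_dup <- sum(rec$secondary | rec$dup)
  rec <- filter(rec, !.data$secondary, !.data$dup)

  # split evidence from SA-linked primary records
  prim <- filter(rec, !.data$supplementary, !is.na(.data$sa), .data$sa != "")
  n_split_rejected <- 0L
  split_ev <- empty_evidence()
  if (nrow(prim) > 0) {
    sa1 <- stringr::str_split_fixed(
      stringr::str_split_fixed(prim$sa, ";", 2)[, 1], ",", 6)
    supp <- tibble(
      chrom = sa1[, 1],
      start = as.numeric(sa1[, 2]) - 1,
      strand = sa1[, 3],
      mapq = as.numeric(sa1[, 5])
    )
    supp$end <- supp$start + cigar_ref_width(sa1[, 4])
    split_ev <- split_to_junction(
      select(prim, "chrom", "start", "end", "strand", "mapq",
             "barcode", "read_id"),
      supp, params)
    n_split_rejected <- nrow(prim) - nrow(split_ev)
  }

  # discordant evidence from outward-facing primary pairs (pairs where a
  # mate already produced split evidence are not re-counted)
  pairs <- filter(rec, !.data$supplementary, is.na(.data$sa) | .data$sa == "",
                  !.data$read_id %in% prim$read_id)
  pairs <- arrange(pairs, .data$read_id, .data$start)
  qf <- factor(pairs$read_id)
  full <- tabulate(qf)[as.integer(qf)] == 2L
  pairs <- pairs[full, ]
  disc_ev <- empty_evidence()
  n_pairs_concordant <- 0L
  n_pairs_other <- 0L
  if (nrow(pairs) > 0) {
    i1 <- seq(1, nrow(pairs), by = 2)
    i2 <- i1 + 1L
    both_mates <- pairs$first_mate[i1] != pairs$first_mate[i2]
    p <- tibble(
      read_id = pairs$read_id[i1],
      chrom1 = pairs$chrom[i1], chrom2 = pairs$chrom[i2],
      left_start = pairs$start[i1], left_strand = pairs$strand[i1],
      right_end = pmax(pairs$end[i1], pairs$end[i2]),
      right_strand = pairs$strand[i2],
      mapq = pmin(pairs$mapq[i1], pairs$mapq[i2]),
      barcode = pairs$barcode[i1]
    )[both_mates, ]
    same_chrom <- p$chrom1 == p$chrom2
    outward <- same_chrom & p$left_strand == "-" & p$right_strand == "+"
    concord <- same_chrom & p$left_strand == "+" & p$right_strand == "-"
    keep <- outward & p$mapq >= params$min_mapq &
      (p$right_end - p$left_start) <= params$max_span_bp &
      p$left_start < p$right_end
    n_pairs_concordant <- sum(concord)
    n_pairs_other <- sum(!outward & !concord)
    disc_ev <- tibble(
      kind = "discordant",
      chrom = p$chrom1[keep],
      left_bp = p$left_start[keep],
      right_bp = p$right_end[keep],
      barcode = p$barcode[keep],
      mapq = p$mapq[keep],
      read_id = p$read_id[keep]
    )
  }
  evidence <- bind_rows(split_ev, disc_ev)
  list(evidence = evidence, counters = list(
    n_records = n_records,
    n_secondary_or_dup = n_secondary_or_dup,
    n_no_barcode = sum(is.na(evidence$barcode)),
    n_split_rejected = n_split_rejected,
    n_pairs_concordant = n_pairs_concordant,
    n_pairs_other = n_pairs_other
  ))
}

# single-linkage union-find over evidence whose left and right breakpoints
# both agree within tol; evidence must be from one chromosome. Runs on the
# unique (left, right) pairs, then maps components back to records.
cluster_one_chrom <- function(ev, tol) {
  key <- paste(ev$left_bp, ev$right_bp)
  uniq <- !duplicated(key)
  lefts0 <- ev$left_bp[uniq]
  rights0 <- ev$right_bp[uniq]
  n <- length(lefts0)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(lefts0, rights0)
  lefts <- lefts0[ord]
  rights <- rights0[ord]
  for (i in seq_len(n)) {
    j <- i - 1L
    while (j >= 1L && lefts[i] - lefts[j] <= tol) {
      if (abs(rights[i] - rights[j]) <= tol) {
        ri <- find(ord[i]); rj <- find(ord[j])
        if (ri != rj) parent[ri] <- rj
      }
      j <- j - 1L
    }
  }
  comp_u <- vapply(seq_len(n), find, integer(1))
  comp_u[match(key, key[uniq])]
}

# modal value, ties broken toward the smaller coordinate
modal_bp <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

# lower median (ties toward the smaller coordinate)
lower_median <- function(x) {
  sort(x)[ceiling(length(x) / 2)]
}

#' Cluster junction evidence into circle candidates
#'
#' Single-linkage clusters evidence whose left and right breakpoints both
#' agree within `cluster_tolerance_bp`. Each cluster's boundary is the
#' modal breakpoint among its split evidence when any exists, otherwise the
#' median of its discordant breakpoints; ties break toward the smaller
#' coordinate.
#'
#' @param evidence Junction-evidence tibble (one or more chromosomes).
#' @param params A [caller_params()].
#' @return A tibble of candidates: `call_id`, `chrom`, `start`, `end`,
#'   `n_split`, `n_discordant`, `n_cells`, plus an `evidence` list-column
#'   holding the evidence rows assigned to each candidate.
#' @export
cluster_evidence <- function(evidence, params = caller_params()) {
  if (nrow(evidence) == 0) {
    return(tibble(call_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_split = integer(),
                  n_discordant = integer(), n_cells = integer(),
                  evidence = list()))
  }
  by_chrom <- split(evidence, evidence$chrom)
  cands <- map_dfr(by_chrom, function(ev) {
    comp <- cluster_one_chrom(ev, params$cluster_tolerance_bp)
    map_dfr(split(ev, comp), function(cl) {
      splits <- filter(cl, .data$kind == "split")
      if (nrow(splits) > 0) {
        b_left <- modal_bp(splits$left_bp)
        b_right <- modal_bp(splits$right_bp)
      } else {
        b_left <- lower_median(cl$left_bp)
        b_right <- lower_median(cl$right_bp)
      }
      tibble(
        chrom = cl$chrom[1], start = b_left, end = b_right,
        n_split = nrow(splits),
        n_discordant = sum(cl$kind == "discordant"),
        n_cells = dplyr::n_distinct(cl$barcode[!is.na(cl$barcode)]),
        evidence = list(cl)
      )
    })
  })
  cands <- arrange(cands, .data$chrom, .data$start, .data$end)
  cands$call_id <- sprintf("ecc_%04d", seq_len(nrow(cands)))
  select(cands, "call_id", dplyr::everything())
}

#' Evenness quality control
#'
#' Applies the support gate and the read-evenness filter to candidate
#' calls. A candidate's interval is split into `evenness_bins` equal bins
#' (or one bin per base for sub-bin intervals); evenness is the fraction of
#' bins overlapped by at least one mapped read. Support is gated first:
#' a pass needs `n_split >= min_split`, or `n_split >= min_split_with_disc`
#' together with `n_discordant >= min_disc`. Candidates spanning more than
#' `max_span_bp` fail rather than being dropped.
#'
#' @param candidates Candidate tibble from [cluster_evidence()].
#' @param bam The BAM the evidence came from.
#' @param params A [caller_params()].
#' @return The candidates with `evenness` and `status` columns added
#'   (`pass`, `fail_support`, `fail_evenness`, or `fail_span`).
#' @export
evenness_qc <- function(candidates, bam, params = caller_params()) {
  if (nrow(candidates) == 0) {
    candidates$evenness <- numeric()
    candidates$status <- character()
    return(candidates)
  }
  evenness <- map_dbl(seq_len(nrow(candidates)), function(i) {
    span <- candidates$end[i] - candidates$start[i]
    nb <- min(params$evenness_bins, span)
    region <- GenomicRanges::GRanges(
      candidates$chrom[i],
      IRanges::IRanges(candidates$start[i] + 1, candidates$end[i]))
    aln <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(
        which = region,
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isDuplicate = FALSE,
                                      isSecondaryAlignment = FALSE)))
    edges <- candidates$start[i] + round(seq(0, span, length.out = nb + 1))
    bins <- GenomicRanges::GRanges(
      candidates$chrom[i],
      IRanges::IRanges(head(edges, -1) + 1, tail(edges, -1)))
    hit <- GenomicRanges::countOverlaps(bins, GenomicRanges::granges(aln)) > 0
    mean(hit)
  })
  support_ok <- candidates$n_split >= params$min_split |
    (candidates$n_split >= params$min_split_with_disc &
       candidates$n_discordant >= params$min_disc)
  span_ok <- (candidates$end - candidates$start) <= params$max_span_bp
  candidates$evenness <- evenness
  candidates$status <- dplyr::case_when(
    !support_ok ~ "fail_support",
    !span_ok ~ "fail_span",
    evenness < params$evenness_min_frac ~ "fail_evenness",
    TRUE ~ "pass"
  )
  candidates
}

#' Call eccDNA from a BAM file
#'
#' End-to-end detection: [stream_evidence()] then [cluster_evidence()] per
#' chromosome then [evenness_qc()]. Deterministic for a fixed BAM and
#' parameter set.
#'
#' @param bam Path to an indexed, coordinate-sorted BAM.
#' @param params A [caller_params()].
#' @param out_dir Optional output directory; when given, writes
#'   `calls.bed` (pass calls only, BED6 with score = total support),
#'   `calls.tsv` (all candidates with support columns), `evidence.tsv`
#'   (per-evidence rows with call assignment), and `counters.json`.
#' @return A list: `calls` (tibble of all candidates with status),
#'   `evidence` (tibble with `call_id` column), `counters`.
#' @export
call_eccdna <- function(bam, params = caller_params(), out_dir = NULL) {
  streamed <- stream_evidence(bam, params)
  cands <- cluster_evidence(streamed$evidence, params)
  cands <- evenness_qc(cands, bam, params)
  evidence <- if (nrow(cands) > 0) {
    cands |>
      select("call_id", "evidence") |>
      tidyr::unnest("evidence")
  } else {
    mutate(empty_evidence(), call_id = character())
  }
  calls <- select(cands, -"evidence")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pass <- filter(calls, .data$status == "pass")
    readr::write_tsv(
      tibble(chrom = pass$chrom, start = pass$start, end = pass$end,
             name = pass$call_id,
             score = pass$n_split + pass$n_discordant, strand = "."),
      file.path(out_dir, "calls.bed"), col_names = FALSE)
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
    readr::write_tsv(evidence, file.path(out_dir, "evidence.tsv"))
    jsonlite::write_json(streamed$counters,
                         file.path(out_dir, "counters.json"),
                         auto_unbox = TRUE)
  }
  list(calls = calls, evidence = evidence, counters = streamed$counters)
}
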