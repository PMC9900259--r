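# Read emission. Every fragment yields an inward-facing read pair on its
# template. Fragments that wrap a circle junction are written as truth
# alignments on the linear reference:
#   - a read crossing the junction with both pieces >= min_clip becomes a
#     primary alignment soft-clipped at the junction plus an SA-linked
#     supplementary alignment for the clipped part (split-read evidence);
#   - otherwise the pair is written as an outward-facing (RF) discordant
#     pair: the left-end read anchored to the pre-junction side, the
#     right-end read to the post-junction side.
# All other pairs are properly paired FR. Cell barcodes travel in the CB
# tag (BAM) or as a read-name suffix (FASTQ).

# wrapped substring on a circular template [s, s+L) of chromosome string
extract_wrapped <- function(chrom_str, s, L, o, len) {
  o <- o %% L
  first_len <- pmin(len, L - o)
  p1 <- substring(chrom_str, s + o + 1, s + o + first_len)
  need2 <- first_len < len
  p2 <- ifelse(need2, substring(chrom_str, s + 1, s + (len - first_len)), "")
  paste0(p1, p2)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- sample(bases, k, replace = TRUE)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Emit barcoded paired-end reads from simulated fragments
#'
#' Writes reads for every fragment as a coordinate-sorted, indexed BAM of
#' truth alignments (no aligner involved), or as a gzipped FASTQ pair for
#' users who want to run a real aligner. Sidecar truth files (circle BED,
#' cell table TSV, JSON manifest) are written alongside.
#'
#' @param fragments Tibble from [simulate_fragments()].
#' @param truth The `sim_truth` the fragments were drawn from.
#' @param genome The [generate_genome()] output.
#' @param config The matching [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param mode `"bam"` or `"fastq"`.
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a list with `files` (named paths), and `counters`
#'   (`n_proper_pairs`, `n_split_pairs`, `n_discordant_pairs`,
#'   `n_fragments_rejected`).
#' @export
emit_reads <- function(fragments, truth, genome, config, out_dir,
                       mode = c("bam", "fastq"), prefix = "sim") {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(config$seed, 5))
  r <- config$read_length
  chrom_str <- setNames(as.character(genome), names(genome))

  fr <- fragments
  circ <- truth$circles
  ci <- match(fr$circle_id, circ$circle_id)
  cs <- circ$start[ci]
  L <- circ$end[ci] - circ$start[ci]
  o <- fr$offset
  f <- fr$length
  wrap <- !is.na(fr$junction) & fr$junction

  # per-read geometry (A = left/forward mate, B = right/reverse mate)
  clipA <- ifelse(wrap, pmax(0, o + r - L), 0)
  preA <- r - clipA
  startB <- o + f - r
  preB <- ifelse(wrap, pmin(r, pmax(0, L - startB)), 0)
  postB <- r - preB
  crossesA <- wrap & clipA > 0
  crossesB <- wrap & preB > 0 & postB > 0
  qualA <- crossesA & clipA >= config$min_clip & preA >= config$min_clip
  qualB <- crossesB & preB >= config$min_clip & postB >= config$min_clip
  is_split <- wrap & (qualA | qualB)
  is_disc <- wrap & !is_split

  # read A primary alignment: position, CIGAR, longer-piece fallback
  a_use_pre <- !crossesA | qualA | (is_split & preA >= clipA) | is_disc
  a_pos <- ifelse(wrap, ifelse(a_use_pre, cs + o, cs), fr$start)
  a_cigar <- ifelse(!wrap | !crossesA,
                    paste0(r, "M"),
                    ifelse(a_use_pre,
                           paste0(preA, "M", clipA, "S"),
                           paste0(preA, "S", clipA, "M")))
  # read B primary alignment
  b_full_post <- wrap & preB == 0
  b_use_pre <- crossesB & ((qualB) | (is_split & preB >= postB))
  b_use_pre <- b_use_pre & !is_disc            # discordant anchors B post-side
  b_pos <- ifelse(!wrap, fr$start + f - r,
                  ifelse(b_full_post, cs + (startB - L),
                         ifelse(b_use_pre, cs + startB, cs)))
  b_cigar <- ifelse(!wrap | b_full_post,
                    paste0(r, "M"),
                    ifelse(b_use_pre,
                           paste0(preB, "M", postB, "S"),
                           paste0(preB, "S", postB, "M")))

  # sequences (template order; B is sequenced reverse-complement)
  seq_a <- character(nrow(fr)); seq_b <- character(nrow(fr))
  for (ch in names(chrom_str)) {
    idx <- which(fr$chrom == ch)
    if (length(idx) == 0) next
    str <- chrom_str[[ch]]
    w <- wrap[idx]
    sa <- character(length(idx)); sb <- character(length(idx))
    if (any(!w)) {
      g <- fr$start[idx][!w]; fl <- f[idx][!w]
      sa[!w] <- substring(str, g + 1, g + r)
      sb[!w] <- substring(str, g + fl - r + 1, g + fl)
    }
    if (any(w)) {
      sa[w] <- extract_wrapped(str, cs[idx][w], L[idx][w], o[idx][w], r)
      sb[w] <- extract_wrapped(str, cs[idx][w], L[idx][w], startB[idx][w], r)
    }
    seq_a[idx] <- sa
    seq_b[idx] <- sb
  }
  seq_b <- revcomp(seq_b)
  if (config$substitution_rate > 0) {
    seq_a <- apply_substitutions(seq_a, config$substitution_rate)
    seq_b <- apply_substitutions(seq_b, config$substitution_rate)
  }

  files <- list()
  counters <- list(
    n_proper_pairs = sum(!wrap),
    n_split_pairs = sum(is_split),
    n_discordant_pairs = sum(is_disc),
    n_fragments_rejected = attr(fragments, "n_rejected") %||% 0L
  )

  if (mode == "fastq") {
    qual <- strrep("I", r)
    nm <- paste0(fr$fragment_id, "_CB:", fr$barcode)
    for (mate in 1:2) {
      path <- file.path(out_dir, sprintf("%s_R%d.fastq.gz", prefix, mate))
      con <- gzfile(path, "w")
      sq <- if (mate == 1) seq_a else seq_b
      writeLines(paste0("@", nm, "/", mate, "\n", sq, "\n+\n", qual), con)
      close(con)
      files[[paste0("fastq_r", mate)]] <- path
    }
  } else {
    qual <- strrep("I", r)
    cb <- paste0("CB:Z:", fr$barcode)
    flag_a <- ifelse(wrap, 97L, 99L)
    flag_b <- ifelse(wrap, 145L, 147L)
    tlen_a <- ifelse(wrap, 0L, f)
    tlen_b <- ifelse(wrap, 0L, -f)
    sa_of <- function(pos0, strand, cigar) {
      paste0("SA:Z:", fr$chrom, ",", as.integer(pos0 + 1), ",", strand, ",",
             cigar, ",60,0;")
    }
    sam_line <- function(qn, flag, chrom, pos0, cigar, mpos0, tlen, seq, tags) {
      paste(qn, flag, chrom, as.integer(pos0 + 1), 60, cigar, "=",
            as.integer(mpos0 + 1), as.integer(tlen), seq, qual, tags,
            sep = "\t")
    }
    lines <- c(
      sam_line(fr$fragment_id, flag_a, fr$chrom, a_pos, a_cigar, b_pos,
               tlen_a, seq_a,
               ifelse(qualA, paste(cb, sa_of(cs, "+",
                                             paste0(preA, "S", clipA, "M")),
                                   sep = "\t"), cb)),
      sam_line(fr$fragment_id, flag_b, fr$chrom, b_pos, b_cigar, a_pos,
               tlen_b, seq_b,
               ifelse(qualB, paste(cb, sa_of(cs, "-",
                                             paste0(preB, "S", postB, "M")),
                                   sep = "\t"), cb))
    )
    if (any(qualA)) {
      i <- which(qualA)
      lines <- c(lines, sam_line(
        fr$fragment_id[i], flag_a[i] + 2048L, fr$chrom[i], cs[i],
        paste0(preA[i], "S", clipA[i], "M"), b_pos[i], 0L, seq_a[i],
        paste(cb[i],
              paste0("SA:Z:", fr$chrom[i], ",", as.integer(cs[i] + o[i] + 1),
                     ",+,", preA[i], "M", clipA[i], "S,60,0;"),
              sep = "\t")))
    }
    if (any(qualB)) {
      i <- which(qualB)
      lines <- c(lines, sam_line(
        fr$fragment_id[i], flag_b[i] + 2048L, fr$chrom[i], cs[i],
        paste0(preB[i], "S", postB[i], "M"), a_pos[i], 0L, seq_b[i],
        paste(cb[i],
              paste0("SA:Z:", fr$chrom[i], ",",
                     as.integer(cs[i] + startB[i] + 1),
                     ",-,", preB[i], "M", postB[i], "S,60,0;"),
              sep = "\t")))
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        as.integer(config$chrom_lengths)))
    sam_path <- file.path(out_dir, paste0(prefix, ".sam"))
    writeLines(c(header, lines), sam_path)
    bam_base <- file.path(out_dir, prefix)
    bam_path <- Rsamtools::asBam(sam_path, bam_base, overwrite = TRUE,
                                 indexDestination = TRUE)
    unlink(sam_path)
    files$bam <- bam_path
  }

  # truth sidecars
  bed <- file.path(out_dir, paste0(prefix, "_truth_circles.bed"))
  readr::write_tsv(
    mutate(truth$circles, name = paste0("circle_", .data$circle_id),
           score = 0, strand = "+") |>
      select("chrom", "start", "end", "name", "score", "strand"),
    bed, col_names = FALSE)
  files$truth_bed <- bed
  cells_tsv <- file.path(out_dir, paste0(prefix, "_truth_cells.tsv"))
  cell_circ <- truth$assignments |>
    group_by(.data$barcode) |>
    summarise(circle_ids = paste(.data$circle_id, collapse = ","))
  readr::write_tsv(left_join(truth$cells, cell_circ, by = "barcode"),
                   cells_tsv)
  files$truth_cells <- cells_tsv
  manifest <- file.path(out_dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    mode = mode,
    counters = counters
  ), manifest, auto_unbox = TRUE)
  files$manifest <- manifest

  invisible(list(files = files, counters = counters))
}

#' Run the full simulator
#'
#' Convenience wrapper chaining [generate_genome()], [plant_circles()],
#' [assign_cell_profiles()], [simulate_fragments()] and [emit_reads()].
#'
#' @inheritParams emit_reads
#' @param config A [sim_config()].
#' @return A list: `truth`, `genome`, `fragments`, `files`, `counters`.
#' @export
simulate_eccdna_reads <- function(config, out_dir, mode = "bam",
                                  prefix = "sim") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config,
                            fasta = file.path(out_dir, paste0(prefix, ".fa")))
  truth <- plant_circles(genome, config)
  truth <- assign_cell_profiles(truth, config)
  fragments <- simulate_fragments(truth, config)
  emitted <- emit_reads(fragments, truth, genome, config, out_dir,
                        mode = mode, prefix = prefix)
  list(truth = truth, genome = genome, fragments = fragments,
       files = emitted$files, counters = emitted$counters)
}
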