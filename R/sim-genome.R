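#' Generate a toy reference genome
#'
#' Draws uniform random A/C/G/T sequence for each configured chromosome.
#' Deterministic for a fixed config (including its seed): the same config
#' yields byte-identical FASTA output.
#'
#' @param config A [sim_config()].
#' @param fasta Optional path; when given, the genome is written there as
#'   uncompressed FASTA.
#' @return A named [Biostrings::DNAStringSet] (names `chr1`, `chr2`, ...).
#' @export
generate_genome <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  base_codes <- utf8ToInt("ACGT")
  seqs <- vapply(config$chrom_lengths, function(len) {
    intToUtf8(base_codes[sample.int(4L, len, replace = TRUE)])
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(genome, fasta)
  }
  genome
}

#' Plant non-overlapping circular templates
#'
#' Places `n_circles` circle intervals on the genome: spans uniform within
#' `circle_span_range`, positions uniform over the chromosomes (weighted by
#' length), rejected and redrawn on overlap with an already-placed circle.
#'
#' @param genome A genome from [generate_genome()].
#' @param config The [sim_config()] used to generate it.
#' @return A `sim_truth` list with `circles` (tibble: `circle_id`, `chrom`,
#'   `start`, `end`; 0-based half-open), empty cell slots, and the seed.
#' @export
plant_circles <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2))
  chrom_len <- setNames(config$chrom_lengths, names(genome))
  if (config$circle_span_range[1] >= max(chrom_len)) {
    abort("circle span range does not fit inside any chromosome")
  }
  circles <- tibble(circle_id = integer(), chrom = character(),
                    start = numeric(), end = numeric())
  placed <- list()
  max_tries <- 1000L * max(1L, config$n_circles)
  tries <- 0L
  while (nrow(circles) < config$n_circles) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("could not place all circles without overlap; reduce n_circles or spans")
    }
    span <- round(runif(1, config$circle_span_range[1],
                        config$circle_span_range[2]))
    chrom <- sample(names(genome), 1, prob = chrom_len)
    if (span >= chrom_len[[chrom]]) next
    start <- floor(runif(1, 0, chrom_len[[chrom]] - span))
    end <- start + span
    clash <- any(vapply(placed, function(p) {
      p$chrom == chrom && start < p$end && p$start < end
    }, logical(1)))
    if (clash) next
    placed[[length(placed) + 1]] <- list(chrom = chrom, start = start, end = end)
    circles <- bind_rows(circles, tibble(
      circle_id = nrow(circles) + 1L, chrom = chrom,
      start = start, end = end
    ))
  }
  structure(list(
    circles = circles,
    cells = NULL,
    assignments = NULL,
    seed = config$seed
  ), class = "sim_truth")
}

#' Assign circles to cells
#'
#' Each cell receives a type (uniformly over `config$cell_types`) and then
#' draws each planted circle independently with its type's presence
#' probability, emulating sparse per-cell eccDNA presence.
#'
#' @param truth A `sim_truth` from [plant_circles()].
#' @param config The matching [sim_config()].
#' @return The `sim_truth` with `cells` (tibble: `barcode`, `cell_type`)
#'   and `assignments` (tibble: `barcode`, `circle_id`) filled in.
#' @export
assign_cell_profiles <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3))
  barcodes <- sprintf("BC%05d", seq_len(config$n_cells))
  types <- sample(config$cell_types, config$n_cells, replace = TRUE)
  cells <- tibble(barcode = barcodes, cell_type = types)
  n_circ <- nrow(truth$circles)
  if (n_circ > 0) {
    prob <- config$presence_prob[types]
    draws <- matrix(rbinom(config$n_cells * n_circ, 1,
                           rep(prob, times = n_circ)),
                    nrow = config$n_cells)
    idx <- which(draws == 1, arr.ind = TRUE)
    assignments <- tibble(
      barcode = barcodes[idx[, 1]],
      circle_id = truth$circles$circle_id[idx[, 2]]
    ) |> arrange(.data$barcode, .data$circle_id)
  } else {
    assignments <- tibble(barcode = character(), circle_id = integer())
  }
  truth$cells <- cells
  truth$assignments <- assignments
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  circles: %d\n", nrow(x$circles)))
  if (!is.null(x$cells)) {
    cat(sprintf("  cells: %d (%d circle assignments)\n",
                nrow(x$cells), nrow(x$assignments)))
  }
  invisible(x)
}
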