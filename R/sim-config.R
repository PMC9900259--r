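#' Simulation configuration
#'
#' Builds a validated configuration for the read simulator. Defaults emulate
#' a desk-scale version of the data regime the pipeline targets: a small
#' multi-chromosome genome, a handful of short circles (1-20 kb, matching
#' the short-eccDNA range seen in scATAC-seq catalogues), sparse per-cell
#' circle presence (10% of cells of a permissive type), and paired-end
#' 80 bp reads from ~250 bp fragments.
#'
#' @param n_chromosomes Number of reference chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths (bp); recycled
#'   or truncated to `n_chromosomes`.
#' @param n_circles Number of circular templates to plant.
#' @param circle_span_range Length-2 numeric: min/max circle span (bp).
#' @param n_cells Number of cells.
#' @param cell_types Character vector of cell-type labels; cells are
#'   assigned a type uniformly at random.
#' @param presence_prob Named numeric vector (one probability per cell
#'   type) or a single probability applied to all types: the chance that a
#'   given cell carries a given circle, independently per circle.
#' @param reads_per_cell Mean read pairs per cell (Poisson).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param read_length Read length (bp); must be below `fragment_mean`.
#' @param circle_read_fraction Fraction of a circle-positive cell's
#'   fragments drawn from its circles (split evenly among them).
#' @param substitution_rate Per-base substitution error rate (default 0;
#'   the detection logic under test is positional, not sequence-level).
#' @param min_clip Minimum soft-clipped length (bp) for a junction-crossing
#'   read to be written as a split alignment with a supplementary record;
#'   shorter clips demote the pair to discordant-only evidence.
#' @param seed Integer seed; every simulator operation is a pure function
#'   of its inputs and this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_lengths = c(300000, 200000),
                       n_circles = 5,
                       circle_span_range = c(1000, 20000),
                       n_cells = 2000,
                       cell_types = c("malignant", "normal"),
                       presence_prob = 0.1,
                       reads_per_cell = 50,
                       fragment_mean = 250,
                       fragment_sd = 30,
                       read_length = 80,
                       circle_read_fraction = 0.3,
                       substitution_rate = 0,
                       min_clip = 20,
                       seed = 1) {
  chrom_lengths <- rep_len(as.numeric(chrom_lengths), n_chromosomes)
  if (n_chromosomes < 1 || any(chrom_lengths <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  if (length(circle_span_range) != 2 ||
      circle_span_range[1] > circle_span_range[2] ||
      circle_span_range[1] <= 0) {
    abort("circle_span_range must be (min, max) with 0 < min <= max")
  }
  if (length(presence_prob) == 1 && is.null(names(presence_prob))) {
    presence_prob <- setNames(rep(presence_prob, length(cell_types)),
                              cell_types)
  }
  if (!all(cell_types %in% names(presence_prob))) {
    missing_t <- setdiff(cell_types, names(presence_prob))
    abort(sprintf("presence_prob missing cell type(s): %s",
                  paste(missing_t, collapse = ", ")))
  }
  if (any(presence_prob < 0 | presence_prob > 1)) {
    abort("presence probabilities must be in [0, 1]")
  }
  if (read_length >= fragment_mean) {
    abort("read_length must be smaller than fragment_mean")
  }
  if (n_circles < 0 || n_cells < 1 || reads_per_cell <= 0 ||
      fragment_sd < 0 || read_length < 1 ||
      circle_read_fraction < 0 || circle_read_fraction > 1 ||
      substitution_rate < 0 || substitution_rate > 1) {
    abort("invalid simulation parameter (check counts, rates, lengths)")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = chrom_lengths,
    n_circles = as.integer(n_circles),
    circle_span_range = as.numeric(circle_span_range),
    n_cells = as.integer(n_cells),
    cell_types = cell_types,
    presence_prob = presence_prob,
    reads_per_cell = reads_per_cell,
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    read_length = as.integer(read_length),
    circle_read_fraction = circle_read_fraction,
    substitution_rate = substitution_rate,
    min_clip = as.integer(min_clip),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp\n", x$n_chromosomes,
              paste(format(x$chrom_lengths, big.mark = ","), collapse = " + ")))
  cat(sprintf("  circles: %d, span %s-%s bp\n", x$n_circles,
              x$circle_span_range[1], x$circle_span_range[2]))
  cat(sprintf("  cells: %d (%s), presence prob %s\n", x$n_cells,
              paste(x$cell_types, collapse = "/"),
              paste(sprintf("%s=%.2g", names(x$presence_prob),
                            x$presence_prob), collapse = " ")))
  cat(sprintf("  reads: ~%g pairs/cell, fragment %g+/-%g bp, read %d bp, seed %d\n",
              x$reads_per_cell, x$fragment_mean, x$fragment_sd,
              x$read_length, x$seed))
  invisible(x)
}
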