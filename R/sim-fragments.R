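#' Simulate sequencing fragments
#'
#' Draws fragments for every cell: background fragments uniform on the
#' linear chromosomes, and (for circle-positive cells) fragments uniform on
#' the circularised coordinate system of each carried circle, where start
#' positions wrap through the junction. A circle fragment is
#' junction-crossing iff it wraps past the circle end, which happens with
#' probability (f-1)/L for a fragment of length f on a circle of length L.
#'
#' @param truth A `sim_truth` with cell assignments.
#' @param config The matching [sim_config()].
#' @return A tibble of fragments: `fragment_id`, `barcode`, `cell_type`,
#'   `source` (`linear`/`circle`), `circle_id`, `chrom`, `start` (genome,
#'   0-based; for circle fragments the junction-wrapped start is encoded by
#'   `offset` on the circle instead), `offset`, `length`, `junction`
#'   (logical). Fragments longer than their circle are rejected, not
#'   emitted; the count is in `attr(, "n_rejected")`.
#' @export
simulate_fragments <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (is.null(truth$cells)) abort("run assign_cell_profiles() first")
  set.seed(derive_seed(config$seed, 4))
  cells <- truth$cells
  circles <- truth$circles
  n_frag <- rpois(nrow(cells), config$reads_per_cell)

  # split each cell's fragments between its circles (if any) and background
  circ_per_cell <- split(truth$assignments$circle_id, truth$assignments$barcode)
  has_circ <- cells$barcode %in% names(circ_per_cell)
  n_circ_frag <- ifelse(has_circ,
                        rbinom(nrow(cells), n_frag, config$circle_read_fraction),
                        0L)
  n_lin_frag <- n_frag - n_circ_frag

  # linear background fragments
  lin_cells <- rep(seq_len(nrow(cells)), n_lin_frag)
  n_lin <- length(lin_cells)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  lin_chrom_idx <- sample.int(config$n_chromosomes, n_lin, replace = TRUE,
                              prob = config$chrom_lengths)
  lin_len <- pmax(config$read_length,
                  round(rnorm(n_lin, config$fragment_mean, config$fragment_sd)))
  lin_max_start <- config$chrom_lengths[lin_chrom_idx] - lin_len
  keep <- lin_max_start >= 0
  lin <- tibble(
    barcode = cells$barcode[lin_cells[keep]],
    cell_type = cells$cell_type[lin_cells[keep]],
    source = "linear",
    circle_id = NA_integer_,
    chrom = chrom_names[lin_chrom_idx[keep]],
    start = floor(runif(sum(keep)) * (lin_max_start[keep] + 1)),
    offset = NA_real_,
    length = lin_len[keep],
    junction = FALSE
  )

  # circle fragments: pick a carried circle uniformly per fragment
  circ_cells <- rep(seq_len(nrow(cells)), n_circ_frag)
  n_cf <- length(circ_cells)
  n_rejected <- 0L
  if (n_cf > 0) {
    picked <- vapply(cells$barcode[circ_cells], function(b) {
      ids <- circ_per_cell[[b]]
      if (length(ids) == 1) ids else sample(ids, 1)
    }, integer(1), USE.NAMES = FALSE)
    ci <- match(picked, circles$circle_id)
    L <- circles$end[ci] - circles$start[ci]
    cf_len <- pmax(config$read_length,
                   round(rnorm(n_cf, config$fragment_mean, config$fragment_sd)))
    ok <- cf_len <= L
    n_rejected <- sum(!ok)
    offset <- floor(runif(n_cf) * L)
    circ <- tibble(
      barcode = cells$barcode[circ_cells[ok]],
      cell_type = cells$cell_type[circ_cells[ok]],
      source = "circle",
      circle_id = picked[ok],
      chrom = circles$chrom[ci[ok]],
      start = circles$start[ci[ok]] + offset[ok],
      offset = offset[ok],
      length = cf_len[ok],
      junction = (offset[ok] + cf_len[ok]) > L[ok]
    )
  } else {
    circ <- lin[0, ]
  }

  out <- bind_rows(lin, circ) |>
    mutate(fragment_id = sprintf("frag%07d", row_number())) |>
    select("fragment_id", dplyr::everything())
  attr(out, "n_rejected") <- n_rejected
  out
}
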