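#' Build the eccDNA-by-cell count matrix
#'
#' Traces junction evidence back to cells: `counts[i, j]` is the number of
#' evidence records supporting call `i` that carry barcode `j`. Evidence
#' with a missing barcode, or a barcode absent from the supplied cell
#' table, is excluded and counted (the cell table defines the analysis
#' denominator -- typically QC-passed cells).
#'
#' @param evidence Evidence tibble with `call_id` and `barcode` columns
#'   (from [call_eccdna()]).
#' @param calls Call tibble (rows of the matrix; all calls are represented
#'   even with zero barcode-bearing support).
#' @param cells Cell table: one row per barcode with at least `barcode`;
#'   typically also `sample_id`, `cluster_id`, `condition`, `malignancy`,
#'   `cell_label`. Duplicate barcodes are an error.
#' @param dedup When `TRUE`, evidence with the same barcode and identical
#'   breakpoints is counted once (fragment-level deduplication); default
#'   counts evidence reads.
#' @return An object of class `ecc_matrix`: a list with `counts` (sparse
#'   dgCMatrix, calls x cells), `row_meta` (the calls), `col_meta` (the
#'   cell table), and `n_excluded` (evidence records dropped for missing
#'   or unknown barcodes).
#' @export
build_matrix <- function(evidence, calls, cells, dedup = FALSE) {
  if (!"barcode" %in% names(cells)) abort("cell table needs a barcode column")
  if (anyDuplicated(cells$barcode)) {
    abort("duplicate barcodes in cell table")
  }
  ev <- evidence
  if (dedup) {
    ev <- distinct(ev, .data$call_id, .data$barcode, .data$left_bp,
                   .data$right_bp, .keep_all = TRUE)
  }
  known <- !is.na(ev$barcode) & ev$barcode %in% cells$barcode
  n_excluded <- sum(!known)
  ev <- ev[known, ]
  i <- match(ev$call_id, calls$call_id)
  j <- match(ev$barcode, cells$barcode)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(calls), nrow(cells)),
    dimnames = list(calls$call_id, cells$barcode)
  )
  structure(list(
    counts = counts,
    row_meta = select(calls, -dplyr::any_of("evidence")),
    col_meta = as_tibble(cells),
    n_excluded = n_excluded
  ), class = "ecc_matrix")
}

#' @export
print.ecc_matrix <- function(x, ...) {
  cat(sprintf("<ecc_matrix> %d eccDNA call(s) x %d cell(s), %d nonzero, %d evidence excluded\n",
              nrow(x$counts), ncol(x$counts),
              Matrix::nnzero(x$counts), x$n_excluded))
  invisible(x)
}

#' @export
dim.ecc_matrix <- function(x) dim(x$counts)

#' Fraction of cells harboring eccDNA
#'
#' A cell harbors eccDNA iff its column sum in the count matrix is at least
#' one. Fractions are reported per group as percentages with two decimals;
#' empty groups yield a missing fraction.
#'
#' @param mat An [build_matrix()] `ecc_matrix`.
#' @param group_by Column of the cell table to group by (default
#'   `"sample_id"`; use `NULL` for a single overall group).
#' @return A tibble: `group`, `n_cells`, `n_harboring`, `fraction`
#'   (percent, rounded to 2 decimals).
#' @export
harboring_fraction <- function(mat, group_by = "sample_id") {
  stopifnot(inherits(mat, "ecc_matrix"))
  harbors <- Matrix::colSums(mat$counts) >= 1
  grp <- if (is.null(group_by) || !group_by %in% names(mat$col_meta)) {
    rep("all", ncol(mat$counts))
  } else {
    as.character(mat$col_meta[[group_by]])
  }
  tibble(group = grp, harbors = harbors) |>
    group_by(.data$group) |>
    summarise(
      n_cells = n(),
      n_harboring = sum(.data$harbors),
      fraction = ifelse(n() == 0, NA_real_,
                        round(100 * sum(.data$harbors) / n(), 2))
    ) |>
    ungroup()
}

#' Read or write an eccDNA-by-cell matrix
#'
#' Serialises an `ecc_matrix` as a Matrix Market triplet file plus two TSV
#' metadata tables (`matrix.mtx`, `rows.tsv`, `cols.tsv`); a read of a
#' written matrix reproduces counts and metadata exactly.
#'
#' @param x For `direction = "write"`, the `ecc_matrix`; ignored for reads.
#' @param path Directory holding the three files.
#' @param direction `"write"` or `"read"`.
#' @return The directory (write) or the reconstructed `ecc_matrix` (read).
#' @export
io_matrix <- function(x = NULL, path, direction = c("write", "read")) {
  direction <- match.arg(direction)
  if (direction == "write") {
    stopifnot(inherits(x, "ecc_matrix"))
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    readr::write_tsv(x$row_meta, file.path(path, "rows.tsv"))
    readr::write_tsv(x$col_meta, file.path(path, "cols.tsv"))
    invisible(path)
  } else {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) abort(sprintf("no matrix.mtx under %s", path))
    counts <- tryCatch(
      methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                  "CsparseMatrix"),
      error = function(e) abort(sprintf("corrupt Matrix Market file: %s",
                                        conditionMessage(e))))
    row_meta <- readr::read_tsv(file.path(path, "rows.tsv"),
                                show_col_types = FALSE)
    col_meta <- readr::read_tsv(file.path(path, "cols.tsv"),
                                show_col_types = FALSE)
    if (nrow(row_meta) != nrow(counts) || nrow(col_meta) != ncol(counts)) {
      abort("matrix dimensions do not match rows.tsv/cols.tsv")
    }
    dimnames(counts) <- list(row_meta$call_id, col_meta$barcode)
    structure(list(counts = counts, row_meta = row_meta,
                   col_meta = col_meta, n_excluded = NA_integer_),
              class = "ecc_matrix")
  }
}

#' Read a cell metadata table
#'
#' Loads a TSV of per-cell metadata (barcode, sample_id, cluster_id,
#' condition, malignancy, cell_label) and validates the closed
#' vocabularies used by the group comparisons.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cell_table <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!"barcode" %in% names(cells)) abort("cell table needs a barcode column")
  if ("condition" %in% names(cells)) {
    bad <- setdiff(unique(cells$condition), c("adult", "pediatric", NA))
    if (length(bad)) abort(sprintf("unknown condition value(s): %s",
                                   paste(bad, collapse = ", ")))
  }
  if ("malignancy" %in% names(cells)) {
    bad <- setdiff(unique(cells$malignancy),
                   c("malignant", "malignant_mixed", "normal", NA))
    if (length(bad)) abort(sprintf("unknown malignancy value(s): %s",
                                   paste(bad, collapse = ", ")))
  }
  cells
}
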