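# Internal helpers shared across modules. Intervals are carried in tibbles
# with chrom/start/end columns, 0-based half-open; GRanges (1-based closed)
# is used only transiently for overlap machinery.

# tibble(chrom,start,end) -> GRanges; start0 is 0-based half-open
as_granges0 <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tbl0 <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
}

check_interval_tbl <- function(x, what = "interval table") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: start must be < end (first offending row: %d)",
                  what, bad[1]))
  }
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 16807) %% 2147483647
}
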