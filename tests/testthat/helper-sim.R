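# Shared small simulation used by the caller/quant/coverage tests; built
# once per test run and cached.
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    dir <- file.path(tempdir(), "sceccdna_shared_sim")
    cfg <- sim_config(
      n_chromosomes = 2, chrom_lengths = c(80000, 60000),
      n_circles = 2, circle_span_range = c(2000, 4000),
      n_cells = 300, presence_prob = 0.25,
      reads_per_cell = 60, circle_read_fraction = 0.4, seed = 42
    )
    .sim_cache$sim <- simulate_eccdna_reads(cfg, dir)
    .sim_cache$cfg <- cfg
    .sim_cache$dir <- dir
  }
  list(sim = .sim_cache$sim, cfg = .sim_cache$cfg, dir = .sim_cache$dir)
}

# write hand-crafted alignment records to an indexed BAM; records is a
# data frame with qname, flag, chrom, pos0 (0-based), cigar, and optionally
# mpos0, tlen, seq, cb
write_test_bam <- function(records, chrom_lengths, dir = tempdir(),
                           prefix = "handmade") {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  seq <- records$seq %||% strrep("A", 50)
  qual <- strrep("I", nchar(seq))
  lines <- paste(records$qname, records$flag, records$chrom,
                 as.integer(records$pos0 + 1), 60, records$cigar, "=",
                 as.integer((records$mpos0 %||% records$pos0) + 1),
                 as.integer(records$tlen %||% 0), seq, qual,
                 sep = "\t")
  if (!is.null(records$cb)) {
    lines <- paste(lines, paste0("CB:Z:", records$cb), sep = "\t")
  }
  sam <- file.path(dir, paste0(prefix, ".sam"))
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a
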