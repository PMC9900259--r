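test_that("genome generation is deterministic and seed-sensitive", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths = c(10000, 5000),
                    n_circles = 0, n_cells = 10, seed = 1)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  g1 <- generate_genome(cfg, f1)
  g2 <- generate_genome(cfg, f2)
  expect_equal(Biostrings::width(g1), c(10000, 5000))
  expect_true(all(strsplit(as.character(g1[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  cfg2 <- sim_config(n_chromosomes = 2, chrom_lengths = c(10000, 5000),
                     n_circles = 0, n_cells = 10, seed = 2)
  g3 <- generate_genome(cfg2)
  expect_gt(sum(strsplit(as.character(g1[[1]]), "")[[1]] !=
                  strsplit(as.character(g3[[1]]), "")[[1]]), 0)
  expect_error(sim_config(chrom_lengths = c(0, 100)), "positive")
})

test_that("circle placement respects spans, disjointness, and feasibility", {
  cfg0 <- sim_config(n_chromosomes = 1, chrom_lengths = 50000, n_circles = 0,
                     n_cells = 10)
  g <- generate_genome(cfg0)
  expect_equal(nrow(plant_circles(g, cfg0)$circles), 0)

  cfg3 <- sim_config(n_chromosomes = 1, chrom_lengths = 50000, n_circles = 3,
                     circle_span_range = c(500, 2000), n_cells = 10, seed = 5)
  tr <- plant_circles(generate_genome(cfg3), cfg3)
  spans <- tr$circles$end - tr$circles$start
  expect_true(all(spans >= 500 & spans <= 2000))
  expect_true(all(tr$circles$end <= 50000))
  srt <- tr$circles[order(tr$circles$start), ]
  expect_true(all(srt$start[-1] >= srt$end[-nrow(srt)]))

  cfg_bad <- sim_config(n_chromosomes = 1, chrom_lengths = 50000,
                        n_circles = 1, circle_span_range = c(60000, 60000),
                        n_cells = 10)
  expect_error(plant_circles(generate_genome(cfg_bad), cfg_bad),
               "does not fit")
})

test_that("cell-circle assignment matches the configured presence probability", {
  base <- function(p, n_cells, seed = 3) {
    cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 50000, n_circles = 1,
                      circle_span_range = c(1000, 2000), n_cells = n_cells,
                      cell_types = "T", presence_prob = p, seed = seed)
    g <- generate_genome(cfg)
    assign_cell_profiles(plant_circles(g, cfg), cfg)
  }
  expect_equal(nrow(base(0, 200)$assignments), 0)
  expect_equal(nrow(base(1, 1000)$assignments), 1000)
  tr <- base(0.10, 2000)
  frac <- length(unique(tr$assignments$barcode)) / 2000
  ci <- qnorm(0.995) * sqrt(0.1 * 0.9 / 2000)
  expect_true(abs(frac - 0.10) <= ci)
  expect_error(sim_config(cell_types = c("T", "B"),
                          presence_prob = c(T = 0.1)),
               "missing cell type")
})

test_that("junction-crossing fraction follows the (f-1)/L closed form", {
  # fixed-length fragments so the closed form applies exactly
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 50000, n_circles = 1,
                    circle_span_range = c(5000, 5000), n_cells = 200,
                    cell_types = "T", presence_prob = 1,
                    reads_per_cell = 100, circle_read_fraction = 0.8,
                    fragment_mean = 250, fragment_sd = 0, seed = 9)
  g <- generate_genome(cfg)
  tr <- assign_cell_profiles(plant_circles(g, cfg), cfg)
  fr <- simulate_fragments(tr, cfg)
  circ <- fr[fr$source == "circle", ]
  expect_gt(nrow(circ), 10000)
  expect_true(all(fr$length >= cfg$read_length))
  p_expected <- (250 - 1) / 5000
  p_obs <- mean(circ$junction)
  se <- sqrt(p_expected * (1 - p_expected) / nrow(circ))
  expect_true(abs(p_obs - p_expected) <= 3 * se)
  # cells without circles only produce linear fragments
  no_circle_cells <- setdiff(tr$cells$barcode, tr$assignments$barcode)
  expect_true(all(fr$source[fr$barcode %in% no_circle_cells] == "linear"))
})

test_that("circle-free runs emit no junction-like alignments", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 30000, n_circles = 0,
                    n_cells = 50, reads_per_cell = 40, seed = 2)
  out <- simulate_eccdna_reads(cfg, file.path(tempdir(), "sim_nocircle"))
  res <- Rsamtools::scanBam(out$files$bam,
                            param = Rsamtools::ScanBamParam(what = "flag"))[[1]]
  expect_equal(sum(bitwAnd(res$flag, 2048L) > 0), 0)   # no supplementary
  expect_true(all(bitwAnd(res$flag, 2L) > 0))          # all properly paired
})

test_that("a junction-crossing read is written as the forced split geometry", {
  # circle [10000, 15000); fragment wraps with the junction 30 bp before
  # read 1's end -> primary ends at 15000 with a 30 bp soft clip and the
  # supplementary starts at 10000 on the same strand
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 30000, n_circles = 1,
                    circle_span_range = c(5000, 5000), n_cells = 1,
                    cell_types = "T", presence_prob = 1, read_length = 80,
                    fragment_mean = 250, seed = 4)
  g <- generate_genome(cfg)
  truth <- structure(list(
    circles = tibble::tibble(circle_id = 1L, chrom = "chr1",
                             start = 10000, end = 15000),
    cells = tibble::tibble(barcode = "BC00001", cell_type = "T"),
    assignments = tibble::tibble(barcode = "BC00001", circle_id = 1L),
    seed = 4L), class = "sim_truth")
  frag <- tibble::tibble(
    fragment_id = "frag0000001", barcode = "BC00001", cell_type = "T",
    source = "circle", circle_id = 1L, chrom = "chr1",
    start = 10000 + 4950, offset = 4950, length = 250, junction = TRUE
  )
  dir <- file.path(tempdir(), "sim_forced")
  out <- emit_reads(frag, truth, g, cfg, dir, prefix = "forced")
  expect_equal(out$counters$n_split_pairs, 1)
  res <- Rsamtools::scanBam(
    out$files$bam,
    param = Rsamtools::ScanBamParam(what = c("flag", "pos", "cigar"),
                                    tag = "SA"))[[1]]
  prim <- which(bitwAnd(res$flag, 2048L) == 0 & bitwAnd(res$flag, 64L) > 0)
  expect_equal(res$cigar[prim], "50M30S")
  expect_equal(res$pos[prim] - 1 + 50, 15000)  # alignment ends at circle end
  supp <- which(bitwAnd(res$flag, 2048L) > 0)
  expect_equal(res$pos[supp] - 1, 10000)       # supplementary at circle start
  expect_equal(res$cigar[supp], "50S30M")
  # both on the forward strand
  expect_equal(bitwAnd(res$flag[prim], 16L), 0)
  expect_equal(bitwAnd(res$flag[supp], 16L), 0)
})

test_that("emission conserves junction geometry and matches the reference", {
  s <- shared_sim()
  fr <- s$sim$fragments
  expect_equal(sum(fr$junction, na.rm = TRUE),
               s$sim$counters$n_split_pairs +
                 s$sim$counters$n_discordant_pairs)
  # BAM records re-validate against the FASTA: fully matched reads carry
  # the reference bases at their alignment
  res <- Rsamtools::scanBam(
    s$sim$files$bam,
    param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "cigar", "seq", "strand")))[[1]]
  full <- which(res$cigar == paste0(s$cfg$read_length, "M"))
  pick <- full[seq(1, length(full), length.out = 50)]
  genome <- s$sim$genome
  for (i in pick) {
    ref <- substring(as.character(genome[[as.character(res$rname[i])]]),
                     res$pos[i], res$pos[i] + s$cfg$read_length - 1)
    obs <- as.character(res$seq[i])
    if (as.character(res$strand[i]) == "-") {
      obs <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(obs)))
    }
    expect_equal(obs, ref)
  }
})

test_that("fastq mode writes barcode-suffixed read names, deterministically", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 20000, n_circles = 1,
                    circle_span_range = c(2000, 3000), n_cells = 20,
                    presence_prob = 0.5, reads_per_cell = 20, seed = 6)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  o1 <- simulate_eccdna_reads(cfg, d1, mode = "fastq")
  o2 <- simulate_eccdna_reads(cfg, d2, mode = "fastq")
  r1 <- readLines(o1$files$fastq_r1)
  expect_true(grepl("^@frag\\d+_CB:BC\\d+/1$", r1[1]))
  expect_identical(r1, readLines(o2$files$fastq_r1))
  expect_identical(readLines(o1$files$fastq_r2), readLines(o2$files$fastq_r2))
  expect_error(
    emit_reads(o1$fragments, o1$truth, o1$genome, cfg, d1, mode = "sam"),
    "'arg' should be one of")
})
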