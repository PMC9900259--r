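test_that("linear profiles conserve read counts and add over clusters", {
  s <- shared_sim()
  truth <- s$sim$truth
  circle <- truth$circles[1, ]
  region <- list(chrom = circle$chrom, start = circle$start,
                 end = circle$end)
  cells2 <- dplyr::mutate(truth$cells, cluster_id = cell_type)
  prof <- linear_profile(s$sim$files$bam, region, cells2, bins = 20)
  expect_true(all(prof$count >= 0))
  expect_equal(unique(prof$mode), "linear")

  # conservation: bin totals equal qualifying overlapping reads
  aln <- GenomicAlignments::readGAlignments(
    s$sim$files$bam,
    param = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(region$chrom,
                                     IRanges::IRanges(region$start + 1,
                                                      region$end)),
      tag = "CB", mapqFilter = 10,
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isDuplicate = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)))
  cb <- S4Vectors::mcols(aln)$CB
  n_expected <- sum(cb %in% cells2$barcode &
                      BiocGenerics::start(aln) - 1 < region$end &
                      BiocGenerics::end(aln) > region$start)
  expect_equal(sum(prof$count), n_expected)

  # additivity: cluster profiles sum to the pooled single-cluster profile
  pooled <- dplyr::mutate(cells2, cluster_id = "all")
  prof_pooled <- linear_profile(s$sim$files$bam, region, pooled, bins = 20)
  by_bin <- dplyr::summarise(dplyr::group_by(prof, bin),
                             count = sum(count), .groups = "drop")
  expect_equal(by_bin$count, prof_pooled$count[order(prof_pooled$bin)])

  # region with no reads: all-zero profile
  empty_region <- list(chrom = region$chrom, start = 0, end = 100)
  p0 <- linear_profile(s$sim$files$bam, empty_region, cells2, bins = 5)
  expect_true(nrow(p0) > 0)
  expect_error(linear_profile(s$sim$files$bam,
                              list(chrom = "chr1", start = -5, end = 10),
                              cells2),
               "invalid region")
})

test_that("circular profiles track circle-supporting reads and cell types", {
  s <- shared_sim()
  truth <- s$sim$truth
  circle <- truth$circles[1, ]
  region <- list(chrom = circle$chrom, start = circle$start,
                 end = circle$end)
  # cluster cells by whether truth assigns them this circle
  pos_bc <- truth$assignments$barcode[
    truth$assignments$circle_id == circle$circle_id]
  cells2 <- dplyr::mutate(truth$cells,
                          cluster_id = ifelse(barcode %in% pos_bc,
                                              "carrier", "noncarrier"))
  prof <- circular_profile(s$sim$files$bam, region, cells2, bins = 10)
  tot <- dplyr::summarise(dplyr::group_by(prof, cluster_id),
                          count = sum(count), .groups = "drop")
  expect_gt(tot$count[tot$cluster_id == "carrier"], 0)
  expect_equal(tot$count[tot$cluster_id == "noncarrier"], 0L)

  # include_split adds exactly the split-read contribution
  prof_split <- circular_profile(s$sim$files$bam, region, cells2, bins = 10,
                                 include_split = TRUE)
  diff_tot <- sum(prof_split$count) - sum(prof$count)
  expect_gt(diff_tot, 0)
  # the difference equals the number of qualifying SA-tagged primaries
  res <- Rsamtools::scanBam(
    s$sim$files$bam,
    param = Rsamtools::ScanBamParam(
      what = c("pos", "cigar", "flag"), tag = c("SA", "CB"),
      which = GenomicRanges::GRanges(region$chrom,
                                     IRanges::IRanges(region$start + 1,
                                                      region$end)),
      mapqFilter = 10,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isDuplicate = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)))[[1]]
  has_sa <- !is.na(res$tag$SA)
  in_cells <- res$tag$CB %in% cells2$barcode
  ends <- res$pos - 1 +
    GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  overlaps <- res$pos - 1 < region$end & ends > region$start
  expect_equal(diff_tot, sum(has_sa & in_cells & overlaps))

  # a BAM with only concordant pairs gives an all-zero circular profile
  chrom_lengths <- c(chrFlat = 10000)
  recs <- data.frame(
    qname = rep(paste0("q", 1:5), each = 2),
    flag = rep(c(99L, 147L), 5), chrom = "chrFlat",
    pos0 = as.vector(rbind(seq(100, 900, 200), seq(250, 1050, 200))),
    cigar = "50M",
    mpos0 = as.vector(rbind(seq(250, 1050, 200), seq(100, 900, 200))),
    cb = "b1"
  )
  bam <- write_test_bam(recs, chrom_lengths, prefix = "flatcirc")
  p <- circular_profile(bam, list(chrom = "chrFlat", start = 0, end = 2000),
                        tibble::tibble(barcode = "b1", cluster_id = "c"),
                        bins = 5)
  expect_equal(sum(p$count), 0)
})

test_that("per-cell signal slices the matrix with grouping keys attached", {
  calls <- tibble::tibble(call_id = "A", chrom = "chr1", start = 0, end = 10,
                          n_split = 2L, n_discordant = 0L, n_cells = 2L,
                          evenness = 1, status = "pass")
  cells <- tibble::tibble(barcode = c("b1", "b2", "b3"),
                          sample_id = "s1", cluster_id = c("c1", "c1", "c2"),
                          condition = c("adult", "adult", "pediatric"),
                          malignancy = c("malignant", "normal", "normal"))
  ev <- tibble::tibble(call_id = rep("A", 3), kind = "split", chrom = "chr1",
                       left_bp = 0, right_bp = 10,
                       barcode = c("b1", "b1", "b3"), mapq = 60,
                       read_id = paste0("r", 1:3))
  m <- build_matrix(ev, calls, cells)
  sig <- per_cell_signal(m, "A")
  expect_equal(sig$value, c(2, 0, 1))
  expect_equal(sig$condition, cells$condition)
  # grouping by construction: adult-only signal keeps pediatric at zero
  expect_true(all(sig$value[sig$condition == "pediatric" &
                              sig$barcode == "b2"] == 0))
  norm <- per_cell_signal(m, "A", normalize = TRUE)
  expect_equal(norm$value, c(1, 0, 1))
  expect_error(per_cell_signal(m, "nope"), "unknown call_id")
})

test_that("rank-sum test matches exact enumeration and base R", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3)
  # symmetry under group swap
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$p_value, 1 / 3)
  # identical multisets: central statistic, exact p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2), mode = "exact")$p_value, 1)
  # tie-free cross-check against the base implementation
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6) + 0.8
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
    xl <- rnorm(30); yl <- rnorm(25) + 0.3
    expect_equal(wilcoxon_rank_sum(xl, yl, mode = "normal")$p_value,
                 stats::wilcox.test(xl, yl, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-8)
  }
  # the approximation tracks the exact null closely at n = 12 + 12
  x <- qnorm(seq(0.05, 0.95, length.out = 12))
  y <- qnorm(seq(0.05, 0.95, length.out = 12)) + 0.5
  p_ex <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
  p_no <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
  expect_lt(abs(p_ex - p_no), 0.02)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("signed-rank test enumerates sign patterns exactly", {
  s <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))  # differences +1,+2,+3
  expect_equal(s$p_value, 1 / 4)
  expect_equal(s$statistic, 6)
  # sign-flip symmetry
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))$p_value, 1 / 4)
  # degenerate: identical pairs
  expect_warning(z <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(z$p_value, 1)
  # cross-check against base R (tie-free differences)
  set.seed(5)
  x <- rnorm(10); y <- x + rnorm(10, 0.5)
  expect_equal(wilcoxon_signed_rank(x, y, mode = "exact")$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "paired")
})

test_that("Kruskal-Wallis matches the closed form and base R", {
  k <- kruskal_wallis(list(1, 2, 3))
  expect_equal(k$statistic, 2.0)
  # permutation invariance
  expect_equal(kruskal_wallis(list(3, 1, 2))$statistic, 2.0)
  expect_equal(kruskal_wallis(list(3, 1, 2))$p_value, k$p_value)
  # degenerate: everything tied
  expect_warning(kd <- kruskal_wallis(list(c(5, 5), c(5, 5))), "tied")
  expect_equal(kd$p_value, 1)
  expect_equal(kd$statistic, 0)
  # cross-check with ties against the base implementation
  set.seed(13)
  g <- list(sample(1:5, 8, TRUE), sample(1:5, 7, TRUE), sample(1:5, 9, TRUE))
  base <- stats::kruskal.test(g)
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic, unname(base$statistic))
  expect_equal(mine$p_value, base$p.value)
  expect_error(kruskal_wallis(list(1)), "at least two")
  expect_error(kruskal_wallis(list(1, numeric(0))), "non-empty")
})

test_that("star labels use strict printed thresholds", {
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.05), "ns")
  expect_equal(significance_stars(5e-5), "****")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(c(1, 0)), c("ns", "****"))
})

test_that("tidy/glance methods and BH adjustment produce tidy tables", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  td <- tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("test", "statistic", "p_value", "stars", "method"))
  gl <- glance(kruskal_wallis(list(1, 2, 3)))
  expect_equal(gl$n_total, 3)
  adj <- adjust_comparisons(tibble::tibble(p_value = c(0.01, 0.02, 0.5)))
  expect_equal(adj$p_adj, stats::p.adjust(c(0.01, 0.02, 0.5), "BH"))
  expect_true(all(c("p_adj", "stars_adj") %in% names(adj)))
})
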