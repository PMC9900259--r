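# Nonparametric group comparisons. The exact modes enumerate the null
# directly (all C(n, nx) group labelings for the rank sum; all 2^n sign
# patterns for the signed rank), which handles ties without falling back
# to an approximation; the normal modes use the tie-corrected variance
# with a continuity correction. Two-sided p-values throughout.

new_ecc_htest <- function(test, statistic, p_value, n_per_group,
                          method_detail, note = NA_character_) {
  structure(list(
    test = test,
    statistic = statistic,
    p_value = p_value,
    n_per_group = n_per_group,
    stars = significance_stars(p_value),
    method_detail = method_detail,
    note = note
  ), class = "ecc_htest")
}

#' @export
print.ecc_htest <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s), n = %s [%s]\n",
              x$test, x$statistic, x$p_value, x$stars,
              paste(x$n_per_group, collapse = "/"), x$method_detail))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy ecc_htest
#' @export
tidy.ecc_htest <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         stars = x$stars, method = x$method_detail)
}

#' Tidiers for group-comparison results
#'
#' broom-style [generics::tidy()] and [generics::glance()] methods for the
#' `ecc_htest` objects returned by [wilcoxon_rank_sum()],
#' [wilcoxon_signed_rank()] and [kruskal_wallis()].
#'
#' @param x An `ecc_htest` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name tidiers
#' @method glance ecc_htest
#' @export
glance.ecc_htest <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x),
    tibble(n_total = sum(x$n_per_group), n_groups = length(x$n_per_group))
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent groups. In exact mode the null
#' distribution of the rank sum of `x` is enumerated over all
#' `choose(nx + ny, nx)` group labelings of the pooled sample (midranks,
#' so ties are handled exactly); in normal mode a tie-corrected normal
#' approximation with continuity correction is used. `auto` switches to
#' the approximation above a combined n of 12.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return An `ecc_htest` with the rank-sum statistic W (sum of `x` ranks),
#'   two-sided p, group sizes and a significance star label.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && n <= 12)
  note <- NA_character_
  if (use_exact) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    detail <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      note <- "all observations tied; p reported as 1"
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    detail <- "normal approximation, tie + continuity correction"
  }
  new_ecc_htest("wilcoxon_rank_sum", w, p, c(nx, ny), detail, note)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' dropped (and counted in the result's note). Exact enumeration of all
#' sign patterns is used for up to 12 remaining pairs, otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return An `ecc_htest` with the signed-rank statistic V (sum of ranks of
#'   positive differences) and two-sided p.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p reported as 1")
    return(new_ecc_htest("wilcoxon_signed_rank", 0, 1, c(0, 0),
                         "degenerate", "all differences zero"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  note <- if (n_zero > 0) sprintf("%d zero difference(s) dropped", n_zero)
          else NA_character_
  use_exact <- mode == "exact" || (mode == "auto" && n <= 12)
  if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.numeric(signs %*% r)
    p <- mean(abs(sums - mu) >= abs(v - mu) - 1e-9)
    detail <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
      note <- "all differences tied; p reported as 1"
    } else {
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    detail <- "normal approximation, tie + continuity correction"
  }
  new_ecc_htest("wilcoxon_signed_rank", v, p, c(n, n), detail, note)
}

#' Kruskal-Wallis test
#'
#' Tests whether two or more groups originate from the same distribution.
#' The H statistic uses midranks and the standard tie correction; p comes
#' from the chi-square reference with k - 1 degrees of freedom.
#'
#' @param groups A list of non-empty numeric vectors (two or more).
#' @return An `ecc_htest` with H and p.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("kruskal_wallis needs a list of at least two groups")
  }
  if (any(lengths(groups) == 0)) abort("all groups must be non-empty")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  n <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_len(k), n_i)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(n_i * (rbar - (n + 1) / 2)^2)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  note <- NA_character_
  if (corr <= 0) {
    h <- 0
    p <- 1
    warn("all observations are tied; p reported as 1")
    note <- "all observations tied"
  } else {
    h <- h / corr
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  new_ecc_htest("kruskal_wallis", h, p, as.integer(n_i),
                sprintf("chi-square reference, df = %d", k - 1), note)
}

#' Significance star labels
#'
#' Maps p-values to the conventional star key with strict inequalities:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Benjamini-Hochberg adjustment for a table of comparisons
#'
#' Optional multiple-testing correction for catalogue-wide scans; adds
#' `p_adj` and `stars_adj` columns to a tidy comparison table.
#'
#' @param comparisons Tibble with a `p_value` column.
#' @return The table with `p_adj` (BH) and `stars_adj` added.
#' @export
adjust_comparisons <- function(comparisons) {
  stopifnot("p_value" %in% names(comparisons))
  comparisons$p_adj <- stats::p.adjust(comparisons$p_value, method = "BH")
  comparisons$stars_adj <- significance_stars(comparisons$p_adj)
  comparisons
}
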