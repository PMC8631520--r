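#' Pearson chi-square test for a 2 x K findings table
#'
#' Pearson's chi-square *without* continuity correction — the convention
#' under which the recomputable published contingency rows (cyst wall,
#' cystic component, T2 signal, T1 hyperintensity) reproduce their printed
#' p-values; with the Yates correction they do not. For 2 x 2 tables
#' Fisher's exact test is available via [fisher_exact_2x2()].
#'
#' @param counts nonnegative integer matrix with 2 rows (classes) and K
#'   columns (finding categories).
#' @return list: `statistic`, `df`, `p`, `expected`.
#' @examples
#' chi_square_2xk(matrix(c(17, 7, 5, 11), 2))   # p = 0.014
#' @export
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2)
    stop("`counts` must be a 2 x K table with K >= 2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must hold nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("undefined: degenerate margins (empty row or column)", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Fisher's exact test for a 2 x 2 findings table
#' @param counts 2 x 2 nonnegative integer matrix.
#' @return list: `p` (two-sided), `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("`counts` must be 2 x 2", call. = FALSE)
  ht <- stats::fisher.test(counts)
  list(p = ht$p.value, odds_ratio = unname(ht$estimate))
}
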