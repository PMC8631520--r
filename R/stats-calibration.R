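#' Hosmer–Lemeshow goodness-of-fit test
#'
#' Lesions are sorted by predicted probability and divided into
#' `n_groups` equal-count "decile of risk" groups, keeping tied
#' probabilities in the same group. The statistic is
#' \deqn{\chi^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' over the groups (observed vs expected positives), compared against a
#' chi-square with `G - 2` degrees of freedom, G the number of groups
#' actually formed. A group whose expected count is 0 (or equal to its
#' size, the mirrored degeneracy) is merged with its neighbor.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary 0/1 outcomes.
#' @param n_groups target number of risk groups (default 10).
#' @return list: `statistic`, `df`, `p`, `groups` (data frame `n`,
#'   `observed`, `expected`).
#' @export
hosmer_lemeshow <- function(probs, labels, n_groups = 10) {
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1),
            all(probs > 0 & probs < 1))
  n <- length(probs)
  if (n < 2 * n_groups)
    warning("fewer than 2 lesions per risk group on average", call. = FALSE)
  qs <- unique(stats::quantile(probs, seq(0, 1, length.out = n_groups + 1),
                               type = 2))
  if (length(qs) < 2) {
    grp <- rep(1L, n)
  } else {
    grp <- cut(probs, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  g <- stats::aggregate(cbind(n = rep(1, n), observed = labels,
                              expected = probs),
                        by = list(group = grp), FUN = sum)
  # merge degenerate groups (expected 0 or expected == size) into a neighbor
  repeat {
    bad <- which(g$expected <= 0 | g$expected >= g$n)
    bad <- bad[g$n[bad] > 0]
    if (!length(bad) || nrow(g) == 1) break
    i <- bad[1]
    j <- if (i == nrow(g)) i - 1 else i + 1
    g[j, c("n", "observed", "expected")] <-
      g[j, c("n", "observed", "expected")] + g[i, c("n", "observed", "expected")]
    g <- g[-i, , drop = FALSE]
  }
  denom <- g$expected * (1 - g$expected / g$n)
  ok <- denom > 0
  stat <- sum((g$observed[ok] - g$expected[ok])^2 / denom[ok])
  df <- max(nrow(g) - 2, 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = g[, c("n", "observed", "expected")])
}
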