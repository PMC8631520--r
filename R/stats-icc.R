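#' Inter-observer intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' classical ANOVA decomposition of an n-lesion x k-rater table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the between-lesion,
#' between-rater and residual mean squares. The value is banded with the
#' conventional agreement labels (upper bound closed):
#' 0–0.200 poor, 0.201–0.400 fair, 0.401–0.600 moderate,
#' 0.601–0.800 good, 0.801–1.000 excellent.
#'
#' @param ratings numeric matrix or data frame, lesions in rows, the two
#'   (or more) raters in columns; no missing cells.
#' @return list: `icc`, `band`, `ms` (the three mean squares),
#'   `degenerate` (`TRUE` when between-lesion variance is zero, in which
#'   case `icc` is 0).
#' @examples
#' r <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.0, 2.9, 4.2))
#' icc_interobserver(r)
#' @export
icc_interobserver <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    stop("need >= 3 lesions and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || (msr == mse && mse == 0)) {
    return(list(icc = 0, band = icc_band(0),
                ms = c(MSR = msr, MSC = msc, MSE = mse), degenerate = TRUE))
  }
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom > 0) (msr - mse) / denom else 0
  deg <- stats::var(row_m) == 0
  if (deg) icc <- 0
  list(icc = icc, band = icc_band(icc),
       ms = c(MSR = msr, MSC = msc, MSE = mse), degenerate = deg)
}

icc_band <- function(icc) {
  v <- max(icc, 0)
  if (v <= 0.200) "poor"
  else if (v <= 0.400) "fair"
  else if (v <= 0.600) "moderate"
  else if (v <= 0.800) "good"
  else "excellent"
}
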