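#' First-order (gray-level histogram) features
#'
#' Nine statistics of the quantized gray-level distribution inside the VOI,
#' computed from the level histogram \eqn{g(k)}, \eqn{k = 1..N_g}:
#' \itemize{
#'   \item `Mean` \eqn{= \sum_k k\,g(k) / \sum_k g(k)} — average gray level.
#'   \item `Variance` — population variance (denominator Np) of the levels.
#'   \item `Skewness`, `Kurtosis` — standardized third moment and *excess*
#'     fourth moment (normal gives 0); both reported as 0 with an
#'     `undefined` attribute when the variance is 0.
#'   \item `Perc.q%` — the smallest level whose cumulative count reaches
#'     \eqn{q/100 \cdot Np}, for q in 1, 10, 50, 90, 99.
#' }
#'
#' @param q a [normalize_voi()] result (`quantized_voi`).
#' @return Named numeric vector of the 9 features. If the VOI has zero
#'   variance, attribute `undefined` lists the flagged names.
#' @examples
#' vox <- array(seq_len(27), dim = c(3, 3, 3))
#' msk <- array(TRUE, dim = c(3, 3, 3))
#' histogram_features(normalize_voi(voi_volume(vox, msk), 8))
#' @export
histogram_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  lv <- q$levels[!is.na(q$levels)]
  np <- length(lv)
  m <- mean(lv)
  v <- sum((lv - m)^2) / np
  undef <- character(0)
  if (v > 0) {
    s <- sum((lv - m)^3) / np / v^1.5
    k <- sum((lv - m)^4) / np / v^2 - 3
  } else {
    s <- 0; k <- 0
    undef <- c("Skewness", "Kurtosis")
  }
  cnt <- tabulate(lv, nbins = q$n_levels)
  cum <- cumsum(cnt)
  perc <- vapply(c(1, 10, 50, 90, 99) / 100,
                 function(f) which(cum >= f * np)[1], integer(1))
  out <- c(Mean = m, Variance = v, Skewness = s, Kurtosis = k,
           stats::setNames(as.numeric(perc),
                           c("Perc.01%", "Perc.10%", "Perc.50%",
                             "Perc.90%", "Perc.99%")))
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
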