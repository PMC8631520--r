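#' Absolute-gradient features
#'
#' Gradient magnitudes are computed by central differences on the quantized
#' gray levels, per axis \eqn{g_a = (L_{+1} - L_{-1})/2}, evaluated only at
#' VOI voxels whose six axis neighbors all lie inside the VOI (no padding
#' at the lesion boundary). The magnitude is
#' \eqn{\sqrt{g_1^2 + g_2^2 + g_3^2}}. Reported: mean, population variance,
#' skewness, excess kurtosis of the magnitudes, and `GrNonZeros`, the
#' fraction of evaluated voxels with nonzero magnitude.
#'
#' @param q a `quantized_voi`.
#' @return Named numeric vector of the 5 gradient features; all flagged
#'   undefined (attribute `undefined`, values 0) when the VOI has no
#'   interior voxel, and `GrSkewness`/`GrKurtosis` flagged when the
#'   magnitude variance is 0.
#' @export
gradient_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  g <- gradient_magnitudes(q)
  nms <- gradient_stat_names()
  if (length(g) == 0) {
    out <- stats::setNames(numeric(length(nms)), nms)
    attr(out, "undefined") <- nms
    return(out)
  }
  m <- mean(g)
  v <- sum((g - m)^2) / length(g)
  undef <- character(0)
  if (v > 0) {
    s <- sum((g - m)^3) / length(g) / v^1.5
    k <- sum((g - m)^4) / length(g) / v^2 - 3
  } else {
    s <- 0; k <- 0
    undef <- c("GrSkewness", "GrKurtosis")
  }
  out <- c(GrMean = m, GrVariance = v, GrSkewness = s, GrKurtosis = k,
           GrNonZeros = mean(g > 0))
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

# Central-difference gradient magnitudes at interior VOI voxels.
gradient_magnitudes <- function(q) {
  L <- q$levels
  d <- dim(L)
  if (any(d < 3L)) return(numeric(0))
  core <- function(s1, s2, s3) L[s1, s2, s3, drop = FALSE]
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  ctr <- core(i, j, k)
  g1 <- (core(i + 1, j, k) - core(i - 1, j, k)) / 2
  g2 <- (core(i, j + 1, k) - core(i, j - 1, k)) / 2
  g3 <- (core(i, j, k + 1) - core(i, j, k - 1)) / 2
  ok <- !is.na(ctr) & !is.na(g1) & !is.na(g2) & !is.na(g3)
  sqrt(g1[ok]^2 + g2[ok]^2 + g3[ok]^2)
}
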