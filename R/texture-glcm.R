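#' Build a gray-level co-occurrence matrix for one voxel offset
#'
#' Counts pairs of VOI voxels `(a, a + offset)` where *both* ends lie inside
#' the VOI (pairs are broken at non-VOI voxels, never padded), accumulates
#' both orders (Haralick's symmetric convention), and normalizes to a joint
#' probability matrix \eqn{p(i,j)} over the \eqn{N_g \times N_g} level pairs.
#'
#' @param q a `quantized_voi`.
#' @param offset integer 3-vector `(d_row, d_col, d_slice)`, not all zero.
#' @return Object of class `glcm`: list with `p` (Ng x Ng symmetric matrix
#'   summing to 1, or all zero when no valid pair exists), `offset`,
#'   `n_pairs` (symmetric pair count) and `empty` flag.
#' @export
build_glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_voi"))
  off <- as.integer(offset)
  if (length(off) != 3L || any(is.na(off)) || all(off == 0L))
    stop("`offset` must be a nonzero integer 3-vector", call. = FALSE)
  ng <- q$n_levels
  L <- q$levels
  d <- dim(L)
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  cnt <- matrix(0, ng, ng)
  if (all(lo <= hi)) {
    a <- L[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    b <- L[(lo[1] + off[1]):(hi[1] + off[1]),
           (lo[2] + off[2]):(hi[2] + off[2]),
           (lo[3] + off[3]):(hi[3] + off[3]), drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) {
      code <- (a[keep] - 1L) * ng + b[keep]
      cnt <- matrix(tabulate(code, nbins = ng * ng), ng, ng, byrow = TRUE)
      cnt <- cnt + t(cnt)
    }
  }
  n_pairs <- sum(cnt)
  p <- if (n_pairs > 0) cnt / n_pairs else cnt
  structure(list(p = p, offset = off, n_pairs = n_pairs,
                 empty = n_pairs == 0),
            class = "glcm")
}

# Haralick statistics from a normalized symmetric co-occurrence matrix,
# computed on the nonzero cells only. 0*log(0) is taken as 0 throughout.
glcm_stats_from_p <- function(p, ng) {
  nz <- which(p > 0)
  pv <- p[nz]
  i <- ((nz - 1L) %% ng) + 1L
  j <- ((nz - 1L) %/% ng) + 1L
  mu_x <- sum(i * pv)                       # symmetric: mu_x == mu_y
  var_x <- sum((i - mu_x)^2 * pv)
  dif <- abs(i - j)
  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1, via bincounts
  ps <- tabulate_weighted(i + j - 1L, pv, 2L * ng - 1L)   # index k-1
  ks <- seq(2L, 2L * ng)
  pd <- tabulate_weighted(dif + 1L, pv, ng)               # index |d|+1
  kd <- seq(0L, ng - 1L)
  sum_avg <- sum(ks * ps)
  dif_avg <- sum(kd * pd)
  correlat <- if (var_x > 0) (sum(i * j * pv) - mu_x * mu_x) / var_x else NA_real_
  c(AngScMom = sum(pv^2),
    Contrast = sum((i - j)^2 * pv),
    Correlat = correlat,
    SumOfSqs = var_x,
    InvDfMom = sum(pv / (1 + (i - j)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((ks - sum_avg)^2 * ps),
    SumEntrp = -sum(ps[ps > 0] * log(ps[ps > 0])),
    Entropy  = -sum(pv * log(pv)),
    DifVarnc = sum(kd^2 * pd) - dif_avg^2,
    DifEntrp = -sum(pd[pd > 0] * log(pd[pd > 0])))
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Haralick features of a co-occurrence matrix
#'
#' The eleven second-order statistics: angular second moment
#' \eqn{\sum p^2}, contrast \eqn{\sum (i-j)^2 p}, correlation, sum of
#' squares (marginal variance), inverse difference moment, sum
#' average/variance/entropy over \eqn{p_{x+y}}, entropy, and difference
#' variance/entropy over \eqn{p_{x-y}}. Natural logarithms are used in all
#' entropy features. `Correlat` is undefined (returned 0, flagged) when the
#' marginal variance is zero; an empty matrix flags every statistic.
#'
#' @param m a [build_glcm()] result.
#' @return Named numeric vector of 11 statistics; attribute `undefined`
#'   names the flagged entries, which are reported as 0.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  nms <- glcm_stat_names()
  if (m$empty) {
    out <- stats::setNames(numeric(length(nms)), nms)
    attr(out, "undefined") <- nms
    return(out)
  }
  out <- glcm_stats_from_p(m$p, nrow(m$p))[nms]
  undef <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
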