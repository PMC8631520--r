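#' AUC with DeLong confidence interval and Youden operating point
#'
#' The AUC is the Mann–Whitney two-sample estimator: the fraction of
#' (positive, negative) score pairs that are concordant, ties counting
#' one half. Its variance is estimated with DeLong's structural
#' components (placement values), and the 95% CI is built on the logit
#' scale so it respects \[0, 1\]; a degenerate AUC of exactly 0 or 1 gets
#' a collapsed CI. Sensitivity and specificity are reported at the
#' Youden-maximal threshold (largest sensitivity + specificity − 1;
#' ties broken toward the higher threshold, i.e. the more specific rule),
#' classifying `score >= threshold` as positive.
#'
#' @param scores numeric vector of per-lesion scores (higher = more
#'   malignant-like).
#' @param labels binary 0/1 vector; both classes must be present.
#' @param conf confidence level (default 0.95).
#' @param ci_scale `"logit"` (default) or `"normal"` for an untransformed
#'   Wald CI clipped to \[0, 1\].
#' @return Object of class `roc_result`: list with `auc`, `ci` (length 2),
#'   `se`, `sensitivity`, `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @examples
#' auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
auc_delong <- function(scores, labels, conf = 0.95, ci_scale = c("logit", "normal")) {
  ci_scale <- match.arg(ci_scale)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2)
    stop("undefined: both classes must be present", call. = FALSE)
  stopifnot(all(is.finite(scores)))
  x <- scores[labels == 1]; y <- scores[labels == 0]
  pl <- delong_placements(x, y)
  auc <- pl$auc
  var0 <- function(v) if (length(v) > 1) stats::var(v) else 0
  v <- var0(pl$v10) / length(x) + var0(pl$v01) / length(y)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci_scale == "logit" && auc > 0 && auc < 1 && se > 0) {
    lse <- se / (auc * (1 - auc))
    ci <- stats::plogis(stats::qlogis(auc) + c(-1, 1) * z * lse)
  } else {
    ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  }
  op <- youden_point(scores, labels)
  structure(list(auc = auc, ci = ci, se = se,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 threshold = op$threshold,
                 n_pos = length(x), n_neg = length(y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), sens %.3f, spec %.3f\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity))
  invisible(x)
}

# DeLong placement values: v10[i] = mean_j psi(x_i, y_j), psi = 1/0.5/0.
# Computed via midranks, O((m+n) log(m+n)).
delong_placements <- function(x, y) {
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

youden_point <- function(scores, labels, tol = 1e-12) {
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - tol)
  pick <- best[length(best)]   # highest threshold among maxima
  list(threshold = thr[pick], sensitivity = sens[pick], specificity = spec[pick])
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the *same* lesions,
#' using the covariance of their DeLong structural components. When the
#' two scores rank the lesions identically, the variance of the AUC
#' difference is 0 and the test degenerates: p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b numeric score vectors on the same lesions.
#' @param labels binary 0/1 vector.
#' @return list: `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`, `degenerate`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2)
    stop("undefined: both classes must be present", call. = FALSE)
  pos <- labels == 1
  pa <- delong_placements(scores_a[pos], scores_a[!pos])
  pb <- delong_placements(scores_b[pos], scores_b[!pos])
  m <- sum(pos); n <- sum(!pos)
  cov0 <- function(a, b) {
    if (length(a) > 1) stats::cov(cbind(a, b)) else matrix(0, 2, 2)
  }
  s10 <- cov0(pa$v10, pb$v10)
  s01 <- cov0(pa$v01, pb$v01)
  s <- s10 / m + s01 / n
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- pa$auc - pb$auc
  if (v <= 1e-16) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = 0,
                z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = sqrt(v),
       z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
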