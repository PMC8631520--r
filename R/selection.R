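#' Z-score standardization of a feature table
#'
#' Each feature column is centered and scaled to unit sample standard
#' deviation, removing the wildly different physical scales of the texture
#' families before model fitting. Zero-variance columns are flagged and
#' left unscaled. The per-column means and SDs are recorded so a fitted
#' model can be applied to new lesions on the same scale.
#'
#' @param x numeric data frame (features only, no id/label columns).
#' @return list: `table` (standardized data frame), `params` (data frame
#'   `feature`, `mean`, `sd`), `zero_variance` (character vector of flagged
#'   columns).
#' @export
standardize_features <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) >= 2)
  mu <- vapply(x, function(v) mean(v, na.rm = TRUE), numeric(1))
  sd_ <- vapply(x, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  zero <- names(x)[!is.na(sd_) & sd_ == 0]
  out <- x
  for (nm in names(x)) {
    if (!nm %in% zero && is.finite(sd_[[nm]]) && sd_[[nm]] > 0)
      out[[nm]] <- (x[[nm]] - mu[[nm]]) / sd_[[nm]]
  }
  list(table = out,
       params = data.frame(feature = names(x), mean = unname(mu),
                           sd = unname(sd_), stringsAsFactors = FALSE),
       zero_variance = zero)
}

#' Variance-threshold filter (cascade stage 1)
#'
#' Removes features whose variance on the raw (unstandardized) scale is
#' strictly smaller than the threshold. The default threshold is 0.8.
#' Features with any missing (undefined) value are removed here as well,
#' with their own reason, so later stages only see complete columns.
#'
#' @param x numeric feature data frame on the raw scale.
#' @param threshold nonnegative variance threshold; columns with
#'   `var < threshold` are dropped (strict inequality).
#' @return list: `table` (kept columns), `stage` (data frame `feature`,
#'   `variance`, `kept`, `reason`).
#' @export
variance_filter <- function(x, threshold = 0.8) {
  stopifnot(is.data.frame(x), threshold >= 0)
  v <- vapply(x, function(col) stats::var(col), numeric(1))
  has_na <- vapply(x, anyNA, logical(1))
  kept <- !has_na & !is.na(v) & v >= threshold
  reason <- ifelse(has_na, "undefined values",
                   ifelse(kept, "", sprintf("variance %.3g < %.3g", v, threshold)))
  stage <- data.frame(feature = names(x), variance = unname(v),
                      kept = unname(kept), reason = unname(reason),
                      stringsAsFactors = FALSE)
  if (!any(kept))
    warning("variance filter removed every feature", call. = FALSE)
  list(table = x[, kept, drop = FALSE], stage = stage)
}

# SPSS-style Levene test (mean-centered absolute deviations, one-way ANOVA).
levene_p <- function(x, g) {
  z <- abs(x - ave(x, g))
  if (stats::var(z) == 0) return(1)
  fit <- stats::aov(z ~ factor(g))
  summary(fit)[[1]][["Pr(>F)"]][1]
}

# Kolmogorov-Smirnov normality p against a normal with estimated moments.
ks_normal_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' Univariate two-group screen (cascade stage 2)
#'
#' For each feature, the two class distributions are compared with a test
#' chosen by the classical gate: if both groups pass Kolmogorov–Smirnov
#' normality (p > 0.05, against a normal with estimated moments) *and*
#' Levene's homogeneity-of-variance test passes (p > 0.05), a two-sided
#' pooled-variance t-test is used; otherwise the Mann–Whitney U test
#' (normal approximation with tie correction). Features with p < `alpha`
#' are kept. Features that are constant within both groups carry no
#' information and are dropped with a recorded reason.
#'
#' @param x numeric feature data frame.
#' @param labels binary vector (0/1), length `nrow(x)`; both classes need
#'   at least 3 lesions.
#' @param alpha significance level for retention (default 0.05).
#' @return list: `kept` (character), `stage` (data frame `feature`, `test`
#'   used, `statistic`, `p`, `kept`, `reason`).
#' @export
univariate_screen <- function(x, labels, alpha = 0.05) {
  stopifnot(is.data.frame(x), length(labels) == nrow(x),
            all(labels %in% 0:1))
  if (min(table(labels)) < 3)
    stop("both classes need >= 3 lesions", call. = FALSE)
  g0 <- labels == 0
  res <- lapply(names(x), function(nm) {
    a <- x[[nm]][g0]; b <- x[[nm]][!g0]
    if (stats::sd(c(a, b)) == 0 || (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                                    mean(a) == mean(b)))
      return(data.frame(feature = nm, test = "none", statistic = 0, p = 1,
                        kept = FALSE, reason = "degenerate (all tied)"))
    normal <- ks_normal_p(a) > 0.05 && ks_normal_p(b) > 0.05
    homo <- levene_p(c(a, b), labels) > 0.05
    if (normal && homo) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(feature = nm, test = "t", statistic = unname(tt$statistic),
                 p = tt$p.value, kept = tt$p.value < alpha, reason = "")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = FALSE))
      data.frame(feature = nm, test = "mann-whitney",
                 statistic = unname(wt$statistic),
                 p = wt$p.value, kept = wt$p.value < alpha, reason = "")
    }
  })
  stage <- do.call(rbind, res)
  stage$reason[!stage$kept & stage$reason == ""] <-
    sprintf("p = %.3g >= %.3g", stage$p[!stage$kept & stage$reason == ""], alpha)
  list(kept = stage$feature[stage$kept], stage = stage)
}

#' Univariate logistic screen (cascade stage 3)
#'
#' One-predictor maximum-likelihood logistic fit per feature; features with
#' a Wald slope p-value < `alpha` are kept. Complete or quasi-complete
#' separation (a feature that classifies the cohort perfectly) makes the
#' Wald test meaningless; such features are flagged `separation` and kept,
#' because in small cohorts separation is the strongest possible signal,
#' not an artifact.
#'
#' @param x numeric feature data frame (standardized scale recommended).
#' @param labels binary 0/1 vector.
#' @param alpha retention level (default 0.05).
#' @return list: `kept`, `stage` (data frame `feature`, `coefficient`,
#'   `p`, `separation`, `kept`, `reason`).
#' @export
univariate_logistic_screen <- function(x, labels, alpha = 0.05) {
  stopifnot(is.data.frame(x), length(labels) == nrow(x), all(labels %in% 0:1))
  res <- lapply(names(x), function(nm) {
    dat <- data.frame(y = labels, f = x[[nm]])
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ f, family = stats::binomial(), data = dat)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(data.frame(feature = nm, coefficient = NA_real_, p = NA_real_,
                        separation = FALSE, kept = FALSE,
                        reason = "non-convergence"))
    sep <- detect_separation(fit)
    co <- summary(fit)$coefficients
    p <- if (nrow(co) >= 2) co[2, 4] else NA_real_
    beta <- if (nrow(co) >= 2) co[2, 1] else NA_real_
    kept <- isTRUE(sep) || (!is.na(p) && p < alpha)
    data.frame(feature = nm, coefficient = beta, p = p, separation = sep,
               kept = kept,
               reason = if (kept) "" else sprintf("Wald p = %.3g >= %.3g", p, alpha))
  })
  stage <- do.call(rbind, res)
  list(kept = stage$feature[stage$kept], stage = stage)
}

# Heuristic separation flag: fitted probabilities essentially 0/1 everywhere.
detect_separation <- function(fit) {
  mu <- stats::fitted(fit)
  all(mu < 1e-8 | mu > 1 - 1e-8)
}

#' Backward-stepwise multivariate logistic regression (cascade stage 4)
#'
#' Starts from the full logistic model on all candidate features and
#' iteratively removes the feature whose likelihood-ratio removal test has
#' the largest p-value, as long as that p exceeds `p_remove` (default
#' 0.10). Aliased (perfectly collinear) features are removed first with a
#' recorded reason; a non-converging step removes the offending feature.
#' Stops when every remaining feature satisfies p <= `p_remove`. If no
#' feature survives, an intercept-only model is returned with a warning.
#'
#' @param x numeric feature data frame (standardized scale; the recorded
#'   standardization, if attached via `std_params`, is stored in the model).
#' @param labels binary 0/1 vector.
#' @param p_remove removal threshold on the likelihood-ratio p (default 0.10).
#' @param std_params optional standardization record from
#'   [standardize_features()], stored for later application to raw features.
#' @return list: `model` (class `texture_logit_model`), `stage` (data frame
#'   of removal steps `step`, `feature`, `p`, `reason`).
#' @export
multivariate_backward <- function(x, labels, p_remove = 0.10, std_params = NULL) {
  stopifnot(is.data.frame(x), length(labels) == nrow(x), all(labels %in% 0:1))
  feats <- names(x)
  if (length(feats) >= nrow(x) - 1)
    warning("more candidate features than lesions support; fit may be unstable",
            call. = FALSE)
  steps <- list()
  record <- function(feature, p, reason) {
    steps[[length(steps) + 1L]] <<-
      data.frame(step = length(steps) + 1L, feature = feature, p = p,
                 reason = reason)
  }
  # marginal (single-predictor) deviance reductions, used only to break
  # removal-p ties: when the joint likelihood cannot rank two removals
  # (e.g. a saturated fit where every removal p is 1), the feature with
  # the weakest standalone support goes first
  null_dev <- suppressWarnings(
    stats::glm(labels ~ 1, family = stats::binomial()))$deviance
  marginal <- vapply(feats, function(nm) {
    f1 <- tryCatch(
      suppressWarnings(stats::glm(labels ~ f, family = stats::binomial(),
                                  data = data.frame(f = x[[nm]]))),
      error = function(e) NULL)
    if (is.null(f1)) 0 else null_dev - f1$deviance
  }, numeric(1))
  fit <- NULL
  repeat {
    dat <- cbind(data.frame(.y = labels), x[, feats, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = dat)),
      error = function(e) NULL)
    if (length(feats) == 0) break
    if (is.null(fit)) {
      record(feats[length(feats)], NA_real_, "non-convergence")
      feats <- feats[-length(feats)]
      next
    }
    # slope coefficients and drop1 rows align with `feats` by position
    cf <- stats::coef(fit)[-1]
    aliased <- which(is.na(cf))
    if (length(aliased)) {
      for (a in feats[aliased]) record(a, NA_real_, "aliased (collinear)")
      feats <- feats[-aliased]
      next
    }
    d1 <- tryCatch(suppressWarnings(stats::drop1(fit, test = "LRT")),
                   error = function(e) NULL)
    if (is.null(d1)) {
      record(feats[length(feats)], NA_real_, "removal test failure")
      feats <- feats[-length(feats)]
      next
    }
    pvals <- d1[["Pr(>Chi)"]][-1]
    # a removal that cannot change the (saturated) fit has removal p = 1
    pvals[is.na(pvals)] <- 1
    if (!length(pvals) || max(pvals) <= p_remove) break
    ties <- which(pvals >= max(pvals) - 1e-12)
    worst <- if (length(ties) > 1) ties[which.min(marginal[feats[ties]])]
             else ties
    record(feats[worst], pvals[worst],
           sprintf("LR p = %.3g > %.3g", pvals[worst], p_remove))
    feats <- feats[-worst]
  }
  if (length(feats) == 0) {
    warning("backward selection removed every feature; intercept-only model",
            call. = FALSE)
    fit <- stats::glm(labels ~ 1, family = stats::binomial())
  }
  cf <- stats::coef(fit)
  coefs <- cf[-1]
  names(coefs) <- feats                         # undo make.names mangling
  model <- structure(list(intercept = unname(cf[1]),
                          coefficients = coefs,
                          features = feats,
                          standardization = std_params,
                          n = length(labels),
                          converged = isTRUE(fit$converged)),
                     class = "texture_logit_model")
  stage <- if (length(steps)) do.call(rbind, steps)
           else data.frame(step = integer(0), feature = character(0),
                           p = numeric(0), reason = character(0))
  list(model = model, stage = stage)
}

#' Predict with a fitted grading model
#'
#' Applies the stored standardization (if any) and the logistic link.
#'
#' @param object a `texture_logit_model`.
#' @param newdata data frame holding at least the model's features, on the
#'   raw scale if the model stores standardization parameters, otherwise on
#'   the scale it was fitted on.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.texture_logit_model <- function(object, newdata, ...) {
  feats <- object$features
  if (length(feats) == 0)
    return(rep(stats::plogis(object$intercept), nrow(newdata)))
  missing <- setdiff(feats, names(newdata))
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(newdata[, feats, drop = FALSE])
  if (!is.null(object$standardization)) {
    sp <- object$standardization
    idx <- match(feats, sp$feature)
    if (!anyNA(idx)) {
      sds <- ifelse(sp$sd[idx] > 0, sp$sd[idx], 1)
      m <- sweep(sweep(m, 2, sp$mean[idx]), 2, sds, "/")
    }
  }
  stats::plogis(drop(m %*% object$coefficients) + object$intercept)
}

#' @export
print.texture_logit_model <- function(x, ...) {
  cat("<texture_logit_model> n =", x$n, "\n")
  cat("  logit(p) =", format(round(x$intercept, 3)))
  for (nm in x$features)
    cat(sprintf(" %+0.3f*%s", x$coefficients[[nm]], nm))
  cat("\n")
  invisible(x)
}

#' Run the full feature-selection cascade
#'
#' The four-stage reduction applied to a labeled feature table:
#' variance threshold on the raw scale, z-score standardization,
#' normality/homogeneity-gated univariate tests, univariate logistic
#' screen, then backward-stepwise multivariate logistic regression. The
#' kept sets are nested across stages and every removal carries a reason
#' in the returned trace. The cascade is deterministic: it has no internal
#' randomness.
#'
#' @param x numeric feature data frame on the raw scale (no id/label cols).
#' @param labels binary 0/1 vector (0 = benign-like).
#' @param variance_threshold stage-1 threshold (default 0.8).
#' @param alpha significance level for stages 2 and 3 (default 0.05).
#' @param p_remove backward-removal threshold (default 0.10).
#' @param standardize_first if `TRUE`, standardize before the variance
#'   filter (the vacuous order: z-scored columns all have variance 1). The
#'   default applies the variance filter to raw features first.
#' @return list of class `cascade_result`: `model`
#'   (`texture_logit_model`), `trace` (list with one record per stage plus
#'   the nested kept-sets), `kept` (character vector of final features).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_benign = 8, n_malignant = 8, seed = 3))
#' tab <- extract_cohort(lapply(coh$lesions, `[[`, "volume"), coh$labels)
#' res <- run_cascade(tab[, -(1:2)], tab$label)
#' res$model
#' @export
run_cascade <- function(x, labels, variance_threshold = 0.8, alpha = 0.05,
                        p_remove = 0.10, standardize_first = FALSE) {
  stopifnot(is.data.frame(x), length(labels) == nrow(x), all(labels %in% 0:1))
  trace <- list()
  if (standardize_first) {
    std <- standardize_features(x)
    vf <- variance_filter(std$table, variance_threshold)
    tab <- vf$table
  } else {
    vf <- variance_filter(x, variance_threshold)
    std <- standardize_features(vf$table)
    tab <- std$table
  }
  trace$variance <- vf$stage
  trace$standardization <- std$params
  empty_model <- function() {
    structure(list(intercept = stats::qlogis(mean(labels)),
                   coefficients = stats::setNames(numeric(0), character(0)),
                   features = character(0), standardization = std$params,
                   n = length(labels), converged = TRUE),
              class = "texture_logit_model")
  }
  if (ncol(tab) == 0) {
    warning("cascade: no feature survived the variance stage", call. = FALSE)
    return(structure(list(model = empty_model(), trace = trace,
                          kept = character(0)), class = "cascade_result"))
  }
  uni <- univariate_screen(tab, labels, alpha)
  trace$univariate <- uni$stage
  if (length(uni$kept) == 0) {
    warning("cascade: no feature survived the univariate screen", call. = FALSE)
    return(structure(list(model = empty_model(), trace = trace,
                          kept = character(0)), class = "cascade_result"))
  }
  ulog <- univariate_logistic_screen(tab[, uni$kept, drop = FALSE], labels, alpha)
  trace$univariate_logistic <- ulog$stage
  if (length(ulog$kept) == 0) {
    warning("cascade: no feature survived the univariate logistic screen",
            call. = FALSE)
    return(structure(list(model = empty_model(), trace = trace,
                          kept = character(0)), class = "cascade_result"))
  }
  mv <- multivariate_backward(tab[, ulog$kept, drop = FALSE], labels,
                              p_remove, std_params = std$params)
  trace$multivariate <- mv$stage
  trace$kept_sets <- list(variance = vf$stage$feature[vf$stage$kept],
                          univariate = uni$kept,
                          univariate_logistic = ulog$kept,
                          final = mv$model$features)
  structure(list(model = mv$model, trace = trace, kept = mv$model$features),
            class = "cascade_result")
}
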