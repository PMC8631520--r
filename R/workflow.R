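#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline. The defaults are the study
#' settings: 64 gray levels, co-occurrence distances 1–5, variance
#' threshold 0.8, retention level 0.05 for both univariate screens,
#' backward-removal threshold 0.10, 10 Hosmer–Lemeshow risk groups and a
#' logit-scale DeLong CI.
#'
#' @param n_levels gray levels Ng.
#' @param distances co-occurrence between-voxel distances.
#' @param variance_threshold cascade stage-1 threshold.
#' @param alpha univariate retention level.
#' @param p_remove backward-stepwise removal threshold.
#' @param standardize_first standardize before the variance filter
#'   (vacuous order; off by default).
#' @param hl_groups Hosmer–Lemeshow groups.
#' @param ci_scale `"logit"` or `"normal"`.
#' @param seed master seed used when the run simulates its cohort.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_levels = 64L, distances = 1:5,
                       variance_threshold = 0.8, alpha = 0.05,
                       p_remove = 0.10, standardize_first = FALSE,
                       hl_groups = 10L, ci_scale = "logit", seed = 7L) {
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances),
                 variance_threshold = variance_threshold, alpha = alpha,
                 p_remove = p_remove,
                 standardize_first = isTRUE(standardize_first),
                 hl_groups = as.integer(hl_groups), ci_scale = ci_scale,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Findings-only score: logistic fit on the irregular-cyst-wall indicator.
findings_model_scores <- function(findings, labels) {
  wall <- as.integer(findings$cyst_wall == "irregular")
  fit <- suppressWarnings(stats::glm(labels ~ wall, family = stats::binomial()))
  list(scores = unname(stats::fitted(fit)), predictor = wall, fit = fit)
}

#' Run the full study pipeline on a synthetic cohort
#'
#' The whole workflow in one call: generate (or accept) a cohort, extract
#' the 314-feature table, run the selection cascade to the texture model,
#' fit the imaging-findings model (logistic on the irregular-cyst-wall
#' indicator) and the combined model (the texture model's final features
#' plus the wall indicator), then evaluate all three with ROC/DeLong and
#' Hosmer–Lemeshow.
#'
#' @param config a [run_config()].
#' @param cohort a `synthetic_cohort`, or `NULL` to simulate the default
#'   26 + 21 cohort under `config$seed`.
#' @param out_dir optional directory for artifacts (feature table CSV,
#'   selection trace and report JSON).
#' @return list of class `study_result`: `report` (a `model_report`),
#'   `cascade` (the `cascade_result`), `features` (the labeled feature
#'   table), `scores` (named list), `findings`, `config`.
#' @export
run_full_study <- function(config = run_config(), cohort = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort))
    cohort <- generate_cohort(cohort_spec(seed = config$seed))
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ext_cfg <- extraction_config(config$n_levels, config$distances)
  tab <- extract_cohort(lapply(cohort$lesions, `[[`, "volume"),
                        labels = cohort$labels, config = ext_cfg)
  feat <- tab[, setdiff(names(tab), c("lesion_id", "label")), drop = FALSE]
  labels <- tab$label
  cascade <- run_cascade(feat, labels,
                         variance_threshold = config$variance_threshold,
                         alpha = config$alpha, p_remove = config$p_remove,
                         standardize_first = config$standardize_first)
  texture_scores <- predict(cascade$model, feat)
  fm <- findings_model_scores(cohort$findings, labels)
  comb <- combined_model_scores(cascade$model, feat, fm$predictor, labels)
  scores <- list(findings = fm$scores, texture = texture_scores,
                 combined = comb)
  report <- compare_models(scores, labels, hl_groups = config$hl_groups)
  out <- structure(list(report = report, cascade = cascade, features = tab,
                        scores = scores, findings = cohort$findings,
                        config = config),
                   class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    report_to_json(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(
      list(kept_sets = cascade$trace$kept_sets,
           multivariate = cascade$trace$multivariate,
           model = list(intercept = cascade$model$intercept,
                        coefficients = as.list(cascade$model$coefficients))),
      file.path(out_dir, "trace.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

# Combined model: final texture features + the wall indicator, one logistic
# refit on the standardized features (no further selection).
combined_model_scores <- function(texture_model, feat_raw, wall, labels) {
  feats <- texture_model$features
  if (length(feats) == 0) {
    fit <- suppressWarnings(stats::glm(labels ~ wall,
                                       family = stats::binomial()))
    return(unname(stats::fitted(fit)))
  }
  sp <- texture_model$standardization
  m <- as.matrix(feat_raw[, feats, drop = FALSE])
  idx <- match(feats, sp$feature)
  sds <- ifelse(sp$sd[idx] > 0, sp$sd[idx], 1)
  m <- sweep(sweep(m, 2, sp$mean[idx]), 2, sds, "/")
  dat <- as.data.frame(m)
  names(dat) <- paste0("f", seq_along(feats))
  dat$wall <- wall
  dat$.y <- labels
  fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                     data = dat))
  unname(stats::fitted(fit))
}

#' End-to-end demonstration run
#'
#' Convenience wrapper: simulate the default two-class cohort under one
#' seed and run the full pipeline.
#'
#' @param spec a [cohort_spec()]; its seed drives everything.
#' @param config a [run_config()].
#' @return a `study_result` (see [run_full_study()]).
#' @examples
#' \donttest{
#' res <- end_to_end_demo(cohort_spec(n_benign = 10, n_malignant = 10, seed = 1))
#' res$report
#' }
#' @export
end_to_end_demo <- function(spec = cohort_spec(), config = run_config()) {
  cohort <- generate_cohort(spec)
  run_full_study(config, cohort = cohort)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study on", nrow(x$features), "lesions;",
      length(x$cascade$kept), "texture features in the final model\n")
  print(x$report)
  invisible(x)
}
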