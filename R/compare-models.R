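#' Compare grading models on one cohort
#'
#' Scores several fitted models on the same lesions and assembles the
#' evaluation report: per-model ROC summary (AUC, 95% DeLong CI,
#' sensitivity and specificity at the Youden point), per-model
#' Hosmer–Lemeshow calibration, and all pairwise paired DeLong AUC
#' comparisons. The canonical use compares the texture model, the
#' imaging-findings model and the combined model.
#'
#' @param scores named list of numeric probability/score vectors, all of
#'   the same length; names identify the models.
#' @param labels binary 0/1 vector.
#' @param hl_groups Hosmer–Lemeshow group count (default 10); calibration
#'   is skipped (NA) for score vectors not strictly inside (0, 1).
#' @return Object of class `model_report`: list with `roc` (named list of
#'   `roc_result`), `calibration` (named list), `pairwise` (data frame
#'   `model_a`, `model_b`, `delta_auc`, `z`, `p`), `n`, `labels_table`.
#' @export
compare_models <- function(scores, labels, hl_groups = 10) {
  stopifnot(is.list(scores), length(scores) >= 1, !is.null(names(scores)),
            all(nzchar(names(scores))))
  n <- length(labels)
  stopifnot(all(vapply(scores, length, integer(1)) == n))
  roc <- lapply(scores, auc_delong, labels = labels)
  calib <- lapply(scores, function(s) {
    if (all(s > 0 & s < 1) && length(unique(s)) > 1)
      hosmer_lemeshow(s, labels, hl_groups)
    else list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  })
  nm <- names(scores)
  pw <- NULL
  if (length(nm) >= 2) {
    cmb <- utils::combn(nm, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      dt <- delong_paired_test(scores[[a]], scores[[b]], labels)
      data.frame(model_a = a, model_b = b, delta_auc = dt$delta,
                 z = dt$z, p = dt$p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(roc = roc, calibration = calib, pairwise = pw, n = n,
                 labels_table = table(factor(labels, levels = 0:1))),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Model comparison on", x$n, "lesions (",
      x$labels_table[1], "class-0 /", x$labels_table[2], "class-1 )\n\n")
  cat(sprintf("%-22s %6s  %13s  %11s  %11s  %6s\n",
              "Model", "AUC", "95% CI", "Sensitivity", "Specificity", "HL p"))
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    hl <- x$calibration[[nm]]$p
    cat(sprintf("%-22s %6.3f  %6.3f-%6.3f  %11.3f  %11.3f  %6s\n",
                nm, r$auc, r$ci[1], r$ci[2], r$sensitivity, r$specificity,
                ifelse(is.na(hl), "-", sprintf("%.3f", hl))))
  }
  if (!is.null(x$pairwise)) {
    cat("\nPairwise DeLong tests:\n")
    for (i in seq_len(nrow(x$pairwise))) {
      p <- x$pairwise[i, ]
      cat(sprintf("  %s vs %s: dAUC %+0.3f, z = %0.2f, p = %.3f\n",
                  p$model_a, p$model_b, p$delta_auc, p$z, p$p))
    }
  }
  invisible(x)
}

#' Serialize a model report (or any pipeline object) to JSON
#'
#' @param report a `model_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "model_report"))
  x <- list(
    n = report$n,
    models = lapply(report$roc, function(r)
      list(auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
           sensitivity = r$sensitivity, specificity = r$specificity,
           threshold = r$threshold)),
    calibration = lapply(report$calibration, function(h)
      list(statistic = h$statistic, df = h$df, p = h$p)),
    pairwise = report$pairwise)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read back a serialized model report
#' @param path JSON file written by [report_to_json()].
#' @return list mirroring the serialized structure.
#' @export
report_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
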