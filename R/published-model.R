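#' The published texture grading model (frozen)
#'
#' The texture-only logistic grading model reported for the original
#' 47-lesion phyllodes cohort, kept as a frozen evaluator — it is never
#' refit. It expects the five named features as z-scores (the source
#' cohort was standardized before model building):
#' \deqn{logit(p) = 0.067\,S(0,0,1)AngScMom + 0.001\,Z\_GLevNonU
#'   + 1.944\,Perc.90\% - 0.301\,Variance - 1.994\,Mean - 4.552}
#'
#' @return Named list: `coefficients` (5 named values), `intercept`.
#' @export
published_grading_model <- function() {
  list(coefficients = c("S(0,0,1)AngScMom" = 0.067,
                        "Z_GLevNonU"       = 0.001,
                        "Perc.90%"         = 1.944,
                        "Variance"         = -0.301,
                        "Mean"             = -1.994),
       intercept = -4.552)
}

#' Evaluate the frozen published grading model
#'
#' Pure function of the five z-scored inputs; no fitting path can alter
#' the coefficients.
#'
#' @param z_features named numeric vector or one-row data frame holding
#'   z-scores for `S(0,0,1)AngScMom`, `Z_GLevNonU`, `Perc.90%`,
#'   `Variance`, `Mean`. Extra entries are ignored.
#' @return list: `logit`, `probability` (= plogis(logit)).
#' @examples
#' evaluate_published_model(c("S(0,0,1)AngScMom" = 0, "Z_GLevNonU" = 0,
#'                            "Perc.90%" = 0, "Variance" = 0, "Mean" = 0))
#' @export
evaluate_published_model <- function(z_features) {
  pm <- published_grading_model()
  if (is.data.frame(z_features)) z_features <- unlist(z_features[1, ])
  missing <- setdiff(names(pm$coefficients), names(z_features))
  if (length(missing))
    stop("missing named feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  z <- as.numeric(z_features[names(pm$coefficients)])
  logit <- sum(pm$coefficients * z) + pm$intercept
  list(logit = logit, probability = stats::plogis(logit))
}
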