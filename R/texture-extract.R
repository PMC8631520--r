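#' Extraction configuration
#'
#' @param n_levels number of quantized gray levels Ng (default 64, the
#'   6-bit convention whose 1..64 scale matches the magnitudes that
#'   whole-lesion breast-MRI texture studies report for histogram features).
#' @param distances integer between-voxel distances for the co-occurrence
#'   offsets (default 1:5).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(n_levels = 64L, distances = 1:5) {
  stopifnot(n_levels >= 2, all(distances >= 1))
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances)),
            class = "extraction_config")
}

#' Extract the full texture-feature vector from one lesion
#'
#' Runs gray-level normalization ([normalize_voi()]) and then all four
#' feature families on the whole-tumor VOI:
#' \itemize{
#'   \item 9 histogram features;
#'   \item 11 Haralick statistics for each of 5 co-occurrence directions
#'     (three axes and the two in-plane diagonals) at each of 5
#'     between-voxel distances — 275 features named `S(a,b,c)<stat>`;
#'   \item 5 run-length statistics for each of 5 run directions — 25
#'     features named `Z_`/`Horzl_`/`Vertl_`/`45dgr_`/`135dr_<stat>`;
#'   \item 5 absolute-gradient features.
#' }
#' 314 features under the default configuration, in [feature_registry()]
#' order. Features whose defining denominator degenerates (e.g. correlation
#' of a zero-variance matrix, gradient moments with no interior voxel) are
#' returned as `NA` with the reason recorded in attribute
#' `undefined_reasons`, so downstream selection can drop them transparently.
#'
#' @param vm a [voi_volume()].
#' @param config an [extraction_config()].
#' @return Named numeric vector (length 314 by default) with attribute
#'   `undefined_reasons` (named character vector) when any feature is
#'   undefined.
#' @examples
#' vm <- generate_lesion(lesion_spec(seed = 1))$volume
#' fv <- extract_all(vm)
#' length(fv)   # 314
#' @export
extract_all <- function(vm, config = extraction_config()) {
  stopifnot(inherits(vm, "voi_volume"), inherits(config, "extraction_config"))
  q <- withCallingHandlers(
    normalize_voi(vm, config$n_levels),
    warning = function(w) invokeRestart("muffleWarning"))
  reasons <- character(0)
  take <- function(x, prefix = "", why) {
    undef <- attr(x, "undefined")
    out <- as.numeric(x)
    names(out) <- paste0(prefix, names(x))
    if (!is.null(undef)) {
      out[paste0(prefix, undef)] <- NA_real_
      reasons[paste0(prefix, undef)] <<- why
    }
    out
  }
  his <- take(histogram_features(q), why = "zero-variance VOI")
  glcm <- unlist(lapply(config$distances, function(d) {
    unlist(lapply(glcm_base_offsets(), function(b) {
      off <- b * d
      m <- build_glcm(q, off)
      why <- if (m$empty) "no valid voxel pair at this offset"
             else "degenerate co-occurrence marginals"
      take(glcm_features(m), prefix = glcm_feature_name(off, ""), why = why)
    }))
  }))
  rlm <- unlist(lapply(names(rlm_directions()), function(nm) {
    r <- build_rlm(q, nm)
    take(rlm_features(r), prefix = paste0(nm, "_"), why = "no run in direction")
  }))
  grad <- take(gradient_features(q), why = "degenerate gradient field")
  out <- c(his, glcm, rlm, grad)
  out <- out[feature_registry(config)$name]   # canonical registry order
  if (length(reasons)) attr(out, "undefined_reasons") <- reasons
  out
}

#' Extract a feature table for a cohort of lesions
#'
#' @param lesions list of [voi_volume()] objects (optionally named).
#' @param labels optional binary class labels (0 = benign-like,
#'   1 = borderline/malignant-like), recycled checks apply.
#' @param config an [extraction_config()].
#' @return data frame: one row per lesion, columns `lesion_id`, `label`
#'   (if given) and the registry features.
#' @export
extract_cohort <- function(lesions, labels = NULL, config = extraction_config()) {
  stopifnot(is.list(lesions), length(lesions) >= 1)
  ids <- names(lesions)
  if (is.null(ids)) ids <- sprintf("lesion_%03d", seq_along(lesions))
  rows <- lapply(lesions, extract_all, config = config)
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(data.frame(lesion_id = ids, stringsAsFactors = FALSE), tab)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(lesions), all(labels %in% 0:1))
    out <- cbind(out[, "lesion_id", drop = FALSE],
                 label = as.integer(labels),
                 tab)
  }
  rownames(out) <- NULL
  out
}
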