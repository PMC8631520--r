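#' GLCM offset directions and RLM run directions
#'
#' Offsets are integer steps `(d_row, d_col, d_slice)` in array index order.
#' The five co-occurrence base directions are the three axes plus the two
#' in-plane diagonals; each is scaled by the between-voxel distances 1..5.
#' Run-length directions use the field's naming: horizontal runs advance
#' along columns, vertical along rows, Z along slices, and the 45/135 degree
#' runs along the in-plane diagonals.
#' @name directions
#' @keywords internal
NULL

glcm_base_offsets <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
       c(1L, 1L, 0L), c(1L, -1L, 0L))
}

rlm_directions <- function() {
  list("Z"     = c(0L, 0L, 1L),
       "Horzl" = c(0L, 1L, 0L),
       "Vertl" = c(1L, 0L, 0L),
       "45dgr" = c(1L, 1L, 0L),
       "135dr" = c(1L, -1L, 0L))
}

glcm_stat_names <- function() {
  c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
    "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc", "DifEntrp")
}

rlm_stat_names <- function() {
  c("RLNonUni", "GLevNonU", "LngREmph", "ShrtREmp", "Fraction")
}

histogram_stat_names <- function() {
  c("Mean", "Variance", "Skewness", "Kurtosis",
    "Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%")
}

gradient_stat_names <- function() {
  c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
}

glcm_feature_name <- function(offset, stat) {
  sprintf("S(%d,%d,%d)%s", offset[1], offset[2], offset[3], stat)
}

#' The texture-feature registry
#'
#' Single source of truth mapping each of the 314 default feature names to
#' its family, statistic, direction/offset and distance. Naming follows the
#' MaZda-style convention used in the breast-MRI texture literature:
#' `S(a,b,c)<stat>` for co-occurrence features at voxel offset `(a,b,c)`
#' (array order row, column, slice), and `<dir>_<stat>` for run-length
#' features (`Z_`, `Horzl_`, `Vertl_`, `45dgr_`, `135dr_`). Gray levels are
#' 1-based (1..Ng), which the histogram/GLCM index arithmetic assumes.
#'
#' @param config an [extraction_config()]; the registry mirrors its gray
#'   levels and co-occurrence distances.
#' @return A data frame with columns `name`, `family` (`histogram`, `glcm`,
#'   `rlm`, `gradient`), `statistic`, `direction` (`"d1,d2,d3"` or `""`) and
#'   `distance` (integer, `NA` for non-GLCM families). 314 rows by default.
#' @examples
#' reg <- feature_registry()
#' table(reg$family)
#' @export
feature_registry <- function(config = extraction_config()) {
  his <- data.frame(name = histogram_stat_names(), family = "histogram",
                    statistic = histogram_stat_names(), direction = "",
                    distance = NA_integer_)
  glcm <- do.call(rbind, lapply(config$distances, function(d) {
    do.call(rbind, lapply(glcm_base_offsets(), function(b) {
      off <- b * d
      data.frame(name = glcm_feature_name(off, glcm_stat_names()),
                 family = "glcm", statistic = glcm_stat_names(),
                 direction = paste(b, collapse = ","), distance = d)
    }))
  }))
  dirs <- rlm_directions()
  rlm <- do.call(rbind, lapply(names(dirs), function(nm) {
    data.frame(name = paste0(nm, "_", rlm_stat_names()),
               family = "rlm", statistic = rlm_stat_names(),
               direction = paste(dirs[[nm]], collapse = ","),
               distance = NA_integer_)
  }))
  grad <- data.frame(name = gradient_stat_names(), family = "gradient",
                     statistic = gradient_stat_names(), direction = "",
                     distance = NA_integer_)
  out <- rbind(his, glcm, rlm, grad)
  rownames(out) <- NULL
  out
}

#' Write the feature registry as CSV (provenance export)
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_feature_registry <- function(path) {
  utils::write.csv(feature_registry(), path, row.names = FALSE)
  invisible(path)
}
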