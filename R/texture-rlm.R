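#' Build a run-length matrix along one direction
#'
#' A run is a maximal sequence of VOI voxels of equal gray level along a
#' lattice line in the given direction; runs break at any non-VOI voxel.
#' The five directions follow the volumetric convention: `Z` = across
#' slices (0,0,1), `Horzl` = along columns (0,1,0), `Vertl` = along rows
#' (1,0,0), `45dgr` = in-plane diagonal (1,1,0), `135dr` = in-plane
#' diagonal (1,-1,0), in (row, column, slice) index order.
#'
#' @param q a `quantized_voi`.
#' @param direction one of `"Z"`, `"Horzl"`, `"Vertl"`, `"45dgr"`,
#'   `"135dr"`, or an integer step 3-vector with entries in -1/0/1.
#' @return Object of class `rlm`: list with `r` (Ng x Lmax count matrix,
#'   `r[i, j]` = number of runs of level `i` and length `j`; Lmax is the
#'   longest lattice chord in that direction), `direction`, `step`,
#'   `n_runs` (Nr), and `Np` (VOI voxel count).
#' @export
build_rlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_voi"))
  if (is.character(direction)) {
    dirs <- rlm_directions()
    if (!direction %in% names(dirs))
      stop("unknown run direction: ", direction, call. = FALSE)
    step <- dirs[[direction]]
    dname <- direction
  } else {
    step <- as.integer(direction)
    if (length(step) != 3L || all(step == 0L) || any(abs(step) > 1L))
      stop("`direction` must be a unit step 3-vector", call. = FALSE)
    dname <- paste(step, collapse = ",")
  }
  L <- q$levels
  d <- dim(L)
  ng <- q$n_levels
  idx <- arrayInd(seq_along(L), d)
  ax <- which(step != 0L)[1]
  pos <- idx[, ax] * step[ax]           # strictly increasing along the line
  line <- idx - outer(pos, step)        # line invariants (constant per line)
  ord <- order(line[, 1], line[, 2], line[, 3], pos)
  lv <- as.vector(L)[ord]
  key <- (line[ord, 1] * (sum(d) + 1L) + line[ord, 2]) * (sum(d) + 1L) + line[ord, 3]
  valid <- !is.na(lv)
  prev_same <- c(FALSE, key[-1] == key[-length(key)] &
                          valid[-length(valid)] &
                          lv[-1] == lv[-length(lv)])
  prev_same[is.na(prev_same)] <- FALSE
  starts <- valid & !prev_same
  run_id <- cumsum(starts)
  run_id[!valid] <- 0L
  run_len <- tabulate(run_id[valid])
  run_lev <- lv[starts]
  lmax <- min(d[step != 0L])
  r <- matrix(0, ng, lmax)
  if (length(run_lev)) {
    tab <- rowsum(rep(1L, length(run_lev)), (run_len - 1L) * ng + run_lev)
    cells <- as.integer(rownames(tab))
    r[cbind(((cells - 1L) %% ng) + 1L, ((cells - 1L) %/% ng) + 1L)] <- tab[, 1]
  }
  structure(list(r = r, direction = dname, step = step,
                 n_runs = sum(r), Np = q$n_voxels),
            class = "rlm")
}

#' Run-length statistics
#'
#' Five statistics of a run-length matrix \eqn{r(i,j)} with \eqn{N_r}
#' runs over \eqn{N_p} voxels:
#' \deqn{GLevNonU = \sum_i \big(\sum_j r(i,j)\big)^2 / N_r}
#' (gray-level non-uniformity — low when runs are spread evenly over the
#' gray levels, i.e. similar intensities; it grows with heterogeneity
#' because heterogeneous VOIs fragment into many runs concentrated on few
#' levels), and analogously `RLNonUni` over run lengths,
#' `ShrtREmp` \eqn{= \sum r(i,j)/j^2 / N_r},
#' `LngREmph` \eqn{= \sum r(i,j)\,j^2 / N_r}, and
#' `Fraction` \eqn{= N_r / N_p}.
#'
#' @param r a [build_rlm()] result with `n_runs >= 1`.
#' @return Named numeric vector of the 5 statistics; all flagged undefined
#'   (attribute `undefined`, values 0) if the matrix holds no run.
#' @export
rlm_features <- function(r) {
  stopifnot(inherits(r, "rlm"))
  nms <- rlm_stat_names()
  nr <- r$n_runs
  if (nr < 1) {
    out <- stats::setNames(numeric(length(nms)), nms)
    attr(out, "undefined") <- nms
    return(out)
  }
  j <- seq_len(ncol(r$r))
  row_tot <- rowSums(r$r)
  col_tot <- colSums(r$r)
  c(RLNonUni = sum(col_tot^2) / nr,
    GLevNonU = sum(row_tot^2) / nr,
    LngREmph = sum(col_tot * j^2) / nr,
    ShrtREmp = sum(col_tot / j^2) / nr,
    Fraction = nr / r$Np)[nms]
}
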