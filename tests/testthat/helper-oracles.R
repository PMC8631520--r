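# Independent brute-force oracles. These deliberately use naive per-voxel
# loops and direct summation so they share no code path with the package.

# Build a quantized_voi directly from an integer level array (NA = outside
# the VOI), bypassing normalization, so matrix builders can be probed with
# hand-chosen levels.
qvoi_from_levels <- function(lev, n_levels = max(lev, na.rm = TRUE)) {
  stopifnot(is.array(lev), length(dim(lev)) == 3L)
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 n_voxels = sum(!is.na(lev)), shape = dim(lev),
                 params = list(mu = NA_real_, sigma = NA_real_,
                               window = c(NA_real_, NA_real_),
                               n_levels = as.integer(n_levels))),
            class = "quantized_voi")
}

# Random VOI level array for property tests.
random_levels <- function(dim, ng, p_in = 0.8) {
  lev <- array(sample.int(ng, prod(dim), replace = TRUE), dim)
  lev[array(runif(prod(dim)) > p_in, dim)] <- NA_integer_
  if (all(is.na(lev))) lev[1, 1, 1] <- 1L
  lev
}

# Per-voxel clip-and-bin recomputation of the normalization formula.
normalize_oracle <- function(x, ng) {
  np <- length(x)
  mu <- sum(x) / np
  sigma <- sqrt(sum((x - mu)^2) / np)
  if (sigma == 0) return(rep(1L, np))
  lo <- mu - 3 * sigma
  vapply(x, function(xi) {
    xc <- min(max(xi, lo), mu + 3 * sigma)
    l <- 1L + as.integer(floor((xc - lo) / (6 * sigma) * ng))
    min(l, ng)
  }, integer(1))
}

# Exhaustive pair enumeration for the co-occurrence matrix.
glcm_oracle <- function(lev, offset, ng) {
  d <- dim(lev)
  cnt <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    b <- lev[ii, jj, kk]
    if (is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  list(p = if (sum(cnt) > 0) cnt / sum(cnt) else cnt, n_pairs = sum(cnt))
}

# Naive direct-summation recomputation of the 11 co-occurrence statistics.
glcm_stats_oracle <- function(p) {
  ng <- nrow(p)
  asm <- con <- idm <- ent <- mx <- 0
  for (i in 1:ng) for (j in 1:ng) {
    asm <- asm + p[i, j]^2
    con <- con + (i - j)^2 * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    mx <- mx + i * p[i, j]
  }
  vx <- 0
  for (i in 1:ng) for (j in 1:ng) vx <- vx + (i - mx)^2 * p[i, j]
  cor_num <- 0
  for (i in 1:ng) for (j in 1:ng) cor_num <- cor_num + i * j * p[i, j]
  correlat <- if (vx > 0) (cor_num - mx^2) / vx else 0
  ps <- rep(0, 2 * ng)
  pd <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    ps[i + j] <- ps[i + j] + p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((2:(2 * ng)) * ps[2:(2 * ng)])
  sv <- sum(((2:(2 * ng)) - sa)^2 * ps[2:(2 * ng)])
  se <- -sum(ps[ps > 0] * log(ps[ps > 0]))
  da <- sum((0:(ng - 1)) * pd)
  dv <- sum((0:(ng - 1))^2 * pd) - da^2
  de <- -sum(pd[pd > 0] * log(pd[pd > 0]))
  c(AngScMom = asm, Contrast = con, Correlat = correlat, SumOfSqs = vx,
    InvDfMom = idm, SumAverg = sa, SumVarnc = sv, SumEntrp = se,
    Entropy = ent, DifVarnc = dv, DifEntrp = de)
}

# Scan-line run enumeration: walks every lattice line voxel by voxel.
rlm_oracle <- function(lev, step, ng) {
  d <- dim(lev)
  lmax <- min(d[step != 0])
  r <- matrix(0, ng, lmax)
  inb <- function(v) all(v >= 1) && all(v <= d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- c(i, j, k)
    if (inb(v - step)) next   # not a line start
    cur_lev <- NA_integer_; cur_len <- 0L
    while (inb(v)) {
      x <- lev[v[1], v[2], v[3]]
      if (!is.na(x) && !is.na(cur_lev) && x == cur_lev) {
        cur_len <- cur_len + 1L
      } else {
        if (!is.na(cur_lev)) r[cur_lev, cur_len] <- r[cur_lev, cur_len] + 1
        cur_lev <- x
        cur_len <- if (is.na(x)) 0L else 1L
      }
      v <- v + step
    }
    if (!is.na(cur_lev)) r[cur_lev, cur_len] <- r[cur_lev, cur_len] + 1
  }
  list(r = r, n_runs = sum(r))
}

# Exhaustive concordant-pair AUC (+ half ties).
auc_oracle <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yi in y)
    tot <- tot + if (xi > yi) 1 else if (xi == yi) 0.5 else 0
  tot / (length(x) * length(y))
}

# Central-difference gradient magnitudes, looped per voxel.
gradient_oracle <- function(lev) {
  d <- dim(lev)
  out <- numeric(0)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    vals <- c(lev[i, j, k],
              lev[i + 1, j, k], lev[i - 1, j, k],
              lev[i, j + 1, k], lev[i, j - 1, k],
              lev[i, j, k + 1], lev[i, j, k - 1])
    if (anyNA(vals)) next
    g <- c(vals[2] - vals[3], vals[4] - vals[5], vals[6] - vals[7]) / 2
    out <- c(out, sqrt(sum(g^2)))
  }
  out
}

# Small solid-ellipsoid phantom for smoke tests.
make_phantom <- function(dim = c(12L, 12L, 10L), seed = 1) {
  set.seed(seed)
  ctr <- (dim + 1) / 2
  i <- slice.index(array(0, dim), 1) - ctr[1]
  j <- slice.index(array(0, dim), 2) - ctr[2]
  k <- slice.index(array(0, dim), 3) - ctr[3]
  mask <- (i / 4.5)^2 + (j / 4.5)^2 + (k / 3.5)^2 <= 1
  vox <- 100 + 15 * array(rnorm(prod(dim)), dim)
  voi_volume(vox, mask)
}
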