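test_that("co-occurrence of a constant block concentrates in one cell", {
  q <- qvoi_from_levels(array(1L, dim = c(2, 2, 1)), 4)
  m <- build_glcm(q, c(1, 0, 0))
  expect_equal(m$p[1, 1], 1)
  expect_equal(sum(m$p), 1)
})

test_that("alternating strip gives the hand-enumerated symmetric matrix", {
  q <- qvoi_from_levels(array(c(1L, 2L, 1L, 2L), dim = c(4, 1, 1)), 2)
  m <- build_glcm(q, c(1, 0, 0))
  # 3 ordered pairs (1,2),(2,1),(1,2); symmetrized 6, all off-diagonal
  expect_equal(m$p[1, 2], 0.5)
  expect_equal(m$p[2, 1], 0.5)
  expect_equal(m$p[1, 1] + m$p[2, 2], 0)
})

test_that("offsets with no valid pair flag an empty matrix", {
  q <- qvoi_from_levels(array(1L, dim = c(1, 1, 1)), 2)
  m <- build_glcm(q, c(1, 0, 0))
  expect_true(m$empty)
  f <- glcm_features(m)
  expect_setequal(attr(f, "undefined"), names(f))
  expect_error(build_glcm(q, c(0, 0, 0)), "nonzero")
})

test_that("matrix equals brute-force pair enumeration on random VOIs, all offsets", {
  set.seed(101)
  offsets <- unlist(lapply(1:5, function(d) lapply(
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0)),
    function(b) b * d)), recursive = FALSE)
  for (rep in 1:6) {
    ng <- sample(2:4, 1)
    dims <- sample(2:5, 3, replace = TRUE)
    lev <- random_levels(dims, ng)
    q <- qvoi_from_levels(lev, ng)
    for (off in offsets) {
      m <- build_glcm(q, off)
      o <- glcm_oracle(lev, off, ng)
      expect_equal(m$n_pairs, o$n_pairs)
      expect_equal(m$p, o$p)
    }
  }
})

test_that("every matrix is normalized and exactly symmetric", {
  set.seed(5)
  for (rep in 1:5) {
    q <- qvoi_from_levels(random_levels(c(6, 5, 4), 5), 5)
    m <- build_glcm(q, c(1, 1, 0))
    if (m$empty) next
    expect_equal(sum(m$p), 1)
    expect_identical(m$p, t(m$p))
  }
})

test_that("Haralick statistics of closed-form matrices are exact", {
  # single-cell matrix (constant image)
  q <- qvoi_from_levels(array(3L, dim = c(3, 3, 1)), 4)
  f <- glcm_features(build_glcm(q, c(0, 1, 0)))
  expect_equal(unname(f[c("AngScMom", "Contrast", "Entropy", "InvDfMom")]),
               c(1, 0, 0, 1))
  # two-cell checkerboard matrix p(1,2) = p(2,1) = 0.5
  q2 <- qvoi_from_levels(array(c(1L, 2L, 1L, 2L), dim = c(4, 1, 1)), 2)
  f2 <- glcm_features(build_glcm(q2, c(1, 0, 0)))
  expect_equal(unname(f2["AngScMom"]), 0.5)
  expect_equal(unname(f2["Contrast"]), 1)
  expect_equal(unname(f2["Entropy"]), log(2))
})

test_that("all 11 statistics match a naive-summation oracle", {
  set.seed(202)
  for (rep in 1:8) {
    ng <- sample(3:6, 1)
    q <- qvoi_from_levels(random_levels(c(5, 5, 3), ng), ng)
    m <- build_glcm(q, sample(list(c(1, 0, 0), c(0, 0, 1), c(1, -1, 0)), 1)[[1]])
    if (m$empty) next
    f <- glcm_features(m)
    o <- glcm_stats_oracle(m$p)
    expect_equal(unname(f), unname(o[names(f)]), tolerance = 1e-12)
  }
})

test_that("AngScMom is 1 exactly when one cell holds all mass", {
  set.seed(8)
  for (rep in 1:5) {
    ng <- 4
    q <- qvoi_from_levels(random_levels(c(4, 4, 2), ng), ng)
    m <- build_glcm(q, c(1, 0, 0))
    if (m$empty) next
    f <- glcm_features(m)
    expect_gt(unname(f["AngScMom"]), 0)
    expect_lte(unname(f["AngScMom"]), 1)
    expect_equal(unname(f["AngScMom"]) == 1, sum(m$p > 0) == 1)
  }
})
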