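test_that("degenerate score configurations give the expected AUC", {
  labels <- rep(0:1, each = 4)
  sep <- auc_delong(c(1, 2, 3, 4, 5, 6, 7, 8), labels)
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  flat <- auc_delong(rep(2, 8), labels)
  expect_equal(flat$auc, 0.5)
  expect_error(auc_delong(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals the exhaustive concordant-pair count exactly", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.3)
    if (runif(1) < 0.5) scores <- round(scores)   # force ties often
    r <- auc_delong(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("the DeLong interval contains the AUC and narrows with n", {
  set.seed(52)
  width <- vapply(c(30, 300), function(n) {
    w <- replicate(20, {
      labels <- rep(0:1, each = n / 2)
      scores <- labels + rnorm(n)
      r <- auc_delong(scores, labels)
      stopifnot(r$ci[1] <= r$auc, r$auc <= r$ci[2])
      r$ci[2] - r$ci[1]
    })
    mean(w)
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("AUC and DeLong variance agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (rep in 1:10) {
    n <- 40
    labels <- rep(0:1, each = n / 2)
    scores <- labels * runif(1, 0.5, 2) + rnorm(n)
    r <- auc_delong(scores, labels, ci_scale = "normal")
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(pr, method = "delong")))
    expect_equal(r$ci, pmin(pmax(ci[c(1, 3)], 0), 1), tolerance = 1e-9)
  }
})

test_that("identical score vectors give a degenerate paired test", {
  labels <- rep(0:1, each = 10)
  s <- rnorm(20)
  dt <- delong_paired_test(s, s, labels)
  expect_equal(dt$delta, 0)
  expect_equal(dt$p, 1)
  expect_true(dt$degenerate)
})

test_that("the paired test agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  for (rep in 1:8) {
    n <- 60
    labels <- rep(0:1, each = n / 2)
    a <- labels + rnorm(n); b <- labels * 0.5 + rnorm(n)
    dt <- delong_paired_test(a, b, labels)
    pr <- pROC::roc.test(pROC::roc(labels, a, direction = "<", quiet = TRUE),
                         pROC::roc(labels, b, direction = "<", quiet = TRUE),
                         method = "delong", paired = TRUE)
    expect_equal(dt$p, pr$p.value, tolerance = 1e-9)
  }
})

test_that("the paired test holds its size under the null", {
  set.seed(55)
  rej <- mean(replicate(400, {
    labels <- rep(0:1, each = 30)
    delong_paired_test(rnorm(60), rnorm(60), labels)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("the Youden operating point maximizes sensitivity + specificity", {
  set.seed(56)
  labels <- rbinom(50, 1, 0.5); labels[1:2] <- 0:1
  scores <- labels + rnorm(50)
  r <- auc_delong(scores, labels)
  js <- vapply(sort(unique(scores)), function(t)
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1,
    numeric(1))
  expect_equal(r$sensitivity + r$specificity - 1, max(js))
})
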