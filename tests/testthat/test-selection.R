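test_that("standardization z-scores columns and flags constants", {
  x <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize_features(x)
  expect_equal(s$table$a, c(-1, 0, 1))
  expect_equal(s$table$b, c(5, 5, 5))
  expect_identical(s$zero_variance, "b")
  set.seed(1)
  big <- as.data.frame(matrix(rnorm(200) * rep(c(1, 100), each = 100), 20))
  st <- standardize_features(big)$table
  expect_true(all(abs(colMeans(st)) < 1e-12))
  expect_true(all(abs(apply(st, 2, sd) - 1) < 1e-12))
})

test_that("variance filter removes below-threshold columns strictly", {
  n <- 100
  mk <- function(v) sqrt(v) * scale(seq_len(n))[, 1]   # sample variance v
  x <- data.frame(const = rep(1, n), lo = mk(0.79), hi = mk(0.81))
  vf <- variance_filter(x, 0.8)
  expect_identical(names(vf$table), "hi")
  expect_match(vf$stage$reason[vf$stage$feature == "lo"], "variance")
  expect_equal(formals(variance_filter)$threshold, 0.8)
})

test_that("variance filter drops features carrying undefined values", {
  x <- data.frame(ok = rnorm(10), holed = c(NA, rnorm(9)))
  vf <- variance_filter(x, 0)
  expect_identical(names(vf$table), "ok")
  expect_match(vf$stage$reason[vf$stage$feature == "holed"], "undefined")
})

test_that("univariate screen keeps real effects and drops constants", {
  set.seed(31)
  labels <- rep(0:1, each = 20)
  x <- data.frame(flat = rep(3, 40),
                  strong = c(rnorm(20, 0), rnorm(20, 5)),
                  noise = rnorm(40))
  sc <- univariate_screen(x, labels)
  expect_true("strong" %in% sc$kept)
  expect_false("flat" %in% sc$kept)
  expect_match(sc$stage$reason[sc$stage$feature == "flat"], "degenerate")
  # independent rank-sum check of the strong feature
  w <- sum(rank(x$strong)[labels == 1]) - 20 * 21 / 2
  expect_equal(w, 400)   # complete separation of ranks at this seed
})

test_that("heavily skewed features route to the rank test", {
  set.seed(32)
  labels <- rep(0:1, each = 15)
  x <- data.frame(skewed = exp(rnorm(30, sd = 2)),
                  gaussian = c(rnorm(15), rnorm(15, 10)))
  sc <- univariate_screen(x, labels)
  expect_equal(sc$stage$test[sc$stage$feature == "skewed"], "mann-whitney")
  expect_equal(sc$stage$test[sc$stage$feature == "gaussian"], "t")
})

test_that("univariate logistic screen drops noise and flags separation", {
  set.seed(33)
  labels <- rep(0:1, each = 25)
  x <- data.frame(noise = rnorm(50),
                  exact = as.numeric(labels),
                  good = labels * 0.7 + rnorm(50, sd = 1))
  sc <- univariate_logistic_screen(x, labels)
  expect_false("noise" %in% sc$kept)
  expect_true(sc$stage$separation[sc$stage$feature == "exact"])
  expect_true("exact" %in% sc$kept)
  expect_true("good" %in% sc$kept)
  # Wald p of the moderate effect agrees with a likelihood-ratio check
  # within an order of magnitude
  fit <- glm(labels ~ good, family = binomial(), data = x)
  lr_p <- pchisq(fit$null.deviance - fit$deviance, 1, lower.tail = FALSE)
  wald_p <- sc$stage$p[sc$stage$feature == "good"]
  expect_lt(abs(log10(wald_p) - log10(lr_p)), 1)
})

test_that("a single candidate is returned as fitted", {
  set.seed(34)
  labels <- rep(0:1, each = 20)
  x <- data.frame(only = labels + rnorm(40, sd = 0.7))
  mv <- multivariate_backward(x, labels)
  expect_identical(mv$model$features, "only")
  expect_equal(nrow(mv$stage), 0)
  expect_true(all(predict(mv$model, x) > 0 & predict(mv$model, x) < 1))
})

test_that("backward selection retains true predictors and sheds noise", {
  set.seed(35)
  hits_true <- 0; removed_noise <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    n <- 200
    x <- as.data.frame(matrix(rnorm(n * 5), n))
    names(x) <- c("t1", "t2", "n1", "n2", "n3")
    eta <- 2 * x$t1 - 2 * x$t2
    y <- rbinom(n, 1, plogis(eta))
    mv <- suppressWarnings(multivariate_backward(x, y))
    if (all(c("t1", "t2") %in% mv$model$features)) hits_true <- hits_true + 1
    removed_noise <- removed_noise +
      (length(setdiff(c("n1", "n2", "n3"), mv$model$features)) >= 2)
  }
  expect_gte(hits_true / n_rep, 0.9)
  expect_gte(removed_noise / n_rep, 0.9)
})

test_that("removal order is recorded and every removal has a reason", {
  set.seed(36)
  n <- 80
  x <- as.data.frame(matrix(rnorm(n * 4), n))
  names(x) <- paste0("f", 1:4)
  x$dup <- x$f1                      # aliased column
  y <- rbinom(n, 1, plogis(x$f1))
  mv <- suppressWarnings(multivariate_backward(x, y))
  expect_true(all(nzchar(mv$stage$reason)))
  expect_true("dup" %in% mv$stage$feature | "f1" %in% mv$stage$feature)
  # the final model's features were never removed
  expect_length(intersect(mv$model$features, mv$stage$feature), 0)
})

test_that("cascade kept-sets are nested and the run is deterministic", {
  set.seed(37)
  n <- 40
  labels <- rep(0:1, each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 12), n))
  names(x) <- paste0("f", 1:12)
  x$f1 <- x$f1 + 2 * labels
  x$f2 <- x$f2 * 3 - labels * 4
  r1 <- suppressWarnings(run_cascade(x, labels))
  r2 <- suppressWarnings(run_cascade(x, labels))
  ks <- r1$trace$kept_sets
  expect_true(all(ks$univariate %in% ks$variance))
  expect_true(all(ks$univariate_logistic %in% ks$univariate))
  expect_true(all(ks$final %in% ks$univariate_logistic))
  expect_identical(r1$model$coefficients, r2$model$coefficients)
})

test_that("permuted labels leave the cascade with at most a token model", {
  coh <- generate_cohort(cohort_spec(n_benign = 13, n_malignant = 11, seed = 3))
  tab <- extract_cohort(lapply(coh$lesions, `[[`, "volume"), coh$labels)
  feat <- tab[, setdiff(names(tab), c("lesion_id", "label"))]
  set.seed(99)
  sizes <- replicate(15, {
    lab <- sample(tab$label)
    length(suppressWarnings(run_cascade(feat, lab))$kept)
  })
  expect_gte(mean(sizes <= 1), 0.6)
  expect_lte(median(sizes), 1)
})

test_that("univariate screen holds its size on null features", {
  set.seed(38)
  labels <- rep(0:1, each = 15)
  x <- as.data.frame(matrix(rnorm(30 * 400), 30))
  sc <- univariate_screen(x, labels)
  rate <- mean(sc$stage$p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
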