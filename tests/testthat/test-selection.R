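test_that("ICC(2,1) matches a two-way ANOVA oracle on a toy table", {
  x1 <- c(9, 6, 8, 7, 10, 6)
  x2 <- c(2, 1, 4, 1, 5, 2)
  got <- habitatr:::icc21(x1, x2)
  # independent route: ANOVA mean squares via aov
  y <- c(x1, x2)
  subj <- factor(rep(1:6, 2)); rater <- factor(rep(1:2, each = 6))
  ms <- summary(stats::aov(y ~ subj + rater))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  want <- (MSR - MSE) / (MSR + MSE + 2 / 6 * (MSC - MSE))
  expect_equal(got, want, tolerance = 1e-12)
  # identical measurements: ICC 1 and retained
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  res <- icc_filter(m, m)
  expect_equal(unname(res$icc), c(1, 1))
  expect_setequal(res$retained, c("a", "b"))
})

test_that("independent noise is dropped by the ICC filter", {
  set.seed(5)
  a <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  b <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res <- icc_filter(a, b)
  expect_length(res$retained, 0)
  expect_true(all(abs(res$icc) < 0.3))
  # zero-variance features are dropped with a warning
  a[, 1] <- 1; b[, 1] <- 1
  expect_warning(res2 <- icc_filter(a, b), "undefined")
  expect_true(is.na(res2$icc["f1"]))
})

test_that("z-scoring standardizes train and never refits on new data", {
  set.seed(1)
  x <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  zp <- zscore_fit(x)
  xt <- zscore_apply(x, zp)
  expect_true(all(abs(colMeans(xt)) < 1e-12))
  expect_equal(unname(apply(xt, 2, sd)), rep(1, 3))
  # shifted validation data keeps its shift (no leakage)
  xv <- x + 2
  expect_true(all(colMeans(zscore_apply(xv, zp)) > 0.5))
  # constant columns are dropped with a warning
  x2 <- cbind(x, d = 1)
  expect_warning(zp2 <- zscore_fit(x2), "zero-variance")
  expect_identical(zp2$dropped, "d")
})

test_that("the t-test screen matches stats::t.test and screens by power", {
  g1 <- c(1.1, 2.3, 0.4, 1.9); g0 <- c(3.2, 4.4, 2.9, 3.8)
  x <- matrix(c(g1, g0), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(1, 0), each = 4)
  res <- ttest_filter(x, y, alpha = 0.05)
  ref <- stats::t.test(g1, g0)
  expect_equal(unname(res$t["f"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(res$p["f"]), ref$p.value, tolerance = 1e-12)
  # identical distributions: t = 0, p = 1, dropped
  same <- matrix(rep(c(1, 2, 3), 4), ncol = 1, dimnames = list(NULL, "s"))
  res0 <- ttest_filter(same, rep(c(0, 1), each = 6))
  expect_equal(unname(res0$t), 0)
  expect_length(res0$retained, 0)
  # a 3 SD shift at n=30/30 is always retained
  set.seed(2)
  xs <- matrix(c(rnorm(30, 3), rnorm(30, 0)), ncol = 1,
               dimnames = list(NULL, "big"))
  expect_identical(ttest_filter(xs, rep(c(1, 0), each = 30))$retained, "big")
  expect_error(ttest_filter(xs, rep(1, 60)), "class")
})

test_that("Pearson pruning keeps the most important member of each clique", {
  set.seed(3)
  base <- rnorm(100)
  x <- cbind(a = base + rnorm(100, 0, 0.1), b = base + rnorm(100, 0, 0.1),
             c = base + rnorm(100, 0, 0.1), d = rnorm(100))
  imp <- c(a = 3, b = 2, c = 1, d = 0.5)
  kept <- pearson_prune(x, threshold = 0.9, importance = imp)
  expect_setequal(kept, c("a", "d"))
  # duplicated column: exactly one survivor
  x2 <- cbind(u = base, v = base)
  expect_length(pearson_prune(x2, importance = c(u = 1, v = 1)), 1)
  # orthogonal columns all survive
  x3 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("p", "q", "r")))
  expect_length(pearson_prune(x3), 3)
  # no retained pair exceeds the threshold
  r <- abs(cor(x[, kept]))
  expect_true(all(r[upper.tri(r)] <= 0.9))
})

test_that("LASSO recovers a single planted predictor with the right sign", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- rbinom(200, 1, stats::plogis(2 * x[, 1]))
    res <- lasso_cv_select(x, y, seed = s)
    hits <- hits + ("f1" %in% res$selected &&
                      res$coefficients["f1"] > 0)
  }
  expect_gte(hits, 5 * 0.95 - 1)
  # huge penalty shrinks everything to zero
  set.seed(1)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(50, 1, 0.4)
  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = 10)
  expect_true(all(as.matrix(coef(fit))[-1, 1] == 0))
})

test_that("duplicated predictors are not jointly selected with large weights", {
  set.seed(9)
  base <- rnorm(150)
  x <- cbind(a = base, b = base,
             matrix(rnorm(150 * 8), 150, 8,
                    dimnames = list(NULL, paste0("n", 1:8))))
  y <- rbinom(150, 1, stats::plogis(1.5 * base))
  res <- lasso_cv_select(x, y, seed = 4)
  co <- res$coefficients[intersect(c("a", "b"), names(res$coefficients))]
  # at most one of the two clones carries a material weight
  expect_lte(sum(abs(co) > 0.2), 1)
})

test_that("the composite score is the documented linear form", {
  rec <- c(x1 = 2, x2 = -1)
  expect_equal(composite_score(rec, c(x1 = 0, x2 = 0), intercept = 1.5), 1.5)
  expect_equal(composite_score(rec, c(x1 = 1), intercept = 0), 2)
  s_ab <- composite_score(c(x1 = 5, x2 = 1), c(x1 = 2, x2 = 3), 0.5)
  s_a <- composite_score(c(x1 = 2, x2 = 0), c(x1 = 2, x2 = 3), 0.5)
  s_b <- composite_score(c(x1 = 3, x2 = 1), c(x1 = 2, x2 = 3), 0.5)
  expect_equal(s_ab, s_a + s_b - 0.5)
  expect_error(composite_score(c(x1 = 1), c(x1 = 1, x2 = 2)), "x2")
})
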