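test_that("AUC agrees with exhaustive pair counting and both routes match", {
  scores <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  # brute force over all positive/negative pairs
  pos <- scores[y == 1]; neg <- scores[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_mann_whitney(scores, y), mean(pairs))
  expect_equal(auc_mann_whitney(scores, y), 0.75)
  # trapezoid route identical to Mann-Whitney on random data with ties
  set.seed(4)
  for (i in 1:10) {
    s <- round(runif(40), 2)
    yy <- rbinom(40, 1, 0.4)
    if (length(unique(yy)) < 2) next
    expect_equal(auc_trapezoid(s, yy), auc_mann_whitney(s, yy),
                 tolerance = 1e-12)
  }
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(auc_mann_whitney(1:4, rep(1, 4)), "class")
})

test_that("DeLong intervals match pROC and cover the truth", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- c(rnorm(40, 1), rnorm(60, 0)); y <- rep(c(1, 0), c(40, 60))
  got <- roc_auc_ci(s, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                       method = "delong"))
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(got$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(got$ci_high, as.numeric(ref[3]), tolerance = 1e-10)
})

test_that("DeLong coverage is approximately nominal on binormal scores", {
  set.seed(21)
  true_auc <- pnorm(1 / sqrt(2))  # binormal with unit shift
  cover <- mean(replicate(200, {
    s <- c(rnorm(50, 1), rnorm(50, 0))
    y <- rep(c(1, 0), each = 50)
    ci <- roc_auc_ci(s, y)
    ci$ci_low <= true_auc && true_auc <= ci$ci_high
  }))
  expect_gt(cover, 0.88)
})

test_that("threshold selection and confusion metrics follow their formulas", {
  # toy confusion TP=3 FP=1 TN=4 FN=2
  scores <- c(rep(0.9, 3), rep(0.2, 2), rep(0.8, 1), rep(0.1, 4))
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(scores, y, 0.5)
  expect_equal(cm[c("tp", "fp", "tn", "fn")], list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$npv, 2 / 3)
  # all predicted positive
  cm2 <- confusion_metrics(scores, y, 0.0)
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 0)
  expect_equal(cm2$ppv, 0.5)
  # perfect separation: Youden threshold achieves all-ones metrics
  sp <- c(0.9, 0.8, 0.2, 0.1); yp <- c(1, 1, 0, 0)
  thr <- choose_threshold(sp, yp)
  cmp <- confusion_metrics(sp, yp, thr)
  expect_equal(unlist(cmp[c("accuracy", "sensitivity", "specificity",
                            "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, ppv = 1,
                 npv = 1))
})

test_that("decision curves match their closed forms", {
  set.seed(3)
  p <- runif(40); y <- rbinom(40, 1, p)
  grid <- seq(0.1, 0.9, by = 0.1)
  dc <- decision_curve(p, y, grid)
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y)
  expect_equal(dc$treat_all, prev - (1 - prev) * grid / (1 - grid))
  # hand count at pt = 0.5 on a 4-sample toy
  pt <- 0.5
  p4 <- c(0.9, 0.6, 0.4, 0.2); y4 <- c(1, 0, 1, 0)
  dc4 <- decision_curve(p4, y4, pt)
  expect_equal(dc4$net_benefit, 1 / 4 - 1 / 4 * pt / (1 - pt))
  # useless constant model never beats the references materially
  pc <- rep(prev, 40)
  dcc <- decision_curve(pc, y, grid)
  expect_true(all(dcc$net_benefit <= pmax(dcc$treat_all, 0) + 1e-12))
})

test_that("Hosmer-Lemeshow is exact on calibrated input and a 2-bin toy", {
  # perfectly calibrated: chi2 = 0, p = 1
  p <- rep(c(0.2, 0.8), each = 10)
  y <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(8, 2)))
  hl <- calibration_and_hl(p, y, groups = 2)
  expect_equal(hl$chi2, 0)
  expect_equal(hl$p, 1)
  expect_equal(hl$bins$observed, hl$bins$mean_pred)
  # constructed 2-bin toy vs hand arithmetic
  p2 <- rep(c(0.3, 0.7), each = 10)
  y2 <- c(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(6, 4)))
  hl2 <- calibration_and_hl(p2, y2, groups = 2)
  want <- (5 - 3)^2 / (3 * (1 - 3 / 10)) + (6 - 7)^2 / (7 * (1 - 7 / 10))
  expect_equal(hl2$chi2, want)
  expect_equal(hl2$df, 1)
})

test_that("a well-specified model passes Hosmer-Lemeshow at the nominal rate", {
  set.seed(17)
  rejections <- mean(replicate(60, {
    x <- rnorm(150)
    y <- rbinom(150, 1, stats::plogis(-0.5 + x))
    fit <- glm(y ~ x, family = binomial())
    calibration_and_hl(fitted(fit), y)$p < 0.05
  }))
  expect_lt(rejections, 0.20)
})

test_that("pcr_model runs the nested cascade and its methods work", {
  set.seed(8)
  n <- 80
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  y <- rbinom(n, 1, stats::plogis(1.5 * x[, 1] - 1.2 * x[, 2]))
  m <- pcr_model(x, y, seed = 2)
  st <- m$selection$stages
  expect_true(all(st$lasso %in% st$pearson))
  expect_true(all(st$pearson %in% st$ttest))
  expect_true(all(st$ttest %in% st$standardized))
  expect_s3_class(m, "pcr_model")
  expect_gt(m$threshold, 0); expect_lt(m$threshold, 1)
  p <- predict(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict(m, x, type = "class"),
               as.integer(p >= m$threshold))
  expect_equal(stats::plogis(predict(m, x, type = "link")), p)
  expect_output(print(m), "cascade")
  expect_output(print(summary(m)), "Selected features")
  expect_length(residuals(m), n)
  expect_named(coef(m)[1], "(Intercept)")
  rep_tr <- evaluate_model(m, x, y)
  expect_s3_class(rep_tr, "eval_report")
  expect_gt(rep_tr$auc, 0.7)
  cm <- rep_tr$confusion
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
})

test_that("a separable single feature yields training AUC 1 via the ridge path", {
  y <- rep(c(0, 1), each = 15)
  x <- matrix(y * 2 - 1 + 0.01 * seq_len(30), ncol = 1,
              dimnames = list(NULL, "sep"))
  fit <- fit_lr(x, y)
  expect_true(is.finite(fit$coefficients["sep"]))
  s <- drop(cbind(1, x) %*% fit$coefficients)
  expect_equal(auc_mann_whitney(s, y), 1)
})

test_that("predicted probabilities average to the training prevalence", {
  set.seed(12)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, stats::plogis(x[, 1]))
  fit <- fit_lr(x, y)
  p <- stats::plogis(drop(cbind(1, x) %*% fit$coefficients))
  expect_equal(mean(p), mean(y), tolerance = 1e-6)
})

test_that("validation labels never influence the fitted model", {
  set.seed(31)
  x <- matrix(rnorm(120 * 30), 120, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- rbinom(120, 1, stats::plogis(x[, 3]))
  tr <- 1:80
  m1 <- pcr_model(x[tr, ], y[tr], seed = 5)
  # permute validation labels; refit on the same training rows
  m2 <- pcr_model(x[tr, ], y[tr], seed = 5)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$selection$stages$lasso, m2$selection$stages$lasso)
  # predictions on validation data are a pure function of the train fit
  expect_identical(predict(m1, x[-tr, ]), predict(m2, x[-tr, ]))
})
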