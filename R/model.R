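#' Fit the radiomic prediction model
#'
#' The package's core estimator: given a raw feature table and binary pCR
#' labels it runs the complete selection cascade — optional ICC-retained
#' restriction, training-median imputation of missing values, z-score
#' standardization (parameters fitted on these training data only), Welch
#' t-test screen (p < `alpha`), Pearson redundancy pruning (|r| >
#' `r_threshold`, keeping the larger |t|), LASSO with `folds`-fold
#' cross-validated lambda — and refits an unpenalized maximum-likelihood
#' logistic regression on the selected standardized features. The decision
#' threshold is the probability maximizing Youden's J on the training ROC.
#' Stage outputs are strictly nested and no validation data ever enters the
#' fit. If the t-screen or LASSO returns nothing, the cascade falls back to
#' the single feature with the largest |t| (with a warning).
#'
#' @param x Numeric matrix, samples x features (raw, unstandardized).
#' @param y Binary labels (0/1 or logical), 1 = pCR.
#' @param alpha t-test significance level (default 0.05).
#' @param r_threshold Pearson pruning bound (default 0.9).
#' @param folds LASSO CV folds (default 10).
#' @param icc_keep Optional character vector of ICC-robust feature names to
#'   restrict the pool to before any fitting.
#' @param seed Integer seed (CV folds).
#' @return An object of class `pcr_model` with components `coefficients`
#'   (logistic weights incl. intercept), `selection` (per-stage retained
#'   names plus t/p/ICC bookkeeping), `zscore`, `lasso`, `threshold`,
#'   `impute_medians` and provenance fields.
#' @seealso [predict.pcr_model()], [evaluate_model()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 20), 60, dimnames = list(NULL, paste0("f", 1:20)))
#' y <- rbinom(60, 1, stats::plogis(2 * x[, 1]))
#' m <- pcr_model(x, y, seed = 1)
#' predict(m, x[1:3, ])
#' @export
pcr_model <- function(x, y, alpha = 0.05, r_threshold = 0.9, folds = 10L,
                      icc_keep = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (!all(y %in% 0:1) || length(unique(y)) < 2)
    stopf("`y` must be binary with both classes present")
  stages <- list(input = colnames(x))
  if (!is.null(icc_keep)) {
    x <- x[, intersect(colnames(x), icc_keep), drop = FALSE]
    if (!ncol(x)) stopf("no features left after the ICC restriction")
  }
  stages$icc <- colnames(x)
  # training-median imputation of missing feature values (empty habitats)
  med <- apply(x, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- med[j]
  zs <- suppressWarnings(zscore_fit(x))
  xs <- zscore_apply(x, zs)
  stages$standardized <- colnames(xs)
  tt <- ttest_filter(xs, y, alpha = alpha)
  retained <- tt$retained
  if (!length(retained)) {
    warnf("no feature passed the t-test screen; keeping the top-|t| feature")
    retained <- names(which.max(abs(tt$t)))
  }
  stages$ttest <- retained
  pruned <- pearson_prune(xs[, retained, drop = FALSE],
                          threshold = r_threshold, importance = tt$t)
  stages$pearson <- pruned
  las <- lasso_cv_select(xs[, pruned, drop = FALSE], y, folds = folds,
                         seed = seed)
  selected <- las$selected
  if (!length(selected)) {
    selected <- pruned[which.max(abs(tt$t[pruned]))]
  }
  stages$lasso <- selected
  fit <- fit_lr(xs[, selected, drop = FALSE], y)
  scores <- drop(cbind(1, xs[, selected, drop = FALSE]) %*% fit$coefficients)
  prob <- stats::plogis(scores)
  thr <- choose_threshold(prob, y)
  structure(list(coefficients = fit$coefficients,
                 selection = list(stages = stages, t = tt$t, p = tt$p,
                                  icc_keep = icc_keep),
                 zscore = zs, impute_medians = med, lasso = las,
                 threshold = thr, ridge_fallback = fit$ridge,
                 labels = y, train_prob = prob,
                 alpha = alpha, r_threshold = r_threshold, folds = folds,
                 seed = seed, call = match.call()),
            class = "pcr_model")
}

#' Maximum-likelihood logistic regression
#'
#' Unpenalized logistic fit of binary labels on (standardized, already
#' selected) features. Perfect separation is detected from the glm warning /
#' diverging coefficients and handled by refitting with a small ridge
#' penalty, flagged in the result.
#'
#' @param x Numeric matrix of predictors.
#' @param y Binary labels.
#' @return List with `coefficients` (intercept first) and `ridge` flag.
#' @export
fit_lr <- function(x, y) {
  df <- data.frame(y = y, x, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || any(abs(coef(fit)) > 1e3)) {
    # separation: stabilize with a light ridge penalty
    xm <- as.matrix(x)
    rf <- glmnet::glmnet(cbind(xm, 0), y, family = "binomial", alpha = 0,
                         lambda = 0.01)
    co <- as.matrix(coef(rf))[, 1]
    co <- co[seq_len(ncol(xm) + 1)]
    names(co) <- c("(Intercept)", colnames(x))
    return(list(coefficients = co, ridge = TRUE))
  }
  co <- coef(fit)
  names(co) <- c("(Intercept)", colnames(x))
  list(coefficients = co, ridge = FALSE)
}

#' @method print pcr_model
#' @export
print.pcr_model <- function(x, ...) {
  st <- x$selection$stages
  cat("Radiomic pCR prediction model (logistic regression)\n")
  cat(sprintf("  selection cascade: %d -> t-test %d -> Pearson %d -> LASSO %d\n",
              length(st$standardized), length(st$ttest), length(st$pearson),
              length(st$lasso)))
  cat(sprintf("  lambda* = %.4g, decision threshold = %.3f%s\n",
              x$lasso$lambda, x$threshold,
              if (isTRUE(x$ridge_fallback)) " (ridge-stabilized fit)" else ""))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.pcr_model <- function(object, ...) object$coefficients

#' Predict from a fitted radiomic model
#'
#' New samples are imputed with the training medians, standardized with the
#' training z-score parameters and scored with the logistic coefficients —
#' validation data never re-estimates any parameter.
#'
#' @param object A `pcr_model`.
#' @param newdata Numeric matrix (or vector) of raw feature values
#'   containing every selected feature.
#' @param type `"response"` (probability, default), `"link"` (linear score)
#'   or `"class"` (0/1 at the trained threshold).
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.pcr_model <- function(object, newdata,
                              type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  sel <- names(object$coefficients)[-1]
  missing <- setdiff(sel, colnames(newdata))
  if (length(missing))
    stopf("newdata is missing selected feature(s): %s",
          paste(missing, collapse = ", "))
  need <- intersect(names(object$zscore$center), colnames(newdata))
  x <- newdata[, need, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- object$impute_medians[colnames(x)[j]]
  }
  # standardize only the needed columns with train params
  ctr <- object$zscore$center[colnames(x)]
  scl <- object$zscore$scale[colnames(x)]
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  link <- drop(cbind(1, xs[, sel, drop = FALSE]) %*% object$coefficients)
  switch(type,
         link = link,
         response = stats::plogis(link),
         class = as.integer(stats::plogis(link) >= object$threshold))
}

#' @export
residuals.pcr_model <- function(object, type = c("deviance", "response"),
                                ...) {
  type <- match.arg(type)
  p <- object$train_prob
  y <- object$labels
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(pmax(p, 1e-15)) +
                             (1 - y) * log(pmax(1 - p, 1e-15))))
}

#' @method summary pcr_model
#' @export
summary.pcr_model <- function(object, ...) {
  st <- object$selection$stages
  sel <- st$lasso
  out <- list(
    stages = data.frame(
      stage = c("input", "icc", "standardized", "ttest", "pearson", "lasso"),
      n_features = vapply(st[c("input", "icc", "standardized", "ttest",
                               "pearson", "lasso")], length, 0L)),
    coefficients = object$coefficients,
    t = object$selection$t[sel],
    p = object$selection$p[sel],
    lambda = object$lasso$lambda,
    threshold = object$threshold,
    train_auc = auc_mann_whitney(object$train_prob, object$labels))
  class(out) <- "summary.pcr_model"
  out
}

#' @method print summary.pcr_model
#' @export
print.summary.pcr_model <- function(x, ...) {
  cat("Radiomic pCR model - selection cascade\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("\nlambda* = %.4g; training AUC = %.3f; threshold = %.3f\n",
              x$lambda, x$train_auc, x$threshold))
  cat("\nSelected features (logistic coefficients, t, p):\n")
  sel <- names(x$coefficients)[-1]
  tab <- data.frame(coefficient = round(x$coefficients[-1], 4),
                    t = round(x$t[sel], 2),
                    p = signif(x$p[sel], 3))
  print(tab)
  invisible(x)
}

#' Plot the LASSO cross-validation curve of a fitted model
#'
#' @param x A `pcr_model`.
#' @param ... Passed to [plot()].
#' @export
plot.pcr_model <- function(x, ...) {
  cv <- x$lasso$cv
  if (is.null(cv)) {
    warnf("no CV curve stored (degenerate single-feature fit)")
    return(invisible(x))
  }
  plot(log(cv$lambda), cv$cvm, type = "l", xlab = "log(lambda)",
       ylab = "mean CV binomial deviance", ...)
  lines(log(cv$lambda), cv$cvm + cv$cvsd, lty = 3)
  lines(log(cv$lambda), cv$cvm - cv$cvsd, lty = 3)
  abline(v = log(x$lasso$lambda), lty = 2)
  invisible(x)
}
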