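#' ICC robustness filter
#'
#' Intraclass correlation ICC(2,1) — two-way random effects, absolute
#' agreement, single measurement — computed per feature between two aligned
#' measurement sets (e.g. features from an original and a re-drawn
#' segmentation). Features with ICC at or above `threshold` (default 0.75)
#' are retained; features with zero variance in both raters have undefined
#' ICC and are dropped with a warning.
#'
#' @param values_rater1,values_rater2 Numeric matrices, samples x features,
#'   with identical dimnames.
#' @param threshold Retention threshold (default 0.75).
#' @return List with `retained` (character), `icc` (named numeric).
#' @export
icc_filter <- function(values_rater1, values_rater2, threshold = 0.75) {
  stopifnot(identical(dim(values_rater1), dim(values_rater2)))
  p <- ncol(values_rater1)
  nms <- colnames(values_rater1) %||% paste0("f", seq_len(p))
  icc <- vapply(seq_len(p), function(j) {
    icc21(values_rater1[, j], values_rater2[, j])
  }, 0)
  names(icc) <- nms
  undef <- is.na(icc)
  if (any(undef))
    warnf("%d feature(s) had undefined ICC (zero variance) and were dropped",
          sum(undef))
  list(retained = nms[!undef & icc >= threshold], icc = icc)
}

# ICC(2,1) from the two-way ANOVA decomposition of an n x k table.
icc21 <- function(x1, x2) {
  Y <- cbind(x1, x2)
  n <- nrow(Y); k <- 2
  if (sd(Y) < 1e-12) return(NA_real_)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  if (abs(den) < 1e-300) return(NA_real_)
  (MSR - MSE) / den
}

#' Z-score standardization fitted on the training cohort
#'
#' @param train Numeric matrix (samples x features).
#' @return `zscore_fit` returns a `zscore_params` list with `center`,
#'   `scale` and `dropped` (zero-variance feature names, excluded from the
#'   transform).
#' @export
zscore_fit <- function(train) {
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  dropped <- colnames(train)[scl < 1e-12]
  if (length(dropped))
    warnf("%d zero-variance feature(s) dropped during standardization",
          length(dropped))
  keep <- setdiff(colnames(train), dropped)
  structure(list(center = ctr[keep], scale = scl[keep], dropped = dropped),
            class = "zscore_params")
}

#' @rdname zscore_fit
#' @param x Matrix to transform (train or validation).
#' @param params A `zscore_params` object.
#' @export
zscore_apply <- function(x, params) {
  keep <- names(params$center)
  missing <- setdiff(keep, colnames(x))
  if (length(missing))
    stopf("matrix lacks standardized feature(s): %s",
          paste(head(missing, 3), collapse = ", "))
  sweep(sweep(x[, keep, drop = FALSE], 2, params$center), 2, params$scale, `/`)
}

#' Two-sample t-test screen
#'
#' Welch's two-sided t-test of every feature between the two classes;
#' features with p below `alpha` are retained.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary labels (0/1), both classes with >= 2 samples.
#' @param alpha Significance level (default 0.05).
#' @return List with `retained`, `t` and `p` (named vectors).
#' @export
ttest_filter <- function(x, y, alpha = 0.05) {
  y <- as.integer(y)
  if (min(table(factor(y, levels = 0:1))) < 2)
    stopf("both classes need >= 2 samples for the t-test screen")
  g1 <- x[y == 1, , drop = FALSE]
  g0 <- x[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, var); v0 <- apply(g0, 2, var)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)),
                     1e-300)
  pp <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  pp[se2 < 1e-300] <- 1
  tt[se2 < 1e-300] <- 0
  names(tt) <- names(pp) <- colnames(x)
  list(retained = colnames(x)[pp < alpha], t = tt, p = pp)
}

#' Pearson redundancy pruning
#'
#' Greedy pruning of feature pairs with absolute correlation above
#' `threshold`: features are visited in decreasing importance (|t| by
#' default, ties broken lexicographically) and kept only if not correlated
#' above the threshold with an already-kept feature; the result contains no
#' pair above the threshold.
#'
#' @param x Numeric matrix restricted to the candidate features.
#' @param threshold Absolute correlation bound (default 0.9).
#' @param importance Named importance scores (larger = kept preferentially).
#' @return Character vector of retained feature names.
#' @export
pearson_prune <- function(x, threshold = 0.9, importance = NULL) {
  nms <- colnames(x)
  if (length(nms) <= 1) return(nms)
  imp <- if (is.null(importance)) stats::setNames(rep(0, length(nms)), nms)
         else abs(importance[nms])
  ord <- nms[order(-imp, nms)]
  r <- abs(suppressWarnings(cor(x)))
  r[is.na(r)] <- 0
  kept <- character(0)
  for (f in ord) {
    if (!length(kept) || all(r[f, kept] <= threshold)) kept <- c(kept, f)
  }
  nms[nms %in% kept]
}

#' LASSO feature selection with cross-validated lambda
#'
#' L1-penalized logistic regression over a log-spaced lambda grid;
#' `lambda*` minimizes the mean cross-validated binomial deviance, and the
#' selection is the set of features with nonzero coefficient there. An
#' all-zero selection is reported empty with a warning (the model cascade
#' falls back to the single most discriminative feature).
#'
#' @param x Standardized numeric matrix (samples x features).
#' @param y Binary labels (0/1).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `lambda`, `selected`, `coefficients` (named, nonzero,
#'   no intercept), `intercept`, `cv` (data frame lambda/mean deviance) and
#'   the underlying `cv.glmnet` fit.
#' @export
lasso_cv_select <- function(x, y, folds = 10L, seed = 1L) {
  if (nrow(x) < folds) stopf("need at least `folds` = %d samples", folds)
  set.seed(child_seed(seed, "lasso"))
  foldid <- sample(rep_len(seq_len(folds), nrow(x)))
  if (ncol(x) < 2) {
    # glmnet needs >= 2 columns; a single candidate is trivially selected
    return(list(lambda = 0, selected = colnames(x),
                coefficients = stats::setNames(NA_real_, colnames(x)),
                intercept = NA_real_, cv = NULL, fit = NULL))
  }
  # muffle glmnet's small-fold advisories; everything else passes through
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      foldid = foldid, type.measure = "deviance"),
    warning = function(w) {
      if (grepl("grouped=FALSE enforced|fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- as.matrix(coef(cvfit, s = "lambda.min"))
  nz <- co[-1, 1]
  sel <- names(nz)[nz != 0]
  if (!length(sel))
    warnf("LASSO selected no features at lambda.min")
  list(lambda = cvfit$lambda.min, selected = sel,
       coefficients = nz[nz != 0], intercept = co[1, 1],
       cv = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                       cvsd = cvfit$cvsd),
       fit = cvfit)
}

#' Linear composite (radiomic / habitat) score
#'
#' `intercept + sum(coefficients * record[names])`; the record must contain
#' every selected feature (already standardized with the training
#' parameters).
#'
#' @param record Named numeric vector of standardized feature values.
#' @param coefficients Named coefficient vector.
#' @param intercept Scalar intercept.
#' @return The scalar score.
#' @export
composite_score <- function(record, coefficients, intercept = 0) {
  missing <- setdiff(names(coefficients), names(record))
  if (length(missing))
    stopf("record is missing selected feature(s): %s",
          paste(missing, collapse = ", "))
  unname(intercept + sum(coefficients * record[names(coefficients)]))
}
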