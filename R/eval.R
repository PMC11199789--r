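#' ROC curve, AUC and DeLong confidence interval
#'
#' `auc_mann_whitney()` computes the AUC as the Mann-Whitney probability of
#' correct ranking with half credit for ties; `roc_curve()` returns the
#' empirical ROC points (whose trapezoidal area equals the Mann-Whitney AUC
#' identically); `roc_auc_ci()` adds the DeLong 95% confidence interval,
#' truncated to [0, 1].
#'
#' @param scores Numeric risk scores or probabilities.
#' @param y Binary labels (0/1), both classes present.
#' @param conf Confidence level (default 0.95).
#' @return `roc_auc_ci`: list with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
roc_auc_ci <- function(scores, y, conf = 0.95) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  # placements
  v10 <- vapply(pos, function(a) mean(psi(a, neg)), 0)
  v01 <- vapply(neg, function(b) mean(psi(pos, b)), 0)
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), se = se)
}

#' @rdname roc_auc_ci
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc_ci
#' @return `roc_curve`: data frame with `threshold`, `fpr`, `tpr`;
#'   `auc_trapezoid`: scalar trapezoidal area under it.
#' @export
roc_curve <- function(scores, y) {
  y <- as.integer(y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' @rdname roc_auc_ci
#' @export
auc_trapezoid <- function(scores, y) {
  rc <- roc_curve(scores, y)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Training decision threshold and confusion-matrix metrics
#'
#' `choose_threshold()` picks the probability cut maximizing Youden's J
#' (sensitivity + specificity - 1) on the training scores — the paper-style
#' non-0.5 operating point; ties break toward the larger threshold.
#' `confusion_metrics()` applies a threshold (predicted positive when
#' `score >= threshold`) and reports counts and rates; ratios with zero
#' denominator are `NA`.
#'
#' @param scores Predicted probabilities.
#' @param y Binary labels.
#' @param threshold Decision threshold in (0, 1).
#' @return `choose_threshold`: scalar threshold. `confusion_metrics`: list
#'   with counts `tp fp tn fn` and `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
choose_threshold <- function(scores, y) {
  y <- as.integer(y)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    sens <- sum(scores >= t & y == 1) / sum(y == 1)
    spec <- sum(scores < t & y == 0) / sum(y == 0)
    sens + spec - 1
  }, 0)
  best <- which(j == max(j))
  cand[best[length(best)]]
}

#' @rdname choose_threshold
#' @export
confusion_metrics <- function(scores, y, threshold) {
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn))
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` of treating patients whose
#' predicted probability reaches the threshold probability `pt`, with the
#' treat-all and treat-none (identically 0) reference policies.
#'
#' @param probabilities Predicted probabilities.
#' @param y Binary labels.
#' @param pt_grid Threshold-probability grid in (0, 1).
#' @return Data frame `pt`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, y,
                           pt_grid = seq(0.05, 0.95, by = 0.01)) {
  if (any(pt_grid <= 0 | pt_grid >= 1)) stopf("`pt_grid` must lie in (0, 1)")
  y <- as.integer(y)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(pt_grid, function(pt) {
    tp <- sum(probabilities >= pt & y == 1)
    fp <- sum(probabilities >= pt & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  data.frame(pt = pt_grid, net_benefit = nb,
             treat_all = prev - (1 - prev) * pt_grid / (1 - pt_grid),
             treat_none = 0)
}

#' Calibration bins and the Hosmer-Lemeshow test
#'
#' Groups samples into deciles of predicted risk (empty bins are merged with
#' their neighbour and the degrees of freedom adjusted), reports per-bin mean
#' predicted probability vs observed event fraction for calibration plots,
#' and the Hosmer-Lemeshow chi-square
#' `sum (O - E)^2 / (E (1 - E/n_bin))` with `df = bins - 2`.
#'
#' @param probabilities Predicted probabilities.
#' @param y Binary labels.
#' @param groups Number of risk bins (default 10).
#' @return List with `bins` (data frame `n`, `mean_pred`, `observed`),
#'   `chi2`, `df`, `p`.
#' @export
calibration_and_hl <- function(probabilities, y, groups = 10L) {
  y <- as.integer(y)
  n <- length(y)
  if (n < groups) stopf("need at least `groups` = %d samples", groups)
  br <- unique(quantile(probabilities, seq(0, 1, length.out = groups + 1),
                        type = 7))
  if (length(br) < 3) br <- c(-Inf, mean(probabilities), Inf)
  br[1] <- -Inf; br[length(br)] <- Inf
  g <- cut(probabilities, br, labels = FALSE)
  gs <- sort(unique(g))
  bins <- data.frame(
    n = vapply(gs, function(b) sum(g == b), 0),
    mean_pred = vapply(gs, function(b) mean(probabilities[g == b]), 0),
    observed = vapply(gs, function(b) mean(y[g == b]), 0))
  O <- bins$n * bins$observed
  E <- bins$n * bins$mean_pred
  denom <- E * (1 - E / bins$n)
  ok <- denom > 1e-12
  chi2 <- sum((O[ok] - E[ok])^2 / denom[ok])
  df <- max(nrow(bins) - 2, 1)
  list(bins = bins, chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Full discrimination / calibration / decision-curve evaluation
#'
#' Computes the complete performance report of a fitted [pcr_model()] on a
#' cohort: AUC with DeLong 95% CI, confusion-matrix metrics at the trained
#' threshold, the decision curve, calibration bins and the Hosmer-Lemeshow
#' test.
#'
#' @param model A `pcr_model`.
#' @param x Raw feature matrix of the cohort.
#' @param y Binary labels.
#' @param groups Hosmer-Lemeshow bins.
#' @param pt_grid Decision-curve threshold grid.
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, x, y, groups = 10L,
                           pt_grid = seq(0.05, 0.95, by = 0.01)) {
  prob <- predict(model, x, type = "response")
  y <- as.integer(y)
  auc <- roc_auc_ci(prob, y)
  cm <- confusion_metrics(prob, y, model$threshold)
  hl <- if (length(y) >= groups) calibration_and_hl(prob, y, groups) else NULL
  structure(list(n = length(y), auc = auc$auc, auc_ci = c(auc$ci_low, auc$ci_high),
                 threshold = model$threshold, confusion = cm,
                 dca = decision_curve(prob, y, pt_grid),
                 calibration = hl, probabilities = prob, labels = y,
                 roc = roc_curve(prob, y)),
            class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples (prevalence %.2f)\n", x$n,
              mean(x$labels)))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  cm <- x$confusion
  cat(sprintf("  threshold %.3f: acc %.3f, sens %.3f, spec %.3f, PPV %.3f, NPV %.3f\n",
              x$threshold, cm$accuracy, cm$sensitivity, cm$specificity,
              cm$ppv, cm$npv))
  if (!is.null(x$calibration))
    cat(sprintf("  Hosmer-Lemeshow chi2 = %.2f (df %d), p = %.3f\n",
                x$calibration$chi2, x$calibration$df, x$calibration$p))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Serializes an `eval_report` as JSON (scalar metrics) plus CSV curves
#' (ROC, decision curve, calibration bins) under `dir`, prefixed by `name`.
#'
#' @param report An `eval_report` from [evaluate_model()].
#' @param dir Output directory (created if needed).
#' @param name File prefix, e.g. `"habitat_validation"`.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir, name = "eval") {
  stopifnot(inherits(report, "eval_report"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("writing reports requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, paste0(name, ".json")),
    roc = file.path(dir, paste0(name, "_roc.csv")),
    dca = file.path(dir, paste0(name, "_dca.csv")))
  if (!is.null(report$calibration))
    paths["calibration"] <- file.path(dir, paste0(name, "_calibration.csv"))
  scalars <- list(n = report$n, auc = report$auc,
                  auc_ci_low = report$auc_ci[1],
                  auc_ci_high = report$auc_ci[2],
                  threshold = report$threshold,
                  confusion = report$confusion,
                  hosmer_lemeshow = if (!is.null(report$calibration))
                    report$calibration[c("chi2", "df", "p")])
  jsonlite::write_json(scalars, paths["json"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$roc, paths["roc"], row.names = FALSE)
  utils::write.csv(report$dca, paths["dca"], row.names = FALSE)
  if (!is.null(report$calibration))
    utils::write.csv(report$calibration$bins, paths["calibration"],
                     row.names = FALSE)
  invisible(paths)
}
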