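#' First-order intensity statistics
#'
#' The 18 standard first-order descriptors of the in-mask intensity
#' distribution. Variance, skewness and kurtosis are population moments;
#' kurtosis is not excess-corrected; a zero-variance region returns skewness
#' and kurtosis 0 by convention so no NaN enters a feature table. Entropy and
#' uniformity are computed on the discretized grey levels.
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask`.
#' @param disc Optional `discretized_volume` (recomputed if missing).
#' @return Named numeric vector of 18 features (names `firstorder_*`).
#' @export
first_order <- function(image, mask, disc = NULL) {
  check_geometry(image, mask)
  sel <- mask$voxels > 0
  if (!any(sel)) stopf("mask is empty")
  x <- image$voxels[sel]
  if (is.null(disc)) disc <- discretize(image, mask)
  p <- tabulate(disc$levels[disc$levels > 0], disc$ng)
  p <- p / sum(p)
  p <- p[p > 0]
  n <- length(x)
  vv <- prod(image$spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- unname(quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  core <- x[x >= qs[1] & x <= qs[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = vv * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_Percentile10 = qs[1],
    firstorder_Percentile90 = qs[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = qs[3],
    firstorder_InterquartileRange = qs[4] - qs[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(core)) mean(abs(core - mean(core))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}
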