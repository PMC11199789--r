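#' Derived-image filter bank
#'
#' Expands one CT volume into the 20 derived volumes the feature engine
#' operates on: the original image, the 8 bands of a single-level stationary
#' (undecimated) separable Haar wavelet decomposition, Laplacian-of-Gaussian
#' responses at sigma 1..6 mm, and 5 intensity transforms (square,
#' square root, logarithm, exponential, gradient magnitude). All outputs stay
#' on the source grid.
#'
#' The logarithm uses the shift `sign(x) * log(|x| + 1)` so non-positive HU
#' never error; the exponential is `exp(x / max|x|)` to stay bounded.
#'
#' @param image An `image_volume`.
#' @return A named list of 20 `image_volume`s (class `filtered_image_set`),
#'   `"original"` first.
#' @export
apply_filter_bank <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  a <- image$voxels
  sp <- image$spacing
  out <- list(original = a)
  # stationary Haar: low = (x[i] + x[i+1])/sqrt(2), high = (x[i] - x[i+1])/sqrt(2)
  lo <- function(v, ax) conv_axis(v, c(1, 1) / sqrt(2), c(0L, 1L), ax)
  hi <- function(v, ax) conv_axis(v, c(1, -1) / sqrt(2), c(0L, 1L), ax)
  for (band in c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")) {
    v <- a
    for (ax in 1:3) {
      v <- if (substr(band, ax, ax) == "L") lo(v, ax) else hi(v, ax)
    }
    out[[paste0("wavelet.", band)]] <- v
  }
  for (s in 1:6) {
    g <- gaussian_smooth(a, s / sp)
    lap <- array(0, dim(a))
    for (ax in 1:3) {
      lap <- lap + conv_axis(g, c(1, -2, 1) / sp[ax]^2, c(-1L, 0L, 1L), ax)
    }
    out[[sprintf("log.sigma.%d.mm", s)]] <- s^2 * lap
  }
  out$square <- a^2
  out$squareroot <- sign(a) * sqrt(abs(a))
  out$logarithm <- sign(a) * log1p(abs(a))
  m <- max(abs(a), 1e-6)
  out$exponential <- exp(a / m)
  grad2 <- array(0, dim(a))
  for (ax in 1:3) {
    grad2 <- grad2 + conv_axis(a, c(-1, 0, 1) / (2 * sp[ax]), c(-1L, 0L, 1L), ax)^2
  }
  out$gradient <- sqrt(grad2)
  structure(lapply(out, image_volume, spacing = sp, origin = image$origin),
            class = "filtered_image_set")
}

#' Fixed-bin-width grey-level discretization
#'
#' Levels are `floor((v - min_in_mask) / bin_width) + 1`. On original-HU
#' images the default width is 25 HU; derived images with arbitrary dynamic
#' range fall back to `range / 32`. The level count is capped at 256 by
#' widening the bin if necessary.
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask` (nonempty).
#' @param bin_width Positive bin width; `NULL` picks the policy above.
#' @param image_type Name of the derived image (controls the default width).
#' @return A `discretized_volume`: list with `levels` (integer array, 0
#'   outside the mask), `ng`, `bin_width` and `dim`.
#' @export
discretize <- function(image, mask, bin_width = NULL, image_type = "original") {
  check_geometry(image, mask)
  sel <- mask$voxels > 0
  if (!any(sel)) stopf("mask is empty")
  v <- image$voxels[sel]
  rng <- max(v) - min(v)
  if (is.null(bin_width)) {
    bin_width <- if (identical(image_type, "original")) 25 else max(rng / 32, 1e-9)
  }
  if (bin_width <= 0) stopf("`bin_width` must be positive")
  if (rng / bin_width > 255) bin_width <- rng / 255
  lev <- array(0L, dim(image$voxels))
  lev[sel] <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  structure(list(levels = lev, ng = max(lev), bin_width = bin_width,
                 dim = dim(lev), n_voxels = sum(sel)),
            class = "discretized_volume")
}
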