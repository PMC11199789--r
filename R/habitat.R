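#' Voxel-wise radiomic feature maps
#'
#' For every in-mask voxel, computes the original intensity and local
#' first-order statistics (mean, variance, energy, entropy, uniformity) on
#' the `(2r+1)^3` neighbourhood intersected with the ROI; entropy and
#' uniformity use the ROI-wide 25 HU discretization. Columns are z-scored
#' across voxels (zero-variance columns map to 0), ready for clustering.
#' A neighbourhood that degenerates to fewer than 2 voxels falls back to the
#' voxel's own intensity.
#'
#' The default clustering feature set is `intensity` plus `local_mean`: at
#' CT resolution the dispersion-type window statistics (variance, entropy,
#' uniformity) respond mostly to subregion *boundaries* rather than to the
#' subregions themselves, and spending cluster centroids on boundary shells
#' degrades habitat recovery; the full window set stays available through
#' `features`.
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask`.
#' @param kernel_radius Neighbourhood radius in voxels (>= 1).
#' @param bin_width Discretization width for the entropy/uniformity maps.
#' @param features Character subset of `intensity`, `local_mean`,
#'   `local_variance`, `local_energy`, `local_entropy`, `local_uniformity`
#'   used for the clustering matrix.
#' @return A `voxel_feature_matrix`: list with `x` (z-scored matrix, one row
#'   per in-mask voxel), `raw` (all six unscaled maps), `coords` (voxel
#'   indices), `center`, `scale`.
#' @export
voxel_feature_maps <- function(image, mask, kernel_radius = 1L,
                               bin_width = 25,
                               features = c("intensity", "local_mean")) {
  check_geometry(image, mask)
  if (kernel_radius < 1) stopf("`kernel_radius` must be >= 1")
  if (sum(mask$voxels) == 0) stopf("mask is empty")
  disc <- discretize(image, mask, bin_width = bin_width)
  stats <- cpp_local_stats(image$voxels, disc$levels, disc$dim,
                           as.integer(kernel_radius), disc$ng)
  coords <- which(mask$voxels > 0, arr.ind = TRUE)
  # cpp_local_stats walks x-fastest (column-major), same order as which()
  raw <- cbind(intensity = image$voxels[mask$voxels > 0],
               local_mean = stats[, 1], local_variance = stats[, 2],
               local_energy = stats[, 3], local_entropy = stats[, 4],
               local_uniformity = stats[, 5])
  bad <- setdiff(features, colnames(raw))
  if (length(bad)) stopf("unknown voxel feature(s): %s",
                         paste(bad, collapse = ", "))
  sel <- raw[, features, drop = FALSE]
  ctr <- colMeans(sel)
  scl <- apply(sel, 2, sd)
  x <- sweep(sel, 2, ctr)
  pos <- scl > 1e-12
  x[, pos] <- sweep(x[, pos, drop = FALSE], 2, scl[pos], `/`)
  x[, !pos] <- 0
  structure(list(x = x, raw = raw, coords = coords, center = ctr,
                 scale = scl, dim = dim(mask$voxels)),
            class = "voxel_feature_matrix")
}

#' K-means clustering of voxel feature maps
#'
#' k-means with k-means++-style multi-restart initialisation (`nstart`
#' random restarts, deterministic under `seed`).
#'
#' @param vfm A `voxel_feature_matrix` (or plain numeric matrix).
#' @param k Number of clusters (1 <= k <= rows).
#' @param seed Integer seed.
#' @param nstart,iter.max Restart count and iteration cap.
#' @return List with `labels` (1..k per row) and `tot_withinss`.
#' @export
kmeans_cluster <- function(vfm, k, seed = 1L, nstart = 10L, iter.max = 300L) {
  x <- if (inherits(vfm, "voxel_feature_matrix")) vfm$x else as.matrix(vfm)
  n <- nrow(x)
  if (k < 1) stopf("`k` must be >= 1")
  if (k > n) stopf("k = %d exceeds the number of voxels (%d)", k, n)
  if (k == 1) return(list(labels = rep(1L, n),
                          tot_withinss = sum(scale(x, scale = FALSE)^2)))
  set.seed(child_seed(seed, "kmeans", k))
  km <- tryCatch(
    suppressWarnings(kmeans(x, centers = k, nstart = nstart,
                            iter.max = iter.max)),
    error = function(e) NULL)
  if (is.null(km)) {
    # fewer distinct rows than centers: each distinct row is its own cluster
    key <- do.call(paste, as.data.frame(x))
    labs <- as.integer(factor(key, levels = unique(key)))
    return(list(labels = labs, tot_withinss = 0))
  }
  list(labels = as.integer(km$cluster), tot_withinss = km$tot.withinss)
}

#' Calinski-Harabasz index
#'
#' `CH = (B / (K - 1)) / (W / (n - K))` where B is the between-cluster and W
#' the within-cluster dispersion about the respective centroids. Perfectly
#' tight clusters (W = 0) return `Inf` as a documented sentinel.
#'
#' @param vfm A `voxel_feature_matrix` or numeric matrix.
#' @param labels Integer cluster labels (2 <= K <= n - 1).
#' @return The CH score (scalar).
#' @export
calinski_harabasz <- function(vfm, labels) {
  x <- if (inherits(vfm, "voxel_feature_matrix")) vfm$x else as.matrix(vfm)
  n <- nrow(x)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2 || K > n - 1) stopf("need 2 <= K <= n - 1 clusters")
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (g in ks) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(xi, 2, ci)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Select the habitat count by the Calinski-Harabasz elbow
#'
#' Clusters the voxel features for each K in `k_min..k_max`, scores each
#' partition with the CH index and picks the elbow: the K of maximum
#' concavity of the CH curve, `2 CH(K) - CH(K-1) - CH(K+1)`, with the curve
#' extended flat at both ends, so an endpoint is the elbow exactly when the
#' curve falls away from it (ties break to the smaller K). If some partition is perfectly tight (CH = Inf), the
#' smallest such K wins; a featureless curve (no concave point) falls back
#' to `k_min` with a warning.
#'
#' @param vfm A `voxel_feature_matrix`.
#' @param k_min,k_max Candidate range (defaults 2 and 10).
#' @param seed Integer seed threaded to each k-means run.
#' @param nstart Restarts per k-means run.
#' @return List with `k` (the selected K) and `ch_curve`
#'   (data frame `k`, `score`).
#' @export
select_optimal_k <- function(vfm, k_min = 2L, k_max = 10L, seed = 1L,
                             nstart = 10L) {
  x <- if (inherits(vfm, "voxel_feature_matrix")) vfm$x else as.matrix(vfm)
  n <- nrow(x)
  k_max <- min(k_max, n - 1L)
  if (k_min > k_max) stopf("k_min exceeds the feasible maximum (%d)", k_max)
  if (nrow(unique(x)) < 2) {
    warnf("voxel features are constant; falling back to k_min = %d", k_min)
    return(list(k = as.integer(k_min),
                ch_curve = data.frame(k = k_min, score = NA_real_)))
  }
  ks <- k_min:k_max
  scores <- vapply(ks, function(k) {
    cl <- kmeans_cluster(x, k, seed = seed, nstart = nstart)
    calinski_harabasz(x, cl$labels)
  }, 0)
  curve <- data.frame(k = ks, score = scores)
  if (any(is.infinite(scores))) {
    return(list(k = ks[which(is.infinite(scores))[1]], ch_curve = curve))
  }
  padded <- c(scores[1], scores, scores[length(scores)])
  concavity <- vapply(seq_along(ks), function(i) {
    2 * padded[i + 1] - padded[i] - padded[i + 2]
  }, 0)
  if (all(concavity <= 0)) {
    warnf("CH curve has no elbow; falling back to k_min = %d", k_min)
    return(list(k = ks[1], ch_curve = curve))
  }
  list(k = ks[which.max(concavity)], ch_curve = curve)
}

#' Build ordered habitat masks from cluster labels
#'
#' Converts per-voxel cluster labels into K disjoint binary masks whose
#' union is the ROI, deterministically ordered h1..hK by descending mean
#' original intensity — so the pipeline is invariant to the clusterer's
#' arbitrary label permutation.
#'
#' @param image The original `image_volume` (used for the ordering rule).
#' @param mask The ROI `binary_mask`.
#' @param labels Integer labels, one per in-mask voxel (order of `which`).
#' @return List with `masks` (list of `binary_mask`), `map` (integer array,
#'   0 outside, ordered habitat index inside) and `k`.
#' @export
build_habitat_masks <- function(image, mask, labels) {
  check_geometry(image, mask)
  sel <- mask$voxels > 0
  if (length(labels) != sum(sel))
    stopf("labels (%d) do not cover the ROI voxels (%d)",
          length(labels), sum(sel))
  vals <- image$voxels[sel]
  ks <- sort(unique(labels))
  means <- vapply(ks, function(g) mean(vals[labels == g]), 0)
  ord <- ks[order(-means)]
  remap <- integer(max(ks))
  remap[ord] <- seq_along(ord)
  new_lab <- remap[labels]
  map <- array(0L, dim(mask$voxels))
  map[sel] <- new_lab
  masks <- lapply(seq_along(ord), function(h) {
    binary_mask(array(as.numeric(map == h), dim(map)), mask$spacing,
                mask$origin)
  })
  list(masks = masks, map = map, k = length(ord))
}

#' Habitat-wise feature extraction
#'
#' Extracts the 1820 non-shape features from each habitat mask; names are
#' suffixed `_h1`, `_h2`, ... in habitat order. Habitats below
#' `min_voxels` yield missing values (imputed later at the cohort table
#' level).
#'
#' @param image An `image_volume`.
#' @param habitat_masks List of disjoint `binary_mask`s (from
#'   [build_habitat_masks()]).
#' @param min_voxels Minimum habitat size for extraction (default 10).
#' @param bin_width Passed to [extract_features()].
#' @return Named numeric vector of `1820 * length(habitat_masks)` features.
#' @export
extract_habitat_features <- function(image, habitat_masks, min_voxels = 10L,
                                     bin_width = 25) {
  if (!length(habitat_masks)) stopf("need at least one habitat mask")
  out <- NULL
  template <- NULL
  for (h in seq_along(habitat_masks)) {
    mk <- habitat_masks[[h]]
    nv <- sum(mk$voxels)
    if (nv >= min_voxels) {
      f <- extract_features(image, mk, include_shape = FALSE,
                            bin_width = bin_width)
      template <- names(f)
    } else {
      if (is.null(template)) {
        ok <- which(vapply(habitat_masks, function(m) sum(m$voxels), 0) >=
                      min_voxels)[1]
        if (is.na(ok)) stopf("all habitats are below min_voxels = %d",
                             min_voxels)
        template <- names(extract_features(image, habitat_masks[[ok]],
                                           include_shape = FALSE,
                                           bin_width = bin_width))
      }
      f <- stats::setNames(rep(NA_real_, length(template)), template)
    }
    names(f) <- paste0(names(f), "_h", h)
    out <- c(out, f)
  }
  out
}

#' One-call habitat segmentation of a lesion
#'
#' Voxel feature maps, K selection (or a fixed K), clustering and ordered
#' mask construction.
#'
#' @param image An `image_volume`.
#' @param mask The ROI `binary_mask`.
#' @param k Fixed habitat count, or `NULL` to select by the CH elbow.
#' @param k_min,k_max CH search range when `k` is `NULL`.
#' @param kernel_radius Neighbourhood radius for the voxel maps.
#' @param seed Integer seed.
#' @return As [build_habitat_masks()], plus `ch_curve` when K was selected.
#' @export
segment_habitats <- function(image, mask, k = NULL, k_min = 2L, k_max = 10L,
                             kernel_radius = 1L, seed = 1L) {
  vfm <- voxel_feature_maps(image, mask, kernel_radius = kernel_radius)
  ch <- NULL
  if (is.null(k)) {
    sel <- select_optimal_k(vfm, k_min, k_max, seed = seed)
    k <- sel$k
    ch <- sel$ch_curve
  }
  cl <- kmeans_cluster(vfm, k, seed = seed)
  hb <- build_habitat_masks(image, mask, cl$labels)
  hb$ch_curve <- ch
  hb
}
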