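test_that("voxel feature maps satisfy the row and ramp contracts", {
  les <- generate_lesion(small_phantom(seed = 2))
  vfm <- voxel_feature_maps(les$image, les$mask)
  expect_equal(nrow(vfm$x), sum(les$mask$voxels))
  expect_false(anyNA(vfm$x))
  # constant image: z-scored matrix identically zero
  cimg <- image_volume(array(12, dim(les$mask$voxels)))
  vc <- voxel_feature_maps(cimg, les$mask,
                           features = c("intensity", "local_mean",
                                        "local_variance", "local_entropy"))
  expect_true(all(vc$x == 0))
  # linear ramp: interior local mean equals the ramp itself
  d <- c(9, 9, 9)
  ramp <- image_volume(array(rep(seq_len(d[1]), times = prod(d[2:3])), d))
  allm <- binary_mask(array(1, d))
  vr <- voxel_feature_maps(ramp, allm)
  interior <- vr$coords[, 1] > 1 & vr$coords[, 1] < 9 &
    vr$coords[, 2] > 1 & vr$coords[, 2] < 9 &
    vr$coords[, 3] > 1 & vr$coords[, 3] < 9
  expect_equal(vr$raw[interior, "local_mean"],
               vr$raw[interior, "intensity"], tolerance = 1e-12)
})

test_that("k-means separates well-separated blobs and W shrinks with K", {
  set.seed(42)
  x <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
             matrix(rnorm(200, 8, 0.1), ncol = 2))
  truth <- rep(1:2, each = 100)
  cl <- kmeans_cluster(x, 2, seed = 3)
  expect_equal(adjusted_rand(truth, cl$labels), 1)
  w <- vapply(1:6, function(k) kmeans_cluster(x, k, seed = 3)$tot_withinss, 0)
  expect_true(all(diff(w) <= 1e-8))
  expect_error(kmeans_cluster(x, nrow(x) + 1, seed = 1), "exceeds")
  expect_equal(unique(kmeans_cluster(x, 1, seed = 1)$labels), 1L)
})

test_that("the CH index matches its brute-force formula and conventions", {
  # perfectly tight clusters: +Inf sentinel
  x0 <- matrix(c(0, 0, 0, 10, 10, 10), ncol = 1)
  expect_identical(calinski_harabasz(x0, rep(1:2, each = 3)), Inf)
  # jittered version: compare against an independent direct evaluation
  x <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), ncol = 1)
  lab <- rep(1:2, each = 3)
  ch <- calinski_harabasz(x, lab)
  m1 <- mean(x[1:3]); m2 <- mean(x[4:6]); g <- mean(x)
  B <- 3 * (m1 - g)^2 + 3 * (m2 - g)^2
  W <- sum((x[1:3] - m1)^2) + sum((x[4:6] - m2)^2)
  expect_equal(ch, (B / 1) / (W / 4))
  # label permutation symmetry
  expect_equal(calinski_harabasz(x, 3 - lab), ch)
  # random labels on iid noise score near 1 on average
  set.seed(7)
  vals <- replicate(60, {
    xx <- matrix(rnorm(120), ncol = 2)
    calinski_harabasz(xx, sample(1:3, 60, replace = TRUE))
  })
  expect_lt(abs(mean(vals) - 1), 0.25)
})

test_that("the CH elbow recovers the planted habitat count", {
  hit2 <- 0; hit4 <- 0
  for (s in 1:4) {
    sp2 <- phantom_spec(k_true = 2, habitat_means = c(-30, 80),
                        habitat_texture_scales = c(1.5, 3), seed = 300 + s)
    les2 <- generate_lesion(sp2)
    v2 <- voxel_feature_maps(les2$image, les2$mask)
    hit2 <- hit2 + (select_optimal_k(v2, seed = s)$k == 2)
    sp4 <- phantom_spec(seed = 400 + s)
    les4 <- generate_lesion(sp4)
    v4 <- voxel_feature_maps(les4$image, les4$mask)
    hit4 <- hit4 + (select_optimal_k(v4, seed = s)$k == 4)
  }
  expect_gte(hit2, 3)
  expect_gte(hit4, 3)
})

test_that("noiseless phantoms cluster perfectly on intensity", {
  les <- generate_lesion(phantom_spec(noise_sd = 0))
  vfm <- voxel_feature_maps(les$image, les$mask, features = "intensity")
  cl <- kmeans_cluster(vfm, 4, seed = 1)
  gt <- les$habitat_map[les$mask$voxels > 0]
  expect_equal(adjusted_rand(gt, cl$labels), 1)
})

test_that("constant voxel features fall back to k_min with a warning", {
  les <- generate_lesion(small_phantom(seed = 1))
  cimg <- image_volume(array(1, dim(les$mask$voxels)))
  vfm <- voxel_feature_maps(cimg, les$mask)
  expect_warning(sel <- select_optimal_k(vfm, seed = 1), "constant|elbow")
  expect_equal(sel$k, 2L)
})

test_that("habitat masks partition the ROI in intensity order", {
  les <- generate_lesion(small_phantom(seed = 6, k_true = 3))
  vfm <- voxel_feature_maps(les$image, les$mask)
  cl <- kmeans_cluster(vfm, 3, seed = 2)
  hb <- build_habitat_masks(les$image, les$mask, cl$labels)
  expect_equal(hb$k, 3)
  un <- Reduce(`+`, lapply(hb$masks, function(m) m$voxels))
  expect_equal(un, les$mask$voxels)
  means <- vapply(hb$masks, function(m) mean(les$image$voxels[m$voxels > 0]), 0)
  expect_true(all(diff(means) <= 0))
  # permuting the clusterer's label ids leaves h1..hK unchanged
  perm <- c(3L, 1L, 2L)[cl$labels]
  hb2 <- build_habitat_masks(les$image, les$mask, perm)
  expect_identical(hb2$map, hb$map)
})

test_that("habitat features carry the _h suffix and K=4 gives 7280", {
  les <- generate_lesion(small_phantom(seed = 8, k_true = 2))
  hb <- segment_habitats(les$image, les$mask, k = 2, seed = 1)
  f <- extract_habitat_features(les$image, hb$masks)
  expect_length(f, 2 * 1820)
  expect_true(all(grepl("_h[12]$", names(f))))
  # identical content in two habitats gives identical values
  m <- les$mask
  f2 <- extract_habitat_features(les$image, list(m, m))
  expect_equal(unname(f2[seq_len(1820)]), unname(f2[1820 + seq_len(1820)]))
  # tiny habitat: missing values, not errors
  tiny <- array(0, dim(m$voxels)); tiny[10, 10, 10] <- 1
  f3 <- extract_habitat_features(les$image,
                                 list(m, binary_mask(tiny)))
  expect_true(all(is.na(f3[1820 + seq_len(1820)])))
})
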