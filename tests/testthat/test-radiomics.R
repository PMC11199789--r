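test_that("the filter bank returns exactly 20 named volumes, original first", {
  img <- image_volume(array(rnorm(10^3, 0, 50), c(10, 10, 10)))
  bank <- apply_filter_bank(img)
  expect_length(bank, 20)
  expect_identical(names(bank)[1], "original")
  expect_identical(anyDuplicated(names(bank)), 0L)
  expect_true(all(vapply(bank, function(v) identical(dim(v$voxels),
                                                     c(10L, 10L, 10L)), TRUE)))
})

test_that("a constant image kills wavelet details, gradients and LoG", {
  img <- image_volume(array(5, c(8, 8, 8)))
  bank <- apply_filter_bank(img)
  for (nm in grep("wavelet\\..*H", names(bank), value = TRUE)) {
    expect_true(all(abs(bank[[nm]]$voxels) < 1e-10), info = nm)
  }
  expect_true(all(abs(bank$gradient$voxels) < 1e-10))
  for (nm in grep("^log\\.", names(bank), value = TRUE)) {
    expect_true(all(abs(bank[[nm]]$voxels) < 1e-8), info = nm)
  }
})

test_that("discretization follows the floor/bin-width contract", {
  msk <- binary_mask(array(1, c(101, 1, 1)))
  img <- image_volume(array(0:100, c(101, 1, 1)))
  d <- discretize(img, msk, bin_width = 25)
  expect_equal(d$ng, 5L)
  expect_equal(min(d$levels[d$levels > 0]), 1L)
  # range smaller than one bin collapses to a single level
  img2 <- image_volume(array(c(10, 34), c(2, 1, 1)))
  msk2 <- binary_mask(array(1, c(2, 1, 1)))
  d2 <- discretize(img2, msk2, bin_width = 25)
  expect_equal(d2$ng, 1L)
  # constant region
  d3 <- discretize(image_volume(array(3, c(3, 3, 3))),
                   binary_mask(array(1, c(3, 3, 3))))
  expect_equal(d3$ng, 1L)
})

test_that("first-order features match hand computations", {
  msk <- binary_mask(array(1, c(4, 1, 1)))
  img <- image_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  f <- first_order(img, msk)
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Variance"]), 1.25)
  expect_equal(unname(f["firstorder_Range"]), 3)
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(mean((1:4)^2)))

  cimg <- image_volume(array(7, c(3, 3, 3)))
  cmsk <- binary_mask(array(1, c(3, 3, 3)))
  fc <- first_order(cimg, cmsk)
  expect_equal(unname(fc["firstorder_Mean"]), 7)
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Entropy"]), 0)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)
  expect_equal(unname(fc["firstorder_Skewness"]), 0)
  expect_equal(unname(fc["firstorder_Energy"]), 27 * 49)

  ones <- image_volume(array(1, c(3, 3, 3)))
  expect_equal(unname(first_order(ones, cmsk)["firstorder_Energy"]), 27)
})

test_that("shape descriptors are accurate on a digital sphere", {
  d <- c(25, 25, 25)
  u <- habitatr:::ellipsoid_radius(d, c(1, 1, 1), c(10, 10, 10))
  msk <- binary_mask(array(as.numeric(u <= 1), d))
  sh <- shape3d(msk)
  expect_length(sh, 14)
  expect_gte(unname(sh["shape_Sphericity"]), 0.97)
  expect_lte(unname(sh["shape_Sphericity"]), 1.0)
  vol_true <- 4 / 3 * pi * 1000
  expect_lt(abs(sh[["shape_MeshVolume"]] - vol_true) / vol_true, 0.03)
  expect_equal(unname(sh["shape_Maximum3DDiameter"]), 20, tolerance = 0.1)
  expect_equal(unname(sh["shape_Elongation"]), 1, tolerance = 0.05)
})

test_that("shape volume and surface scale as a similarity transform", {
  d1 <- c(13, 13, 13)
  u1 <- habitatr:::ellipsoid_radius(d1, c(1, 1, 1), c(5, 5, 5))
  m1 <- binary_mask(array(as.numeric(u1 <= 1), d1))
  d2 <- c(25, 25, 25)
  u2 <- habitatr:::ellipsoid_radius(d2, c(1, 1, 1), c(10, 10, 10))
  m2 <- binary_mask(array(as.numeric(u2 <= 1), d2))
  s1 <- shape3d(m1); s2 <- shape3d(m2)
  expect_equal(s2[["shape_MeshVolume"]] / s1[["shape_MeshVolume"]], 8,
               tolerance = 0.10)
  expect_equal(s2[["shape_SurfaceArea"]] / s1[["shape_SurfaceArea"]], 4,
               tolerance = 0.10)
})

test_that("single-voxel masks return degenerate but finite descriptors", {
  arr <- array(0, c(5, 5, 5)); arr[3, 3, 3] <- 1
  sh <- shape3d(binary_mask(arr))
  expect_true(all(is.finite(sh)))
  expect_equal(unname(sh[c("shape_MajorAxisLength", "shape_Maximum3DDiameter")]),
               c(0, 0))
  expect_equal(unname(sh["shape_Elongation"]), 1)
})

test_that("the whole-ROI record has exactly 1834 features, 1820 without shape", {
  les <- generate_lesion(small_phantom(seed = 5))
  f <- extract_features(les$image, les$mask, include_shape = TRUE)
  expect_length(f, 1834)
  expect_identical(anyDuplicated(names(f)), 0L)
  expect_true(all(is.finite(f)))
  f2 <- extract_features(les$image, les$mask, include_shape = FALSE)
  expect_length(f2, 1820)
  cls <- sub("^.*_(shape|firstorder|glcm|glrlm|glszm|ngtdm|gldm)_.*$", "\\1",
             names(f2))
  expect_equal(unname(table(cls)[c("firstorder", "glcm", "glrlm", "glszm",
                                   "ngtdm", "gldm")]),
               c(360L, 440L, 320L, 320L, 100L, 280L),
               ignore_attr = TRUE)
  expect_error(extract_features(les$image,
                                binary_mask(array(0, dim(les$mask$voxels))),
                                include_shape = FALSE),
               "empty")
})

test_that("features are invariant to grid translation and intensity shift", {
  # lesion placed so the crop window (bounding box + margin) is interior to
  # both grids, making the cropped content identical up to translation
  sp <- phantom_spec(grid_shape = c(24, 24, 24), lesion_radii = c(7, 6.5, 6),
                     k_true = 2, habitat_means = c(-40, 80),
                     habitat_texture_scales = c(1.5, 3), noise_sd = 8,
                     seed = 9)
  les <- generate_lesion(sp)
  f0 <- extract_features(les$image, les$mask, include_shape = FALSE)
  # translate the lesion within a larger grid
  big <- array(-800, c(32, 32, 32))
  bigm <- array(0, c(32, 32, 32))
  big[4:27, 3:26, 5:28] <- les$image$voxels
  bigm[4:27, 3:26, 5:28] <- les$mask$voxels
  f1 <- extract_features(image_volume(big), binary_mask(bigm),
                         include_shape = FALSE)
  expect_equal(f1, f0, tolerance = 1e-12)
  # adding a constant leaves all texture classes unchanged (min-shifted bins)
  shifted <- image_volume(les$image$voxels + 100, les$image$spacing)
  fs <- extract_features(shifted, les$mask, include_shape = FALSE)
  tex <- grep("^original_(glcm|glrlm|glszm|ngtdm|gldm)_", names(f0),
              value = TRUE)
  expect_equal(fs[tex], f0[tex], tolerance = 1e-10)
})
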