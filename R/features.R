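#' Extract the full radiomic feature record of one ROI
#'
#' Runs the complete inventory: 14 shape descriptors on the original mask
#' (once, optional), and for each of the 20 filter-bank volumes the 18
#' first-order plus 22 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM texture
#' descriptors — 1834 features with shape, 1820 without. Feature names follow
#' `<imagetype>_<class>_<feature>`. The pair is cropped to the mask bounding
#' box (4-voxel margin) before filtering, which makes every feature invariant
#' to mask-preserving translations of the grid.
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask` on the identical grid.
#' @param include_shape Compute shape features? Use `FALSE` for habitat
#'   subregions, where 3D shape is not meaningful.
#' @param bin_width Discretization width for original-HU intensities
#'   (default 25 HU; derived images use range/32).
#' @param crop_margin Bounding-box margin in voxels before filtering.
#' @return Named numeric vector of length 1834 (or 1820).
#' @export
extract_features <- function(image, mask, include_shape = TRUE,
                             bin_width = 25, crop_margin = 4L) {
  check_geometry(image, mask)
  if (sum(mask$voxels) == 0) stopf("cannot extract features from an empty mask")
  cr <- crop_to_roi(image, mask, crop_margin)
  out <- if (include_shape) shape3d(cr$mask) else NULL
  bank <- apply_filter_bank(cr$image)
  for (nm in names(bank)) {
    vol <- bank[[nm]]
    disc <- discretize(vol, cr$mask,
                       bin_width = if (identical(nm, "original")) bin_width
                                   else NULL,
                       image_type = nm)
    fo <- first_order(vol, cr$mask, disc)
    tex <- c(glcm_features(disc), glrlm_features(disc), glszm_features(disc),
             ngtdm_features(disc), gldm_features(disc))
    block <- c(fo, tex)
    names(block) <- paste(nm, names(block), sep = "_")
    out <- c(out, block)
  }
  if (include_shape) {
    names(out)[seq_len(14)] <- paste0("original_", names(out)[seq_len(14)])
  }
  out
}

#' Feature inventory sizes
#'
#' Per-class descriptor counts and the number of derived image types of the
#' configured extractor; the products give the printed inventory (18 x 20 =
#' 360 first-order, 22 x 20 = 440 GLCM, and so on).
#'
#' @return Named integer vector.
#' @export
feature_inventory <- function() {
  c(image_types = 20L, shape = 14L, firstorder = 18L, glcm = 22L,
    glrlm = 16L, glszm = 16L, ngtdm = 5L, gldm = 14L)
}
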