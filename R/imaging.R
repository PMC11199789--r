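#' Image volume and binary mask containers
#'
#' An `image_volume` is a 3D scalar grid of attenuation values (HU) with
#' physical voxel spacing in mm; a `binary_mask` is a co-registered
#' region-of-interest grid with values in \{0, 1\}. All geometry is carried in
#' mm; voxel centres sit at `origin + (index - 1) * spacing`.
#'
#' @param voxels 3D numeric array.
#' @param spacing Positive numeric triple, voxel spacing in mm.
#' @param origin Numeric triple, world coordinate of the first voxel centre.
#' @return An object of class `image_volume` or `binary_mask`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stopf("`voxels` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("`spacing` must be a positive mm triple")
  if (!all(is.finite(voxels))) stopf("voxel values must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stopf("`voxels` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("`spacing` must be a positive mm triple")
  v <- array(as.numeric(voxels != 0), dim(voxels))
  structure(list(voxels = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @method print image_volume
#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @method print binary_mask
#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$voxels > 0)))
  invisible(x)
}

# Enforce that an image/mask pair lives on the identical grid.
check_geometry <- function(image, mask) {
  di <- dim(image$voxels); dm <- dim(mask$voxels)
  if (!identical(di, dm))
    stopf("geometry mismatch: image grid %s vs mask grid %s",
          paste(di, collapse = "x"), paste(dm, collapse = "x"))
  if (max(abs(image$spacing - mask$spacing)) > 1e-6)
    stopf("geometry mismatch: image spacing (%s) vs mask spacing (%s)",
          paste(signif(image$spacing, 6), collapse = ", "),
          paste(signif(mask$spacing, 6), collapse = ", "))
  invisible(TRUE)
}

#' Read and write volumes and masks as NIfTI
#'
#' NIfTI (`.nii` / `.nii.gz`) is the supported on-disk format; voxel spacing
#' travels in the header `pixdim`. Masks are binarized on read (any nonzero
#' voxel becomes 1).
#'
#' @param path Path to a NIfTI file.
#' @param x An `image_volume` or `binary_mask`.
#' @return `read_volume` returns an `image_volume`; `read_mask` a
#'   `binary_mask`; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("missing or invalid voxel spacing in %s", path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  image_volume(arr, spacing = sp)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  m <- binary_mask(vol$voxels, spacing = vol$spacing, origin = vol$origin)
  if (sum(m$voxels) == 0) stopf("mask %s has no foreground voxels", path)
  m
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(x, path) write_volume(x, path)

#' Resample an image/mask pair to a target grid
#'
#' Both members are resampled onto the identical target grid: the image by
#' trilinear interpolation, the mask by nearest neighbour followed by
#' re-binarization, so the mask stays strictly binary. The default 1 mm
#' isotropic grid is the conventional radiomics working resolution.
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask`.
#' @param target_spacing Positive mm triple (default `c(1, 1, 1)`).
#' @return A list with resampled `image` and `mask`.
#' @export
resample_pair <- function(image, mask, target_spacing = c(1, 1, 1)) {
  check_geometry(image, mask)
  if (any(target_spacing <= 0)) stopf("target spacing must be positive")
  if (max(abs(image$spacing - target_spacing)) < 1e-9)
    return(list(image = image, mask = mask))
  d <- dim(image$voxels)
  nd <- pmax(2L, as.integer(round(d * image$spacing / target_spacing)))
  img2 <- interp_resample(image$voxels, image$spacing, nd, target_spacing,
                          method = "linear")
  msk2 <- interp_resample(mask$voxels, mask$spacing, nd, target_spacing,
                          method = "nearest")
  msk2 <- array(as.numeric(msk2 >= 0.5), dim(msk2))
  if (sum(msk2) == 0)
    stopf("resampling to %s mm emptied the mask; use a finer target spacing",
          paste(target_spacing, collapse = "x"))
  list(image = image_volume(img2, target_spacing, image$origin),
       mask = binary_mask(msk2, target_spacing, mask$origin))
}

# Vectorised grid resampling (trilinear or nearest neighbour), voxel-centre
# aligned: output centre i maps to world (i-1)*target.
interp_resample <- function(a, spacing, new_dim, target, method = "linear") {
  d <- dim(a)
  gx <- (seq_len(new_dim[1]) - 1) * target[1] / spacing[1] + 1
  gy <- (seq_len(new_dim[2]) - 1) * target[2] / spacing[2] + 1
  gz <- (seq_len(new_dim[3]) - 1) * target[3] / spacing[3] + 1
  if (method == "nearest") {
    ix <- pmin(pmax(round(gx), 1), d[1])
    iy <- pmin(pmax(round(gy), 1), d[2])
    iz <- pmin(pmax(round(gz), 1), d[3])
    return(a[ix, iy, iz, drop = FALSE])
  }
  x0 <- pmin(pmax(floor(gx), 1), d[1] - 1); fx <- pmin(pmax(gx - x0, 0), 1)
  y0 <- pmin(pmax(floor(gy), 1), d[2] - 1); fy <- pmin(pmax(gy - y0, 0), 1)
  z0 <- pmin(pmax(floor(gz), 1), d[3] - 1); fz <- pmin(pmax(gz - z0, 0), 1)
  if (d[1] == 1) { x0 <- rep(1, length(gx)); fx <- rep(0, length(gx)) }
  if (d[2] == 1) { y0 <- rep(1, length(gy)); fy <- rep(0, length(gy)) }
  if (d[3] == 1) { z0 <- rep(1, length(gz)); fz <- rep(0, length(gz)) }
  FX <- array(fx, new_dim)
  FY <- array(rep(fy, each = new_dim[1]), new_dim)
  FZ <- array(rep(fz, each = new_dim[1] * new_dim[2]), new_dim)
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  g <- function(ix, iy, iz) a[ix, iy, iz, drop = FALSE]
  g(x0, y0, z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
    g(x1, y0, z0) * FX * (1 - FY) * (1 - FZ) +
    g(x0, y1, z0) * (1 - FX) * FY * (1 - FZ) +
    g(x1, y1, z0) * FX * FY * (1 - FZ) +
    g(x0, y0, z1) * (1 - FX) * (1 - FY) * FZ +
    g(x1, y0, z1) * FX * (1 - FY) * FZ +
    g(x0, y1, z1) * (1 - FX) * FY * FZ +
    g(x1, y1, z1) * FX * FY * FZ
}

#' Crop an image/mask pair to the mask bounding box
#'
#' @param image An `image_volume`.
#' @param mask The paired `binary_mask` (must be nonempty).
#' @param margin_voxels Non-negative integer margin added on every side,
#'   clipped to the grid.
#' @return A list with cropped `image` and `mask`.
#' @export
crop_to_roi <- function(image, mask, margin_voxels = 0L) {
  check_geometry(image, mask)
  idx <- which(mask$voxels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("cannot crop: mask is empty")
  d <- dim(mask$voxels)
  lo <- pmax(apply(idx, 2, min) - margin_voxels, 1)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  sel <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  new_origin <- image$origin + (lo - 1) * image$spacing
  list(image = image_volume(image$voxels[sel[[1]], sel[[2]], sel[[3]],
                                         drop = FALSE],
                            image$spacing, new_origin),
       mask = binary_mask(mask$voxels[sel[[1]], sel[[2]], sel[[3]],
                                      drop = FALSE],
                          mask$spacing, new_origin))
}
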