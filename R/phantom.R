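#' Synthetic CT lesion phantoms with planted habitat structure
#'
#' `phantom_spec()` describes a single ellipsoidal lesion embedded in a
#' chest-CT-like background: `k_true` planted habitats (concentric shells by
#' default, mimicking perfusion-driven core/rim heterogeneity; wedge sectors
#' optionally) with distinct mean attenuation and texture correlation length,
#' plus additive white acquisition noise. Habitat texture is correlated
#' Gaussian noise produced by smoothing white noise with a per-habitat kernel,
#' so habitats differ in local texture as well as in mean HU. The texture
#' amplitude defaults to `1.5 * noise_sd`, so a noiseless phantom is exactly
#' piecewise constant.
#'
#' @param grid_shape Integer triple, voxel grid size.
#' @param spacing mm triple.
#' @param lesion_radii mm triple of ellipsoid semi-axes.
#' @param k_true Number of planted habitats (>= 1).
#' @param habitat_means Mean attenuation (HU) per habitat, length `k_true`.
#' @param habitat_texture_scales Texture correlation length (mm) per habitat.
#' @param noise_sd White acquisition noise SD in HU (>= 0).
#' @param texture_sd Texture field SD in HU; default `1.5 * noise_sd`.
#' @param background_mean Background attenuation (HU), lung-like by default.
#' @param layout `"shells"` (concentric, default) or `"wedges"` (angular
#'   sectors about the z axis).
#' @param seed Integer seed; lesion generation is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(28L, 28L, 28L),
                         spacing = c(1, 1, 1),
                         lesion_radii = c(10, 9, 8),
                         k_true = 4L,
                         habitat_means = c(-60, 10, 60, 110),
                         habitat_texture_scales = c(1.5, 2.5, 3.5, 4.5),
                         noise_sd = 10,
                         texture_sd = NULL,
                         background_mean = -800,
                         layout = c("shells", "wedges"),
                         seed = 1L) {
  layout <- match.arg(layout)
  k_true <- as.integer(k_true)
  if (k_true < 1L) stopf("`k_true` must be >= 1")
  if (length(habitat_means) != k_true ||
      length(habitat_texture_scales) != k_true)
    stopf("`habitat_means` and `habitat_texture_scales` must have length k_true (%d)",
          k_true)
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (any(spacing <= 0)) stopf("`spacing` must be positive")
  if (any(lesion_radii <= 0)) stopf("`lesion_radii` must be positive")
  # the ellipsoid (centred) must fit strictly inside the grid
  if (any(2 * lesion_radii / spacing > grid_shape - 2))
    stopf("lesion of semi-axes (%s) mm does not fit inside a %s grid at %s mm",
          paste(lesion_radii, collapse = ", "),
          paste(grid_shape, collapse = "x"),
          paste(spacing, collapse = "x"))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 lesion_radii = as.numeric(lesion_radii),
                 k_true = k_true,
                 habitat_means = as.numeric(habitat_means),
                 habitat_texture_scales = as.numeric(habitat_texture_scales),
                 noise_sd = as.numeric(noise_sd),
                 texture_sd = if (is.null(texture_sd)) 1.5 * noise_sd
                              else as.numeric(texture_sd),
                 background_mean = as.numeric(background_mean),
                 layout = layout,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized ellipsoid radius u(x) so that {u <= 1} is the lesion.
ellipsoid_radius <- function(grid_shape, spacing, radii) {
  ctr <- (grid_shape + 1) / 2
  cx <- (seq_len(grid_shape[1]) - ctr[1]) * spacing[1] / radii[1]
  cy <- (seq_len(grid_shape[2]) - ctr[2]) * spacing[2] / radii[2]
  cz <- (seq_len(grid_shape[3]) - ctr[3]) * spacing[3] / radii[3]
  sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
}

#' Generate a synthetic lesion
#'
#' @param spec A [phantom_spec()].
#' @param fractions Optional habitat volume fractions (length `k_true`,
#'   positive, normalised internally); equal fractions by default.
#' @return A list with `image` (an `image_volume`), `mask` (a `binary_mask`)
#'   and `habitat_map` (integer array; 0 outside the lesion, 1..k inside —
#'   the ground-truth habitat of every lesion voxel).
#' @export
generate_lesion <- function(spec, fractions = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  k <- spec$k_true
  f <- fractions %||% rep(1 / k, k)
  if (length(f) != k || any(f <= 0)) stopf("`fractions` must be %d positive values", k)
  f <- f / sum(f)
  u <- ellipsoid_radius(spec$grid_shape, spec$spacing, spec$lesion_radii)
  inside <- u <= 1
  n_in <- sum(inside)
  if (n_in < k)
    stopf("k_true = %d exceeds the lesion voxel count (%d)", k, n_in)
  hab <- array(0L, spec$grid_shape)
  if (spec$layout == "shells") {
    # habitat 1 is the core; shell boundaries chosen so shell k holds
    # volume fraction f[k] of the ellipsoid: r_k = (cumsum f)^(1/3)
    bounds <- c(0, cumsum(f)^(1 / 3))
    bounds[k + 1] <- 1
    lab <- findInterval(u[inside], bounds, rightmost.closed = TRUE,
                        all.inside = TRUE)
  } else {
    ctr <- (spec$grid_shape + 1) / 2
    ang <- atan2(
      rep(rep((seq_len(spec$grid_shape[2]) - ctr[2]), each = spec$grid_shape[1]),
          times = spec$grid_shape[3]),
      rep((seq_len(spec$grid_shape[1]) - ctr[1]),
          times = spec$grid_shape[2] * spec$grid_shape[3]))
    ang <- array(ang, spec$grid_shape)
    bounds <- -pi + 2 * pi * c(0, cumsum(f))
    bounds[k + 1] <- pi
    lab <- findInterval(ang[inside], bounds, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  hab[inside] <- lab
  # every habitat must own at least one voxel; steal from the largest if not
  for (j in seq_len(k)) {
    if (!any(lab == j)) {
      big <- which.max(tabulate(lab, k))
      swap <- which(lab == big)[1]
      lab[swap] <- j
      hab[inside] <- lab
    }
  }
  set.seed(child_seed(spec$seed, "lesion"))
  img <- array(spec$background_mean, spec$grid_shape)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(spec$grid_shape), 0, spec$noise_sd),
                       spec$grid_shape)
  for (j in seq_len(k)) {
    sel <- inside & hab == j
    img[sel] <- spec$habitat_means[j]
    if (spec$texture_sd > 0) {
      w <- array(rnorm(prod(spec$grid_shape)), spec$grid_shape)
      w <- gaussian_smooth(w, spec$habitat_texture_scales[j] / spec$spacing)
      w <- w / max(sd(w), 1e-12)
      img[sel] <- img[sel] + spec$texture_sd * w[sel]
    }
    if (spec$noise_sd > 0)
      img[sel] <- img[sel] + rnorm(sum(sel), 0, spec$noise_sd)
  }
  list(image = image_volume(img, spec$spacing),
       mask = binary_mask(array(as.numeric(inside), spec$grid_shape),
                          spec$spacing),
       habitat_map = hab)
}

#' Cohort of synthetic lesions with a planted class effect
#'
#' `cohort_spec()` describes a two-class cohort in which the response class
#' (pCR) differs from the non-response class in its habitat structure, via
#' two coupled channels both scaled by `effect`:
#' * a *composition* shift — class-1 lesions have their habitat
#'   log-volume-fractions tilted along a linear core-to-rim contrast;
#' * a *marginal-neutral attenuation redistribution* — per-habitat means are
#'   shifted along the same contrast (`30 * effect` HU at the extremes) with
#'   zero pooled-mean footprint, emulating perfusion redistribution between
#'   core and rim;
#' At `effect = 0` both channels vanish and the cohort is an exact null.
#'
#' Lesion size, composition, a global attenuation offset (scanner-like
#' variation, `center_sd`) and the per-habitat attenuation levels themselves
#' (biological variability, `habitat_mean_sd`, independent per habitat and
#' subject) are jittered per subject.
#'
#' @param n Number of subjects (>= 2).
#' @param pcr_fraction Prevalence of the positive (pCR) class; default 0.36.
#' @param effect Non-negative composition shift between classes.
#' @param base A [phantom_spec()] giving the cohort-level lesion template.
#' @param habitat_mean_sd SD (HU) of independent per-subject, per-habitat
#'   attenuation jitter (default 5).
#' @param center_sd SD (HU) of the per-subject global attenuation offset
#'   emulating scanner/contrast-timing variation across centers; it decoheres
#'   whole-lesion marginal intensity statistics so the class signal is the
#'   habitat composition itself, as in a multicenter setting.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, pcr_fraction = 0.36, effect = 0.25,
                        base = phantom_spec(), center_sd = 15,
                        habitat_mean_sd = 5, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stopf("`n` must be >= 2")
  if (pcr_fraction < 0 || pcr_fraction > 1)
    stopf("`pcr_fraction` must lie in [0, 1]")
  if (effect < 0) stopf("`effect` must be >= 0")
  n_pos <- round(n * pcr_fraction)
  if (pcr_fraction > 0 && pcr_fraction < 1 && (n_pos == 0 || n_pos == n))
    stopf("n = %d with pcr_fraction = %.2f leaves a class empty", n, pcr_fraction)
  if (center_sd < 0) stopf("`center_sd` must be >= 0")
  if (habitat_mean_sd < 0) stopf("`habitat_mean_sd` must be >= 0")
  structure(list(n = n, pcr_fraction = pcr_fraction, effect = effect,
                 base = base, center_sd = center_sd,
                 habitat_mean_sd = habitat_mean_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @return `generate_cohort()` returns a list with `lesions` (list of
#'   [generate_lesion()] results), `labels` (0/1 integer vector, 1 = pCR) and
#'   `ids` (subject identifiers).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_pos <- round(spec$n * spec$pcr_fraction)
  set.seed(child_seed(spec$seed, "cohort"))
  labels <- sample(rep(c(1L, 0L), c(n_pos, spec$n - n_pos)))
  k <- spec$base$k_true
  contrast <- if (k > 1) seq(-0.5, 0.5, length.out = k) else 0
  lesions <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    set.seed(child_seed(spec$seed, "subject", i))
    radii <- spec$base$lesion_radii * runif(3, 0.85, 1.15)
    hu_offset <- rnorm(1, 0, spec$center_sd %||% 15)
    logf <- rep(0, k) + rnorm(k, 0, 0.15)
    if (labels[i] == 1L) logf <- logf + spec$effect * contrast
    f <- exp(logf) / sum(exp(logf))
    sp_i <- spec$base
    sp_i$lesion_radii <- radii
    sp_i$habitat_means <- spec$base$habitat_means + hu_offset +
      rnorm(k, 0, spec$habitat_mean_sd %||% 5)
    if (labels[i] == 1L && k > 1) {
      # zero-sum redistribution of attenuation along the core-rim contrast
      shift <- 60 * spec$effect * contrast
      sp_i$habitat_means <- sp_i$habitat_means + shift - sum(f * shift)
    }
    sp_i$background_mean <- spec$base$background_mean + hu_offset
    sp_i$seed <- child_seed(spec$seed, "noise", i)
    class(sp_i) <- "phantom_spec"
    lesions[[i]] <- generate_lesion(sp_i, fractions = f)
  }
  list(lesions = lesions, labels = labels,
       ids = sprintf("P%03d", seq_len(spec$n)))
}

#' Simulate a second rater's segmentation
#'
#' Perturbs a binary mask by moving its boundary by up to `boundary_jitter`
#' mm: the mask is smoothed with a Gaussian of width `boundary_jitter` and
#' re-thresholded with a randomly shifted, spatially varying threshold, which
#' dilates or erodes the boundary locally. Used to emulate re-segmentation
#' for ICC robustness studies.
#'
#' @param mask A `binary_mask`.
#' @param boundary_jitter Boundary displacement bound in mm (>= 0); 0 returns
#'   the mask unchanged.
#' @param seed Integer seed.
#' @return A perturbed `binary_mask` overlapping the original.
#' @export
perturb_mask <- function(mask, boundary_jitter, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (boundary_jitter < 0) stopf("`boundary_jitter` must be >= 0")
  if (sum(mask$voxels) == 0) stopf("mask is empty")
  if (boundary_jitter == 0) return(mask)
  r_eq <- (3 * sum(mask$voxels) * prod(mask$spacing) / (4 * pi))^(1 / 3)
  if (boundary_jitter >= r_eq)
    stopf("jitter of %.1f mm reaches the lesion's equivalent radius (%.1f mm); the mask would not survive",
          boundary_jitter, r_eq)
  set.seed(child_seed(seed, "perturb"))
  smooth <- gaussian_smooth(mask$voxels, boundary_jitter / mask$spacing)
  field <- gaussian_smooth(array(rnorm(length(mask$voxels)), dim(mask$voxels)),
                           3 / mask$spacing)
  field <- field / max(sd(field), 1e-12)
  shift <- runif(1, -0.2, 0.2)
  pert <- smooth + 0.1 * field
  out <- array(as.numeric(pert > 0.5 + shift), dim(mask$voxels))
  if (sum(out) == 0 || sum(out * mask$voxels) == 0)
    stopf("jitter of %.1f mm destroyed the mask (no overlap with original)",
          boundary_jitter)
  binary_mask(out, mask$spacing, mask$origin)
}
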