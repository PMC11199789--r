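#' Pipeline configuration
#'
#' One place for every tunable of the two experiment arms. All stochastic
#' stages (k-means restarts, CV folds, phantoms) derive their streams from
#' the single `seed`.
#'
#' @param target_spacing Resampling grid (mm triple).
#' @param bin_width Original-HU discretization width.
#' @param kernel_radius Voxel-map neighbourhood radius.
#' @param k_range Candidate habitat counts for CH selection.
#' @param fixed_k Fix the habitat count cohort-wide (skips CH selection);
#'   `NULL` selects it on a training calibration subset.
#' @param n_calibration Training lesions used to calibrate K (majority vote).
#' @param icc_threshold,alpha,r_threshold,folds Selection-cascade settings.
#' @param min_habitat_voxels Below this size a habitat's features are missing.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_spacing = c(1, 1, 1), bin_width = 25,
                            kernel_radius = 1L, k_range = 2:10,
                            fixed_k = NULL, n_calibration = 12L,
                            icc_threshold = 0.75, alpha = 0.05,
                            r_threshold = 0.9, folds = 10L,
                            min_habitat_voxels = 10L, seed = 1L) {
  stopifnot(icc_threshold >= 0, icc_threshold <= 1, alpha > 0, alpha < 1,
            r_threshold > 0, r_threshold <= 1, folds >= 2)
  structure(list(target_spacing = target_spacing, bin_width = bin_width,
                 kernel_radius = as.integer(kernel_radius),
                 k_range = as.integer(k_range), fixed_k = fixed_k,
                 n_calibration = as.integer(n_calibration),
                 icc_threshold = icc_threshold, alpha = alpha,
                 r_threshold = r_threshold, folds = as.integer(folds),
                 min_habitat_voxels = as.integer(min_habitat_voxels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Assemble a samples x features table from per-sample named vectors.
bind_feature_rows <- function(rows, ids) {
  nms <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[nms]))
  rownames(mat) <- ids
  colnames(mat) <- nms
  mat
}

#' Whole-ROI radiomics arm
#'
#' The conventional arm: extracts the 1834-feature whole-ROI record for each
#' lesion, fits the selection cascade + logistic model on the training
#' split, and evaluates both splits. The split is an explicit input, never
#' randomized internally.
#'
#' @param cohort A [generate_cohort()] result (or a list with `lesions`,
#'   `labels`, `ids`).
#' @param split Character/factor vector per sample: `"train"` or
#'   `"validation"`.
#' @param config A [pipeline_config()].
#' @param icc_keep Optional ICC-retained feature names (see
#'   [run_icc_study()]).
#' @return List with `model` (a `pcr_model`), `train` and `validation`
#'   (`eval_report`s) and `features` (the full table).
#' @export
run_radiomics_arm <- function(cohort, split, config = pipeline_config(),
                              icc_keep = NULL) {
  rows <- lapply(cohort$lesions, function(l) {
    extract_features(l$image, l$mask, include_shape = TRUE,
                     bin_width = config$bin_width)
  })
  feats <- bind_feature_rows(rows, cohort$ids)
  fit_and_eval(feats, cohort$labels, split, config, icc_keep)
}

#' Habitat (intratumoral heterogeneity) arm
#'
#' The habitat arm: voxel-wise feature maps, per-lesion K-means habitat
#' partitioning (K fixed cohort-wide, either from `config$fixed_k` or
#' calibrated by majority CH-elbow vote over the first training lesions),
#' intensity-ordered habitat masks, and the 1820-per-habitat feature table
#' feeding the identical cascade and logistic model as the radiomics arm.
#'
#' @inheritParams run_radiomics_arm
#' @return As [run_radiomics_arm()], plus `k` (habitat count used).
#' @export
run_habitat_arm <- function(cohort, split, config = pipeline_config(),
                            icc_keep = NULL) {
  k <- config$fixed_k
  if (is.null(k)) {
    tr <- which(split == "train")
    cal <- tr[seq_len(min(config$n_calibration, length(tr)))]
    votes <- vapply(cal, function(i) {
      l <- cohort$lesions[[i]]
      vfm <- voxel_feature_maps(l$image, l$mask,
                                kernel_radius = config$kernel_radius,
                                bin_width = config$bin_width)
      select_optimal_k(vfm, min(config$k_range), max(config$k_range),
                       seed = child_seed(config$seed, "kselect", i))$k
    }, 0L)
    tab <- table(votes)
    k <- as.integer(names(tab)[which.max(tab)])
  }
  rows <- lapply(seq_along(cohort$lesions), function(i) {
    l <- cohort$lesions[[i]]
    hb <- segment_habitats(l$image, l$mask, k = k,
                           kernel_radius = config$kernel_radius,
                           seed = child_seed(config$seed, "habitat", i))
    extract_habitat_features(l$image, hb$masks,
                             min_voxels = config$min_habitat_voxels,
                             bin_width = config$bin_width)
  })
  feats <- bind_feature_rows(rows, cohort$ids)
  out <- fit_and_eval(feats, cohort$labels, split, config, icc_keep)
  out$k <- k
  out
}

fit_and_eval <- function(feats, labels, split, config, icc_keep) {
  stopifnot(length(split) == nrow(feats))
  tr <- split == "train"
  warnings_seen <- character(0)
  model <- withCallingHandlers(
    pcr_model(feats[tr, , drop = FALSE], labels[tr],
              alpha = config$alpha, r_threshold = config$r_threshold,
              folds = config$folds, icc_keep = icc_keep,
              seed = config$seed),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(model = model,
       train = evaluate_model(model, feats[tr, , drop = FALSE], labels[tr]),
       validation = if (any(!tr))
         evaluate_model(model, feats[!tr, , drop = FALSE], labels[!tr])
       else NULL,
       features = feats,
       manifest = run_manifest(config, feats, model, warnings_seen))
}

# Deterministic provenance record: content hashes of the inputs and the
# fitted model, so identical seed + config reruns are verifiable.
run_manifest <- function(config, feats, model, warnings_seen = character(0)) {
  list(package_version = as.character(utils::packageVersion("habitatr")),
       config_hash = object_checksum(config),
       feature_checksum = object_checksum(feats),
       model_checksum = object_checksum(list(model$coefficients,
                                             model$selection$stages,
                                             model$threshold)),
       n_features = ncol(feats),
       warnings = warnings_seen)
}

object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Segmentation-robustness (ICC) study
#'
#' Re-draws each of `n_cases` lesion masks with [perturb_mask()] (emulating a
#' second rater), extracts the features of the chosen arm from both
#' segmentations and retains the features with ICC(2,1) at or above the
#' configured threshold. For the habitat arm the whole per-lesion habitat
#' pipeline (voxel maps, clustering, ordered masks) is re-run on the
#' perturbed segmentation, so clustering instability is part of what the
#' filter measures.
#'
#' @param cohort A [generate_cohort()] result.
#' @param n_cases Number of cases to use (default 50).
#' @param boundary_jitter Mask perturbation amplitude in mm.
#' @param config A [pipeline_config()].
#' @param arm `"radiomics"` (whole-ROI, with shape) or `"habitat"`.
#' @param k Habitat count for `arm = "habitat"`.
#' @param include_shape Extract shape features (radiomics arm only).
#' @return List with `retained` (feature names) and `icc` (per-feature).
#' @export
run_icc_study <- function(cohort, n_cases = 50L, boundary_jitter = 1,
                          config = pipeline_config(),
                          arm = c("radiomics", "habitat"), k = 4L,
                          include_shape = TRUE) {
  arm <- match.arg(arm)
  if (n_cases > length(cohort$lesions))
    stopf("n_cases = %d exceeds the cohort size (%d)", n_cases,
          length(cohort$lesions))
  idx <- seq_len(n_cases)
  one <- function(l, mask, i) {
    if (arm == "radiomics") {
      extract_features(l$image, mask, include_shape = include_shape,
                       bin_width = config$bin_width)
    } else {
      hb <- segment_habitats(l$image, mask, k = k,
                             kernel_radius = config$kernel_radius,
                             seed = child_seed(config$seed, "habitat", i))
      extract_habitat_features(l$image, hb$masks,
                               min_voxels = config$min_habitat_voxels,
                               bin_width = config$bin_width)
    }
  }
  r1 <- list(); r2 <- list()
  for (i in idx) {
    l <- cohort$lesions[[i]]
    m2 <- perturb_mask(l$mask, boundary_jitter,
                       seed = child_seed(config$seed, "icc", i))
    r1[[i]] <- one(l, l$mask, i)
    r2[[i]] <- one(l, m2, i)
  }
  v1 <- bind_feature_rows(r1, cohort$ids[idx])
  v2 <- bind_feature_rows(r2, cohort$ids[idx])
  # features missing for some case (empty habitat) cannot be assessed
  ok <- colSums(is.na(v1)) == 0 & colSums(is.na(v2)) == 0
  icc_filter(v1[, ok, drop = FALSE], v2[, ok, drop = FALSE],
             threshold = config$icc_threshold)
}
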