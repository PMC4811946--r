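#' Specify an implanted region-of-interest effect
#'
#' Describes one spherical region in which the texture of the affected
#' group's volumes is altered. Three effect kinds are supported:
#' \describe{
#'   \item{`"variance-scale"`}{the local noise standard deviation is
#'     multiplied by `magnitude` (e.g. 3 means a 3-fold SD increase; values
#'     below 1 reduce local variance).}
#'   \item{`"correlation-length"`}{the noise inside the sphere is replaced by
#'     a Gaussian-smoothed copy with kernel SD `magnitude` voxels, increasing
#'     spatial correlation and lowering local contrast.}
#'   \item{`"mean-shift"`}{`magnitude` intensity units are added inside the
#'     sphere.}
#' }
#' A magnitude of exactly 0 disables the effect (null region), whatever the
#' kind.
#'
#' @param center integer vector of length 3, sphere centre in voxel indices
#'   (1-based).
#' @param radius sphere radius in voxels.
#' @param group which group carries the effect, `"patient"` or `"control"`.
#' @param kind effect kind, see Details.
#' @param magnitude effect magnitude (units depend on `kind`).
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(center, radius, group = "patient",
                     kind = c("variance-scale", "correlation-length", "mean-shift"),
                     magnitude = 3) {
  kind <- match.arg(kind)
  group <- match.arg(group, c("patient", "control"))
  stopifnot(length(center) == 3, radius >= 1, is.finite(magnitude))
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 group = group, kind = kind, magnitude = magnitude),
            class = "roi_spec")
}

#' Configure a synthetic two-group cohort
#'
#' Defines a case-control cohort of MNI-like T1 volumes: a smooth,
#' deterministic pseudo-anatomical baseline inside an ellipsoidal brain mask,
#' plus stationary Gaussian noise. Patient volumes differ from controls only
#' inside the configured ROI spheres, where the noise field is altered
#' according to each [roi_spec()]. Symptom duration is drawn uniformly over
#' `duration_range` for patients, and the per-patient effect magnitude is
#' `magnitude + clinical_link * duration`, so a positive `clinical_link`
#' implants a recoverable texture-duration correlation.
#'
#' Ages are drawn once and shared between the groups, and sexes alternate
#' within each group, so both covariates are balanced by construction (they
#' still exercise covariate adjustment downstream).
#'
#' Volumes emulate intensity-standardized input: the baseline is rescaled so
#' its in-mask range spans a fixed window slightly wider than `[0, 255]` and
#' the final volumes are clipped to `[0, 255]`. Every subject therefore
#' attains the same in-mask minimum and maximum, so per-volume equal-width
#' quantization uses identical bin edges across subjects — as it would after
#' the intensity standardization such pipelines assume. The default ROI sits
#' in a mid-intensity region away from the clipped caps.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param volume_shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size numeric length 3, mm per voxel along each axis.
#' @param roi_specs list of [roi_spec()] objects; may be empty.
#' @param noise_sd SD of the stationary intensity noise.
#' @param baseline_smoothness FWHM (mm) of the baseline pseudo-anatomy blobs.
#' @param age_range,duration_range uniform sampling ranges (years; months).
#' @param clinical_link slope tying duration (months) to effect magnitude.
#' @param seed integer master seed; identical seed and config give a
#'   bit-identical cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 20,
                          volume_shape = c(24, 24, 24),
                          voxel_size = c(1, 1, 1),
                          roi_specs = list(roi_spec(center = c(8, 12, 12), radius = 4)),
                          noise_sd = 10,
                          baseline_smoothness = 12,
                          age_range = c(25, 80),
                          duration_range = c(9, 72),
                          clinical_link = 0,
                          seed = 1) {
  stopifnot(n_per_group >= 2, length(volume_shape) == 3, all(volume_shape >= 8),
            length(voxel_size) == 3, all(voxel_size > 0),
            noise_sd > 0, baseline_smoothness > 0,
            diff(age_range) > 0, diff(duration_range) > 0)
  if (length(roi_specs) > 0 && !all(vapply(roi_specs, inherits, TRUE, "roi_spec")))
    stop("roi_specs must be a list of roi_spec() objects")
  cfg <- structure(list(
    n_per_group = as.integer(n_per_group),
    volume_shape = as.integer(volume_shape),
    voxel_size = as.numeric(voxel_size),
    roi_specs = roi_specs,
    noise_sd = noise_sd,
    baseline_smoothness = baseline_smoothness,
    age_range = as.numeric(age_range),
    duration_range = as.numeric(duration_range),
    clinical_link = clinical_link,
    seed = as.integer(seed)), class = "cohort_config")

  mask <- brain_mask(cfg$volume_shape)
  for (s in roi_specs) {
    rm_ <- sphere_mask(cfg$volume_shape, s$center, s$radius)
    if (!any(rm_)) stop("ROI sphere at (", paste(s$center, collapse = ","),
                        ") contains no voxels")
    if (any(rm_ & !mask))
      stop("ROI sphere at (", paste(s$center, collapse = ","),
           ") extends outside the brain mask")
  }
  cfg
}

#' Ellipsoidal brain mask for a synthetic volume
#'
#' Semi-axes are 0.45 of the grid extent along each axis, centred in the
#' volume — a cheap stand-in for a brain outline that leaves an out-of-mask
#' rim to exercise edge handling.
#'
#' @param shape integer vector of length 3.
#' @return A logical 3D array.
#' @export
brain_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  i <- (seq_len(shape[1]) - ctr[1]) / semi[1]
  j <- (seq_len(shape[2]) - ctr[2]) / semi[2]
  k <- (seq_len(shape[3]) - ctr[3]) / semi[3]
  d2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(d2 <= 1, dim = shape)
}

sphere_mask <- function(shape, center, radius) {
  i <- seq_len(shape[1]) - center[1]
  j <- seq_len(shape[2]) - center[2]
  k <- seq_len(shape[3]) - center[3]
  d2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(d2 <= radius^2, dim = shape)
}

# Deterministic pseudo-anatomy: a fixed set of low-frequency 3D Gaussian
# blobs at fractional positions, widths tied to baseline_smoothness (mm).
baseline_volume <- function(shape, voxel_size, smoothness_mm) {
  centers <- rbind(c(0.50, 0.50, 0.50),
                   c(0.32, 0.42, 0.60),
                   c(0.68, 0.42, 0.60),
                   c(0.50, 0.65, 0.35),
                   c(0.45, 0.30, 0.40))
  amps <- c(60, 35, 35, 25, 20)
  sigma_mm <- smoothness_mm / 2.3548 * c(2.5, 1.4, 1.4, 1.2, 1.0)
  out <- array(50, dim = shape)
  mm <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * voxel_size[a])
  for (b in seq_along(amps)) {
    ctr <- centers[b, ] * vapply(1:3, function(a) max(mm[[a]]), 0)
    g1 <- exp(-(mm[[1]] - ctr[1])^2 / (2 * sigma_mm[b]^2))
    g2 <- exp(-(mm[[2]] - ctr[2])^2 / (2 * sigma_mm[b]^2))
    g3 <- exp(-(mm[[3]] - ctr[3])^2 / (2 * sigma_mm[b]^2))
    out <- out + amps[b] * outer(outer(g1, g2), g3)
  }
  out
}

# Separable Gaussian smoothing of a 3D array (kernel SD in voxels per axis);
# edge rows of each 1D kernel matrix are renormalized.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    n <- dim(arr)[axis]
    K <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a deterministic toy volume
#'
#' Small analytic fixtures for exercising the texture engine: a constant
#' block, a 3D checkerboard (voxel value chosen by the parity of the index
#' sum), a linear ramp along the first axis, or white Gaussian noise.
#'
#' @param pattern one of `"constant"`, `"checkerboard"`, `"ramp"`,
#'   `"white-noise"`.
#' @param shape integer vector of length 3.
#' @param levels intensity values: `constant` uses `levels[1]`;
#'   `checkerboard` alternates `levels[1]` (even parity) and `levels[2]`;
#'   `ramp` runs linearly from `levels[1]` to `levels[2]`; `white-noise`
#'   draws N(`levels[1]`, `levels[2]`^2).
#' @param seed integer seed, required for `"white-noise"`.
#' @return A numeric 3D array.
#' @export
generate_toy_volume <- function(pattern, shape, levels = c(0, 1), seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  shape <- as.integer(shape)
  switch(pattern,
    "constant" = array(levels[1], dim = shape),
    "checkerboard" = {
      par <- outer(outer(seq_len(shape[1]), seq_len(shape[2]), `+`),
                   seq_len(shape[3]), `+`) %% 2
      array(ifelse(par == 1, levels[1], levels[2]), dim = shape)
    },
    "ramp" = {
      ramp <- seq(levels[1], levels[2], length.out = shape[1])
      array(ramp, dim = shape)
    },
    "white-noise" = {
      if (is.null(seed)) stop("white-noise pattern requires a seed")
      sdv <- if (length(levels) >= 2) levels[2] else 1
      with_seed(seed, array(rnorm(prod(shape), levels[1], sdv), dim = shape))
    },
    stop("unknown pattern: ", pattern)
  )
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Draws the full cohort defined by a [cohort_config()]: per-subject volumes
#' (baseline + noise, with ROI effects applied to patients' noise fields),
#' the brain mask and affine, a subject table, and a ground-truth object
#' holding the ROI masks, expected effect directions and the true clinical
#' scores.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `volumes` (list of 3D arrays, controls then
#'   patients), `mask`, `affine`, `subjects` (data frame with columns
#'   subject_id, group, age_years, sex, duration_months, alsfrs, fi_left,
#'   fi_right), and `truth` (list: roi_masks, effect_directions,
#'   clinical_table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  shape <- config$volume_shape
  n <- config$n_per_group
  mask <- brain_mask(shape)
  base <- baseline_volume(shape, config$voxel_size, config$baseline_smoothness)
  # emulate intensity standardization: fixed window, clipped caps at both ends
  rng <- range(base[mask])
  base <- (base - rng[1]) / (rng[2] - rng[1]) * 320 - 30
  roi_masks <- lapply(config$roi_specs, function(s)
    sphere_mask(shape, s$center, s$radius))

  with_seed(config$seed, {
    ages <- round(runif(n, config$age_range[1], config$age_range[2]), 1)
    sex_c <- rep_len(c(0L, 1L), n)
    sex_p <- rep_len(c(1L, 0L), n)
    duration <- round(runif(n, config$duration_range[1], config$duration_range[2]), 1)
    alsfrs <- pmin(40, pmax(0, round(40 - 0.25 * duration + rnorm(n, 0, 2))))
    fi_c_l <- round(rnorm(n, 55, 5), 1)
    fi_c_r <- round(rnorm(n, 55, 5), 1)
    fi_p_l <- round(pmax(5, 55 - 0.3 * duration + rnorm(n, 0, 5)), 1)
    fi_p_r <- round(pmax(5, 55 - 0.3 * duration + rnorm(n, 0, 5)), 1)

    make_subject <- function(group_id, idx) {
      noise <- array(rnorm(prod(shape), 0, config$noise_sd), dim = shape)
      affected <- c("control", "patient")[group_id + 1L]
      for (r in seq_along(config$roi_specs)) {
        s <- config$roi_specs[[r]]
        if (s$group != affected) next
        mag <- s$magnitude +
          if (affected == "patient") config$clinical_link * duration[idx] else 0
        if (mag == 0) next
        rm_ <- roi_masks[[r]]
        noise <- switch(s$kind,
          "variance-scale" = { noise[rm_] <- noise[rm_] * mag; noise },
          "mean-shift" = { noise[rm_] <- noise[rm_] + mag; noise },
          "correlation-length" = {
            sm <- gaussian_smooth_3d(noise, mag)
            noise[rm_] <- sm[rm_]
            noise
          })
      }
      vol <- pmin(pmax(base + noise, 0), 255)
      vol[!mask] <- 0
      vol
    }

    volumes <- c(lapply(seq_len(n), function(i) make_subject(0L, i)),
                 lapply(seq_len(n), function(i) make_subject(1L, i)))
  })

  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(2 * n)),
    group = rep(c(0L, 1L), each = n),
    age_years = c(ages, ages),
    sex = c(sex_c, sex_p),
    duration_months = c(rep(NA_real_, n), duration),
    alsfrs = c(rep(NA_real_, n), alsfrs),
    fi_left = c(fi_c_l, fi_p_l),
    fi_right = c(fi_c_r, fi_p_r),
    stringsAsFactors = FALSE
  )

  mean_dur <- mean(config$duration_range)
  dirs <- vapply(config$roi_specs, function(s) {
    mag <- s$magnitude + if (s$group == "patient") config$clinical_link * mean_dur else 0
    switch(s$kind,
      "variance-scale" = if (mag > 1) 1 else -1,
      "mean-shift" = sign(mag),
      "correlation-length" = -1)
  }, 0)

  if (length(roi_masks) > 1) {
    overlap <- Reduce(`+`, lapply(roi_masks, as.numeric))
    if (any(overlap > 1)) stop("ROI spheres overlap; ground-truth masks must be disjoint")
  }

  clinical_table <- data.frame(
    subject_id = subjects$subject_id[subjects$group == 1L],
    duration_months = duration,
    stringsAsFactors = FALSE
  )
  for (r in seq_along(config$roi_specs)) {
    s <- config$roi_specs[[r]]
    clinical_table[[paste0("magnitude_roi", r)]] <-
      if (s$group == "patient") s$magnitude + config$clinical_link * duration
      else 0
  }

  list(volumes = volumes,
       mask = mask,
       affine = make_affine(shape, config$voxel_size),
       subjects = subjects,
       truth = list(roi_masks = roi_masks,
                    effect_directions = dirs,
                    clinical_table = clinical_table))
}

#' Build a centred scaling affine for a synthetic grid
#'
#' Diagonal voxel-size scaling with the world origin at the volume centre;
#' maps 0-based voxel indices to mm, following the NIfTI convention.
#'
#' @param shape integer vector of length 3.
#' @param voxel_size mm per voxel along each axis.
#' @return A 4x4 numeric matrix.
#' @export
make_affine <- function(shape, voxel_size = c(1, 1, 1)) {
  A <- diag(c(voxel_size, 1))
  A[1:3, 4] <- -voxel_size * (shape - 1) / 2
  A
}

#' Write a synthetic cohort to disk as a fixture set
#'
#' Generates the cohort and writes one NIfTI volume per subject, the brain
#' mask, the subject table CSV and a ground-truth JSON, plus a manifest.
#'
#' @param dir output directory (created if needed).
#' @param config a [cohort_config()].
#' @return Invisibly, a manifest list: `volumes`, `mask`, `subjects`,
#'   `ground_truth` (paths) and `seed`.
#' @export
write_fixture_set <- function(dir, config = cohort_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  cohort <- generate_cohort(config)

  vol_paths <- file.path(dir, paste0(cohort$subjects$subject_id, "_T1w.nii.gz"))
  for (i in seq_along(cohort$volumes))
    write_nifti_volume(cohort$volumes[[i]], cohort$affine, vol_paths[i])
  mask_path <- file.path(dir, "brain_mask.nii.gz")
  write_nifti_volume(cohort$mask * 1, cohort$affine, mask_path)

  subj_path <- file.path(dir, "subjects.csv")
  write.csv(cohort$subjects, subj_path, row.names = FALSE)

  gt_path <- file.path(dir, "ground_truth.json")
  gt <- list(
    seed = config$seed,
    rois = lapply(seq_along(config$roi_specs), function(r) {
      s <- config$roi_specs[[r]]
      list(center = s$center, radius = s$radius, group = s$group,
           kind = s$kind, magnitude = s$magnitude,
           direction = cohort$truth$effect_directions[r],
           n_voxels = sum(cohort$truth$roi_masks[[r]]))
    }),
    clinical_table = cohort$truth$clinical_table
  )
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)

  invisible(list(volumes = vol_paths, mask = mask_path,
                 subjects = subj_path, ground_truth = gt_path,
                 seed = config$seed))
}

# Write a 3D array as NIfTI with the given 0-based-index affine.
write_nifti_volume <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
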