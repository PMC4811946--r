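TEXTURE_FEATURES <- c("auto", "savg", "sosv", "svar")

#' GLCM computation parameters
#'
#' Parameters of the per-voxel co-occurrence analysis. Defaults match the
#' standard configuration for whole-brain T1 texture mapping: 8 gray levels,
#' a 3x3 in-plane neighbourhood (radius 1), co-occurrence distance 1, and no
#' post-smoothing of the maps.
#'
#' @param n_levels number of quantization levels Ng (>= 2).
#' @param radius in-plane neighbourhood half-width r in voxels (>= 1); the
#'   patch is (2r+1) x (2r+1).
#' @param distance co-occurrence offset d in voxels; must satisfy
#'   `1 <= d <= 2 * radius` or no pair fits inside the patch.
#' @param smoothing FWHM (in voxels) of an optional Gaussian post-filter
#'   applied to the finished texture maps; 0 disables it.
#' @return A list of class `glcm_params`. The four in-plane directions
#'   (0, 45, 90, 135 degrees) are always accumulated into one symmetric
#'   matrix per plane.
#' @export
glcm_params <- function(n_levels = 8, radius = 1, distance = 1, smoothing = 0) {
  stopifnot(n_levels >= 2, radius >= 1, smoothing >= 0)
  if (distance < 1 || distance > 2 * radius)
    stop("distance must satisfy 1 <= distance <= 2*radius")
  structure(list(n_levels = as.integer(n_levels), radius = as.integer(radius),
                 distance = as.integer(distance), smoothing = smoothing,
                 directions = rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))),
            class = "glcm_params")
}

#' Quantize an intensity volume to gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_levels` bins:
#' the in-mask minimum maps to level 1, the maximum to level `n_levels`
#' (upper bin edge inclusive). Out-of-mask voxels become `NA`. A constant
#' in-mask volume maps everywhere to level 1.
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D array of the same shape.
#' @param n_levels number of gray levels.
#' @return A list of class `quantized_volume`: `levels` (integer array, NA
#'   outside the mask), `mask`, `bin_edges` (length `n_levels + 1`),
#'   `n_levels`.
#' @export
quantize_volume <- function(volume, mask, n_levels = 8) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  if (is.null(dim(mask)) || !all(dim(mask) == dim(volume)))
    stop("mask must be a 3D array matching the volume shape")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  vals <- volume[mask]
  if (!all(is.finite(vals))) stop("non-finite intensities inside the mask")
  n_levels <- as.integer(n_levels)
  rng <- range(vals)
  lev <- array(NA_integer_, dim = dim(volume))
  if (rng[1] == rng[2]) {
    lev[mask] <- 1L
    edges <- seq(rng[1], rng[1] + 1, length.out = n_levels + 1)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_levels + 1)
    idx <- floor((vals - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1
    lev[mask] <- as.integer(pmin(idx, n_levels))
  }
  structure(list(levels = lev, mask = mask, bin_edges = edges,
                 n_levels = n_levels), class = "quantized_volume")
}

plane_axes <- function(plane) {
  switch(plane,
         axial = c(1L, 2L),
         coronal = c(1L, 3L),
         sagittal = c(2L, 3L),
         stop("unknown plane: ", plane))
}

#' Accumulate the in-plane GLCM at one voxel
#'
#' Scans the (2r+1) x (2r+1) patch centred on `center` in the requested
#' orthogonal plane and counts every ordered pair of in-mask voxels
#' separated by one of the four in-plane directions at distance d; each pair
#' is added symmetrically (both (i,j) and (j,i)). Pairs with either endpoint
#' outside the volume, outside the patch, or outside the mask are dropped.
#'
#' Plane convention (grid axes of the array): axial = axes (1,2),
#' coronal = axes (1,3), sagittal = axes (2,3); for MNI-oriented input these
#' coincide with the anatomical planes.
#'
#' @param quantized a [quantize_volume()] result.
#' @param center integer voxel index (1-based, length 3); must be in-mask.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param params a [glcm_params()].
#' @return A list of class `glcm`: `p` (Ng x Ng normalized matrix; all zero
#'   when no pair exists), `pair_count` (contributing pairs before
#'   normalization).
#' @export
accumulate_plane_glcm <- function(quantized, center, plane, params = glcm_params()) {
  stopifnot(inherits(quantized, "quantized_volume"), length(center) == 3)
  center <- as.integer(center)
  dm <- dim(quantized$levels)
  if (any(center < 1) || any(center > dm)) stop("center outside the volume")
  if (!isTRUE(quantized$mask[center[1], center[2], center[3]]))
    stop("center voxel is outside the mask")
  ax <- plane_axes(plane)
  ng <- quantized$n_levels
  r <- params$radius
  d <- params$distance
  counts <- matrix(0, ng, ng)
  pair_count <- 0L
  for (u in -r:r) {
    for (v in -r:r) {
      a <- center
      a[ax[1]] <- a[ax[1]] + u
      a[ax[2]] <- a[ax[2]] + v
      if (any(a < 1) || any(a > dm)) next
      la <- quantized$levels[a[1], a[2], a[3]]
      if (is.na(la)) next
      for (q in seq_len(nrow(params$directions))) {
        uu <- u + params$directions[q, 1] * d
        vv <- v + params$directions[q, 2] * d
        if (abs(uu) > r || abs(vv) > r) next
        b <- center
        b[ax[1]] <- b[ax[1]] + uu
        b[ax[2]] <- b[ax[2]] + vv
        if (any(b < 1) || any(b > dm)) next
        lb <- quantized$levels[b[1], b[2], b[3]]
        if (is.na(lb)) next
        counts[la, lb] <- counts[la, lb] + 1
        counts[lb, la] <- counts[lb, la] + 1
        pair_count <- pair_count + 1L
      }
    }
  }
  p <- if (pair_count > 0) counts / sum(counts) else counts
  structure(list(p = p, pair_count = pair_count, n_levels = ng),
            class = "glcm")
}

#' Haralick-type features of a normalized GLCM
#'
#' With p(i,j) the normalized symmetric matrix over levels 1..Ng and
#' p_{x+y}(k) = sum over i+j = k of p(i,j):
#' \describe{
#'   \item{auto}{autocorrelation, sum of i*j*p(i,j) — regularity/linear
#'     dependency of neighbouring intensities.}
#'   \item{savg}{sum average, sum of k*p_{x+y}(k) — overall intensity level
#'     of the texture.}
#'   \item{sosv}{sum of squares variance, sum of (i - mu)^2 p(i,j) with mu
#'     the GLCM grand mean sum of i*p(i,j) — contrast about the mean level.}
#'   \item{svar}{sum variance, sum of (k - savg)^2 p_{x+y}(k), with the
#'     deviation centred on savg — joint spread of co-occurring levels.}
#' }
#'
#' @param glcm an [accumulate_plane_glcm()] result (or any list with a
#'   normalized `p` matrix and positive `pair_count`).
#' @return Named numeric vector `c(auto, savg, sosv, svar)`.
#' @export
glcm_features <- function(glcm) {
  if (is.null(glcm$pair_count) || glcm$pair_count <= 0)
    stop("GLCM has no contributing pairs")
  p <- glcm$p
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM is not normalized")
  ng <- nrow(p)
  i <- row(p)
  j <- col(p)
  auto <- sum(i * j * p)
  mu <- sum(i * p)
  sosv <- sum((i - mu)^2 * p)
  k <- 2:(2 * ng)
  psum <- vapply(k, function(kk) sum(p[i + j == kk]), 0)
  savg <- sum(k * psum)
  svar <- sum((k - savg)^2 * psum)
  c(auto = auto, savg = savg, sosv = sosv, svar = svar)
}

#' Compute all four per-voxel texture maps for one volume
#'
#' For every in-mask voxel the GLCM is accumulated in each of the three
#' orthogonal planes; features are computed per plane and averaged over the
#' planes with at least one valid pair. A voxel with zero pairs in all three
#' planes is `NA`. With `params$smoothing > 0` a Gaussian post-filter
#' (FWHM in voxels, NA-aware) is applied to each finished map.
#'
#' @param quantized a [quantize_volume()] result.
#' @param params a [glcm_params()].
#' @return Named list of four numeric 3D arrays (`auto`, `savg`, `sosv`,
#'   `svar`), NA where undefined.
#' @export
texture_maps <- function(quantized, params = glcm_params()) {
  stopifnot(inherits(quantized, "quantized_volume"))
  maps <- cpp_texture_maps(quantized$levels, dim(quantized$levels),
                           quantized$n_levels, params$radius, params$distance)
  if (params$smoothing > 0)
    maps <- lapply(maps, smooth_map, fwhm_vox = params$smoothing)
  maps
}

#' Per-voxel texture map for a single feature
#'
#' Convenience wrapper around [texture_maps()] returning one feature.
#'
#' @inheritParams texture_maps
#' @param feature one of `"auto"`, `"savg"`, `"sosv"`, `"svar"`.
#' @return Numeric 3D array, NA where undefined.
#' @export
voxel_texture_map <- function(quantized, feature, params = glcm_params()) {
  feature <- check_features(feature)
  texture_maps(quantized, params)[[feature]]
}

check_features <- function(features) {
  bad <- setdiff(features, TEXTURE_FEATURES)
  if (length(bad))
    stop("unknown texture feature(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(TEXTURE_FEATURES, collapse = ", "), ")")
  features
}

# NA-aware separable Gaussian smoothing of a map: smooth the zero-filled map
# and the indicator of defined voxels, then renormalize.
smooth_map <- function(map, fwhm_vox) {
  sigma <- fwhm_vox / 2.3548
  ok <- !is.na(map)
  filled <- map
  filled[!ok] <- 0
  num <- gaussian_smooth_3d(filled, sigma)
  den <- gaussian_smooth_3d(array(as.numeric(ok), dim = dim(map)), sigma)
  out <- num / den
  out[!ok] <- NA_real_
  out
}

#' Texture maps for a whole cohort
#'
#' Applies quantization and [texture_maps()] to each subject's volume
#' independently (per-volume equal-width binning), returning the requested
#' features. Subjects are processed in order but each is independent, so
#' permuting the input order permutes the output only.
#'
#' @param volumes named or unnamed list of numeric 3D arrays (or
#'   `niftiImage`s), one per subject.
#' @param mask logical 3D array shared by all subjects.
#' @param features character vector of feature names.
#' @param params a [glcm_params()].
#' @param verbose log one line per subject.
#' @return A list (one element per subject, names preserved) of named lists
#'   of 3D feature maps.
#' @export
cohort_texture_maps <- function(volumes, mask, features = TEXTURE_FEATURES,
                                params = glcm_params(), verbose = FALSE) {
  features <- check_features(features)
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("subject%03d", seq_along(volumes))
  out <- vector("list", length(volumes))
  names(out) <- ids
  for (s in seq_along(volumes)) {
    vol <- unclass(volumes[[s]])
    attributes(vol) <- list(dim = dim(volumes[[s]]))
    if (!all(dim(vol) == dim(mask)))
      stop("volume shape mismatch for subject ", ids[s], ": ",
           paste(dim(vol), collapse = "x"), " vs mask ",
           paste(dim(mask), collapse = "x"))
    q <- quantize_volume(vol, mask, params$n_levels)
    out[[s]] <- texture_maps(q, params)[features]
    if (verbose)
      message("texture: subject ", ids[s], " (", s, "/", length(volumes),
              "), ", sum(q$mask), " in-mask voxels")
  }
  out
}
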