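#' Build the group-comparison design matrix
#'
#' Intercept, binary group indicator, age and sex — the standard
#' covariate-adjusted two-group design. Age and sex enter as nuisance
#' covariates; the group column carries the effect of interest.
#'
#' @param subjects data frame with columns `group` (0/1), `age_years`,
#'   `sex` (0/1).
#' @return Numeric matrix with columns `intercept`, `group`, `age`, `sex`.
#' @export
build_design_matrix <- function(subjects) {
  req <- c("group", "age_years", "sex")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  g <- subjects$group
  if (!all(g %in% c(0, 1))) stop("group must be binary 0/1")
  X <- cbind(intercept = 1, group = as.numeric(g),
             age = as.numeric(subjects$age_years),
             sex = as.numeric(subjects$sex))
  rownames(X) <- subjects$subject_id
  X
}

#' Voxel-wise GLM with a partial F-test for the group effect
#'
#' At each voxel where every subject has a defined value, texture is
#' regressed on the design by ordinary least squares and the group effect is
#' tested with a partial F-test (full model vs. the design without the group
#' column), df (1, n - p). Since df1 = 1 this F equals the square of the
#' group-coefficient t statistic. Voxels missing in any subject are dropped
#' listwise and counted.
#'
#' @param maps list of per-subject 3D arrays (one feature), all on one grid.
#' @param design design matrix from [build_design_matrix()] (or any
#'   full-rank matrix with a binary column named `"group"`).
#' @return A list of class `stat_map`: 3D arrays `F`, `p`, `group_coef`
#'   (NA off the analysis set), `df1`, `df2`, `n_valid` (voxels tested),
#'   `n_excluded` (voxels defined for some but not all subjects).
#' @export
fit_voxelwise_glm <- function(maps, design) {
  n <- length(maps)
  if (is.null(colnames(design)) || !"group" %in% colnames(design))
    stop("design must have a column named 'group'")
  if (nrow(design) != n)
    stop("design has ", nrow(design), " rows but there are ", n, " maps")
  p_cols <- ncol(design)
  if (qr(design)$rank < p_cols) stop("design matrix is rank deficient")
  if (n < p_cols + 3) stop("need at least ", p_cols + 3, " subjects for ", p_cols, " design columns")
  if (!all(design[, "group"] %in% c(0, 1))) stop("group column must be binary 0/1")

  dm <- dim(maps[[1]])
  Y <- vapply(maps, function(m) {
    if (!all(dim(m) == dm)) stop("texture maps are not on a common grid")
    as.vector(m)
  }, numeric(prod(dm)))           # voxels x subjects
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  defined <- !is.na(Y)
  all_def <- rowSums(defined) == n
  any_def <- rowSums(defined) > 0
  n_excluded <- sum(any_def & !all_def)
  if (!any(all_def)) stop("no voxel is defined for all subjects")

  Yv <- t(Y[all_def, , drop = FALSE]) # subjects x voxels
  qr_full <- qr(design)
  qr_red <- qr(design[, colnames(design) != "group", drop = FALSE])
  rss1 <- colSums(qr.resid(qr_full, Yv)^2)
  rss0 <- colSums(qr.resid(qr_red, Yv)^2)
  df2 <- n - p_cols
  Fv <- pmax(0, (rss0 - rss1)) / (rss1 / df2)
  pv <- pf(Fv, 1, df2, lower.tail = FALSE)
  coefs <- qr.coef(qr_full, Yv)["group", ]

  Fm <- array(NA_real_, dm); Fm[all_def] <- Fv
  pm <- array(NA_real_, dm); pm[all_def] <- pv
  cm <- array(NA_real_, dm); cm[all_def] <- coefs
  structure(list(F = Fm, p = pm, group_coef = cm, df1 = 1L, df2 = df2,
                 n_valid = sum(all_def), n_excluded = n_excluded),
            class = "stat_map")
}

#' Benjamini-Hochberg FDR correction of a p-value map
#'
#' Step-up BH adjustment over all defined voxels; the significance mask
#' keeps voxels with adjusted q at or below `q_level`.
#'
#' @param p numeric array (or vector) of p-values in (0, 1], NA allowed.
#' @param q_level FDR level (default 0.05).
#' @return A list: `q` (same shape as `p`), `sig_mask` (logical, FALSE where
#'   `p` is NA), `n_significant`.
#' @export
fdr_correct <- function(p, q_level = 0.05) {
  vals <- p[!is.na(p)]
  if (length(vals) == 0) stop("no defined p-values to correct")
  if (any(vals <= 0 | vals > 1)) stop("p-values must lie in (0, 1]")
  q <- p
  q[!is.na(p)] <- p.adjust(vals, method = "BH")
  sig <- !is.na(q) & q <= q_level
  if (!is.null(dim(p))) dim(sig) <- dim(p)
  list(q = q, sig_mask = sig, n_significant = sum(sig))
}

#' Map a voxel index to world (mm) coordinates
#'
#' Homogeneous transform of the index by the affine. NIfTI affines map
#' 0-based voxel indices; when converting a 1-based R array index with a
#' NIfTI affine, subtract 1 first (as [extract_clusters()] does).
#'
#' @param index numeric length-3 vector, or an n x 3 matrix of indices.
#' @param affine invertible 4x4 matrix.
#' @return Length-3 vector (or n x 3 matrix) of mm coordinates.
#' @export
voxel_to_world <- function(index, affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is not invertible")
  if (is.matrix(index)) {
    out <- t(affine %*% rbind(t(index), 1))[, 1:3, drop = FALSE]
    return(out)
  }
  (affine %*% c(index, 1))[1:3]
}

#' Extract suprathreshold clusters from a significance mask
#'
#' Connected components of the significance mask (default 26-connectivity);
#' components with strictly more than `min_size` voxels are kept. The peak
#' is the maximum-F voxel (ties broken toward the smallest linear index);
#' its world coordinate applies the affine to the 0-based peak index. The
#' cluster direction is the sign of the group coefficient at the peak.
#' Clusters are returned sorted by descending peak F.
#'
#' @param sig_mask logical 3D array.
#' @param f_map numeric 3D array of F statistics on the same grid.
#' @param affine 4x4 voxel-to-mm matrix (0-based index convention).
#' @param min_size strict lower bound on cluster size: a component is kept
#'   only when `size > min_size` (default 10).
#' @param connectivity 6, 18 or 26.
#' @param group_coef optional 3D array of group coefficients for the
#'   direction sign.
#' @return A list of class `cluster_set`; each element is a `cluster` list
#'   with `id`, `voxels` (n x 3 index matrix, 1-based), `size`,
#'   `peak_index`, `peak_mm`, `peak_F`, `direction` (NA when `group_coef`
#'   is not given). Convert with [cluster_table()].
#' @export
extract_clusters <- function(sig_mask, f_map, affine, min_size = 10,
                             connectivity = 26, group_coef = NULL) {
  stopifnot(length(dim(sig_mask)) == 3, all(dim(sig_mask) == dim(f_map)),
            connectivity %in% c(6, 18, 26))
  labels <- cpp_label_components(array(as.logical(sig_mask), dim(sig_mask)),
                                 dim(sig_mask), as.integer(connectivity))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes > min_size)
  clusters <- lapply(keep, function(lab) {
    lin <- which(labels == lab)           # ascending linear indices
    fvals <- f_map[lin]
    peak_lin <- lin[which.max(fvals)]     # first max = smallest linear index
    peak_idx <- arrayInd(peak_lin, dim(labels))[1, ]
    list(voxels = arrayInd(lin, dim(labels)),
         size = length(lin),
         peak_index = as.integer(peak_idx),
         peak_mm = as.numeric(voxel_to_world(peak_idx - 1, affine)),
         peak_F = f_map[peak_lin],
         direction = if (is.null(group_coef)) NA_real_
                     else sign(group_coef[peak_lin]))
  })
  ord <- order(vapply(clusters, `[[`, 0, "peak_F"), decreasing = TRUE)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    class(clusters[[i]]) <- "cluster"
  }
  structure(clusters, class = "cluster_set")
}

#' Tabulate a cluster set
#'
#' @param clusters a [extract_clusters()] result.
#' @param q_map optional q-value array to report q at each peak.
#' @return Data frame: cluster_id, size_voxels, peak_x_mm, peak_y_mm,
#'   peak_z_mm, peak_F, q_at_peak, direction.
#' @export
cluster_table <- function(clusters, q_map = NULL) {
  if (length(clusters) == 0)
    return(data.frame(cluster_id = integer(), size_voxels = integer(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), peak_F = numeric(),
                      q_at_peak = numeric(), direction = numeric()))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$id, size_voxels = cl$size,
               peak_x_mm = cl$peak_mm[1], peak_y_mm = cl$peak_mm[2],
               peak_z_mm = cl$peak_mm[3], peak_F = cl$peak_F,
               q_at_peak = if (is.null(q_map)) NA_real_
                           else q_map[cl$peak_index[1], cl$peak_index[2], cl$peak_index[3]],
               direction = cl$direction)
  }))
}
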