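#' Per-subject mean texture over a region
#'
#' Averages each subject's texture map over the region's voxels, skipping
#' undefined (NA) voxels. Subjects with no defined voxel in the region get
#' `NA` and are flagged.
#'
#' @param maps list of per-subject 3D arrays (one feature).
#' @param region a `cluster` from [extract_clusters()], a logical 3D array,
#'   or an n x 3 matrix of voxel indices.
#' @param group optional per-subject group labels (0/1), carried along for
#'   [roc_analysis()].
#' @return A list of class `region_sample`: `values` (named per subject),
#'   `group`, `n_voxels`, `flagged` (subjects with no defined voxel).
#' @export
region_means <- function(maps, region, group = NULL) {
  vox <- region_voxels(region, dim(maps[[1]]))
  if (nrow(vox) == 0) stop("region is empty")
  lin <- vox[, 1] + dim(maps[[1]])[1] * ((vox[, 2] - 1) +
           dim(maps[[1]])[2] * (vox[, 3] - 1))
  values <- vapply(maps, function(m) {
    v <- m[lin]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  if (!is.null(group)) stopifnot(length(group) == length(maps))
  structure(list(values = values, group = group, n_voxels = nrow(vox),
                 flagged = names(values)[is.na(values)]),
            class = "region_sample")
}

region_voxels <- function(region, dm) {
  if (inherits(region, "cluster")) return(region$voxels)
  if (is.matrix(region) && ncol(region) == 3) return(region)
  if (is.array(region) && length(dim(region)) == 3) {
    if (!all(dim(region) == dm)) stop("region mask shape does not match maps")
    return(which(array(as.logical(region), dim(region)), arr.ind = TRUE))
  }
  stop("region must be a cluster, a logical mask, or an index matrix")
}

#' Pair-counting (rank statistic) AUC
#'
#' The probability that a random positive's value exceeds a random
#' negative's, with ties counted one half — computed from mean ranks, which
#' is algebraically the pair-counting statistic.
#'
#' @param values numeric vector.
#' @param labels binary labels (1 = positive).
#' @return AUC in `[0, 1]` for the "higher value = positive" orientation.
#' @export
auc_rank <- function(values, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of a region sample
#'
#' Sweeps every candidate threshold (midpoints between consecutive distinct
#' values, plus one below the minimum and one above the maximum), computes
#' sensitivity and specificity at each, integrates the curve by the
#' trapezoidal rule for the AUC, and picks the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1 (ties broken toward higher
#' specificity). Orientation is chosen so the AUC is at least 0.5: when
#' patients tend to have lower values, "value below cutoff" is called
#' positive and `higher_is_positive` is `FALSE`.
#'
#' @param sample a [region_means()] result with group labels, or a numeric
#'   vector of values (then `group` is required).
#' @param group binary labels (1 = patient/positive), if `sample` is a
#'   plain vector.
#' @return A list of class `roc_result`: `auc`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `higher_is_positive`, `curve`
#'   (data frame of threshold, sensitivity, specificity), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(sample, group = NULL) {
  if (inherits(sample, "region_sample")) {
    group <- sample$group
    values <- sample$values
  } else values <- sample
  if (is.null(group)) stop("group labels are required")
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- group[ok]
  if (length(unique(group)) < 2) stop("both groups must be represented")
  if (sum(group == 1) < 2 || sum(group == 0) < 2)
    stop("need at least 2 subjects per group")

  higher <- auc_rank(values, group) >= 0.5
  v <- if (higher) values else -values

  su <- sort(unique(v))
  thr <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
           su[length(su)] + 1)
  pos <- group == 1
  sens <- vapply(thr, function(t) mean(v[pos] > t), 0)
  spec <- vapply(thr, function(t) mean(v[!pos] <= t), 0)

  # trapezoid over the (FPR, TPR) polyline; thresholds descend FPR as t grows
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  cutoff <- if (higher) thr[best] else -thr[best]

  structure(list(auc = auc, cutoff = cutoff,
                 sensitivity_pct = 100 * sens[best],
                 specificity_pct = 100 * spec[best],
                 higher_is_positive = higher,
                 curve = data.frame(threshold = if (higher) thr else -thr,
                                    sensitivity = sens, specificity = spec),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fn,tn,fp nonnegative counts; `tp + fn` and `tn + fp` must be
#'   positive.
#' @param digits optional rounding of the percentages for display (e.g. 0
#'   for whole percent); `NULL` keeps full precision.
#' @return Named numeric vector `c(sensitivity_pct, specificity_pct)`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp, digits = NULL) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn <= 0) stop("no positive cases (tp + fn = 0)")
  if (tn + fp <= 0) stop("no negative cases (tn + fp = 0)")
  out <- c(sensitivity_pct = 100 * tp / (tp + fn),
           specificity_pct = 100 * tn / (tn + fp))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Pearson correlation of region texture with a clinical measure
#'
#' Pairs with a missing value in either variable are dropped and counted;
#' the two-sided p-value uses the t transform with n - 2 degrees of
#' freedom. Correlations with symptom duration should be restricted to
#' patients (`subset`), since duration is undefined for controls.
#'
#' @param values per-subject region means (e.g. `region_means()$values`).
#' @param measure per-subject clinical values, same length/order.
#' @param subset optional logical or index vector selecting subjects before
#'   pairing (e.g. `group == 1`).
#' @return A list of class `correlation_result`: `r`, `p`, `n`,
#'   `n_dropped`.
#' @export
clinical_correlation <- function(values, measure, subset = NULL) {
  stopifnot(length(values) == length(measure))
  if (!is.null(subset)) {
    values <- values[subset]
    measure <- measure[subset]
  }
  ok <- !is.na(values) & !is.na(measure)
  n_dropped <- sum(!ok)
  x <- values[ok]
  y <- measure[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the variables")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 n_dropped = n_dropped),
            class = "correlation_result")
}
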