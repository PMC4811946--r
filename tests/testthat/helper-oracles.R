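# Literal-loop reference implementations, kept deliberately naive and
# independent of the package's engine code paths.

oracle_plane_axes <- function(plane) {
  switch(plane, axial = c(1, 2), coronal = c(1, 3), sagittal = c(2, 3))
}

# Brute-force single-voxel GLCM: enumerate every patch position and
# direction, drop pairs leaving the patch/volume/mask, accumulate
# symmetrically, normalize.
oracle_glcm <- function(levels, center, plane, ng, r = 1, d = 1,
                        directions = list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))) {
  ax <- oracle_plane_axes(plane)
  dm <- dim(levels)
  p <- matrix(0, ng, ng)
  pairs <- 0L
  for (u in -r:r) {
    for (v in -r:r) {
      a <- center
      a[ax[1]] <- a[ax[1]] + u
      a[ax[2]] <- a[ax[2]] + v
      if (any(a < 1) || any(a > dm)) next
      la <- levels[a[1], a[2], a[3]]
      if (is.na(la)) next
      for (dir in directions) {
        uu <- u + dir[1] * d
        vv <- v + dir[2] * d
        if (abs(uu) > r || abs(vv) > r) next
        b <- center
        b[ax[1]] <- b[ax[1]] + uu
        b[ax[2]] <- b[ax[2]] + vv
        if (any(b < 1) || any(b > dm)) next
        lb <- levels[b[1], b[2], b[3]]
        if (is.na(lb)) next
        p[la, lb] <- p[la, lb] + 1
        p[lb, la] <- p[lb, la] + 1
        pairs <- pairs + 1L
      }
    }
  }
  if (pairs > 0) p <- p / sum(p)
  list(p = p, pair_count = pairs)
}

# Literal sums over the matrix entries for the four features.
oracle_features <- function(p) {
  ng <- nrow(p)
  auto <- 0
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) {
    auto <- auto + i * j * p[i, j]
    mu <- mu + i * p[i, j]
  }
  sosv <- 0
  for (i in 1:ng) for (j in 1:ng) sosv <- sosv + (i - mu)^2 * p[i, j]
  psum <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) psum[i + j] <- psum[i + j] + p[i, j]
  savg <- 0
  for (k in 2:(2 * ng)) savg <- savg + k * psum[k]
  svar <- 0
  for (k in 2:(2 * ng)) svar <- svar + (k - savg)^2 * psum[k]
  c(auto = auto, savg = savg, sosv = sosv, svar = svar)
}

# Full-map brute force: every voxel, every plane, averaged over planes with
# pairs. Returns all four feature maps.
oracle_texture_maps <- function(levels, ng, r = 1, d = 1) {
  dm <- dim(levels)
  out <- list(auto = array(NA_real_, dm), savg = array(NA_real_, dm),
              sosv = array(NA_real_, dm), svar = array(NA_real_, dm))
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(levels[i, j, k])) next
    acc <- c(auto = 0, savg = 0, sosv = 0, svar = 0)
    npl <- 0
    for (pl in c("axial", "coronal", "sagittal")) {
      g <- oracle_glcm(levels, c(i, j, k), pl, ng, r, d)
      if (g$pair_count > 0) {
        acc <- acc + oracle_features(g$p)
        npl <- npl + 1
      }
    }
    if (npl > 0) for (f in names(out)) out[[f]][i, j, k] <- acc[[f]] / npl
  }
  out
}

# Construct a quantized_volume directly from a level array (test fixture).
make_quantized <- function(levels, ng = 8) {
  structure(list(levels = levels, mask = !is.na(levels),
                 bin_edges = seq(0, ng, length.out = ng + 1), n_levels = ng),
            class = "quantized_volume")
}

# Exhaustive ROC: pair-counting AUC by double loop, threshold sweep over all
# candidate cutoffs with the Youden criterion, specificity tie-break.
oracle_roc <- function(values, group) {
  vp <- values[group == 1]
  vn <- values[group == 0]
  wins <- 0
  for (a in vp) for (b in vn) wins <- wins + (a > b) + 0.5 * (a == b)
  auc <- wins / (length(vp) * length(vn))
  higher <- auc >= 0.5
  if (!higher) auc <- 1 - auc
  v <- if (higher) values else -values
  su <- sort(unique(v))
  thr <- c(su[1] - 1,
           if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
           su[length(su)] + 1)
  best <- NULL
  for (t in thr) {
    sens <- mean(v[group == 1] > t)
    spec <- mean(v[group == 0] <= t)
    if (is.null(best) || sens + spec > best$sens + best$spec ||
        (sens + spec == best$sens + best$spec && spec > best$spec))
      best <- list(t = t, sens = sens, spec = spec)
  }
  list(auc = auc, cutoff = if (higher) best$t else -best$t,
       sensitivity_pct = 100 * best$sens, specificity_pct = 100 * best$spec,
       higher_is_positive = higher)
}

# Definitional Pearson r and its t-transform p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

# Dice overlap between two logical arrays.
dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Union mask of a cluster set.
clusters_to_mask <- function(clusters, dm) {
  out <- array(FALSE, dm)
  for (cl in clusters) out[cl$voxels] <- TRUE
  out
}
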