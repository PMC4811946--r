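make_maps <- function(Y, dm) {
  # rows of Y = subjects, columns = voxels laid out in an array of dim dm
  lapply(seq_len(nrow(Y)), function(s) array(Y[s, ], dm))
}

toy_subjects <- function(n, group = rep(c(0, 1), each = n / 2)) {
  data.frame(subject_id = sprintf("s%02d", 1:n), group = group,
             age_years = seq(30, 70, length.out = n),
             sex = rep_len(c(0, 1), n))
}

test_that("design matrix has the covariate structure and full rank", {
  subj <- toy_subjects(8)
  X <- build_design_matrix(subj)
  expect_equal(colnames(X), c("intercept", "group", "age", "sex"))
  expect_equal(qr(X)$rank, 4)
  expect_error(build_design_matrix(transform(subj, group = group + 1)), "binary")
})

test_that("perfect group separation drives p to zero", {
  subj <- toy_subjects(10)
  X <- build_design_matrix(subj)
  dm <- c(4, 3, 2)
  Y <- matrix(rep(subj$group, prod(dm)), nrow = 10)
  sm <- fit_voxelwise_glm(make_maps(Y, dm), X)
  expect_true(all(sm$p < 1e-12))
  expect_equal(sm$df1, 1L)
  expect_equal(sm$df2, 6L)
  expect_equal(sm$n_valid, prod(dm))
})

test_that("null p-values are approximately uniform", {
  subj <- toy_subjects(20)
  X <- build_design_matrix(subj)
  set.seed(8)
  dm <- c(500, 1, 1)
  Y <- matrix(rnorm(20 * 500), nrow = 20)
  sm <- fit_voxelwise_glm(make_maps(Y, dm), X)
  ks <- suppressWarnings(ks.test(as.vector(sm$p), "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("partial F matches an independent lm/anova fit on toy data", {
  subj <- toy_subjects(8)
  X <- build_design_matrix(subj)
  set.seed(12)
  y <- subj$group * 2 + 0.05 * subj$age_years + rnorm(8)
  sm <- fit_voxelwise_glm(make_maps(matrix(y, 8, 1), c(1, 1, 1)), X)

  full <- lm(y ~ group + age_years + sex, data = subj)
  red <- lm(y ~ age_years + sex, data = subj)
  ref <- anova(red, full)
  expect_equal(sm$F[1, 1, 1], ref$F[2], tolerance = 1e-10)
  expect_equal(sm$p[1, 1, 1], ref$`Pr(>F)`[2], tolerance = 1e-10)
  # df1 = 1 identity: F equals the squared group t statistic
  tstat <- summary(full)$coefficients["group", "t value"]
  expect_equal(sm$F[1, 1, 1], tstat^2, tolerance = 1e-10)
  expect_equal(sm$group_coef[1, 1, 1], unname(coef(full)["group"]), tolerance = 1e-10)
})

test_that("voxels missing in any subject are excluded and counted", {
  subj <- toy_subjects(10)
  X <- build_design_matrix(subj)
  set.seed(4)
  dm <- c(3, 3, 1)
  Y <- matrix(rnorm(90), nrow = 10)
  maps <- make_maps(Y, dm)
  maps[[2]][1, 1, 1] <- NA   # defined for 9/10 subjects
  sm <- fit_voxelwise_glm(maps, X)
  expect_true(is.na(sm$F[1, 1, 1]))
  expect_equal(sm$n_valid, 8)
  expect_equal(sm$n_excluded, 1)

  expect_error(fit_voxelwise_glm(maps, X[, c(1, 1, 2, 3)]), "rank deficient")
})

test_that("a pure age effect does not inflate group significance", {
  subj <- toy_subjects(20)
  X <- build_design_matrix(subj)
  set.seed(77)
  nv <- 2000
  noise <- matrix(rnorm(20 * nv), nrow = 20)
  with_age <- noise + outer(0.5 * subj$age_years, rep(1, nv))
  p_null <- fit_voxelwise_glm(make_maps(noise, c(nv, 1, 1)), X)$p
  p_age <- fit_voxelwise_glm(make_maps(with_age, c(nv, 1, 1)), X)$p
  expect_lt(mean(p_age < 0.05), 0.08)
  expect_lt(abs(mean(p_age < 0.05) - mean(p_null < 0.05)), 0.03)
})

test_that("Benjamini-Hochberg step-up behaves at its boundary cases", {
  r <- fdr_correct(array(c(0.001, 0.5, 0.9), c(3, 1, 1)), 0.05)
  expect_equal(as.vector(r$sig_mask), c(TRUE, FALSE, FALSE))
  expect_equal(r$q[1, 1, 1], 0.003)   # 0.001 * 3 / 1

  all1 <- fdr_correct(array(1, c(4, 1, 1)), 0.05)
  expect_equal(all1$n_significant, 0)

  tied <- fdr_correct(array(0.04, c(10, 1, 1)), 0.05)
  expect_equal(tied$n_significant, 10)

  set.seed(2)
  p <- array(runif(100)^2, c(100, 1, 1))
  q <- fdr_correct(p)$q
  expect_true(all(q >= p))
  expect_true(all(q <= 1))

  expect_error(fdr_correct(array(NA_real_, c(2, 1, 1))), "no defined")
  expect_error(fdr_correct(array(c(0, 0.5), c(2, 1, 1))), "0, 1")
})

test_that("cluster extraction honours the strict size threshold", {
  dm <- c(10, 10, 10)
  sig <- array(FALSE, dm)
  sig[2:4, 2:4, 2] <- TRUE            # 9 voxels
  sig[2:4, 2, 3] <- TRUE              # +3 connected -> 12-voxel blob
  sig[8:9, 8, c(6, 7)] <- TRUE        # 4 voxels, separate
  sig[7, 2, 8] <- TRUE                # singleton
  f <- array(1, dm)
  f[3, 3, 2] <- 5
  cl <- extract_clusters(sig, f, diag(4), min_size = 10)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 12)
  expect_equal(cl[[1]]$peak_index, c(3L, 3L, 2L))
  expect_equal(cl[[1]]$peak_F, 5)

  # a blob of exactly 10 voxels is dropped ("larger than" is strict)
  sig10 <- array(FALSE, dm)
  sig10[1:10, 1, 1] <- TRUE
  expect_length(extract_clusters(sig10, f, diag(4), min_size = 10), 0)
  expect_length(extract_clusters(sig10, f, diag(4), min_size = 9), 1)

  # empty mask is fine
  expect_length(extract_clusters(array(FALSE, dm), f, diag(4)), 0)
})

test_that("corner-touching blobs merge under 26- but not 6-connectivity", {
  dm <- c(8, 8, 8)
  sig <- array(FALSE, dm)
  sig[1:4, 1:4, 1] <- TRUE                   # 16 voxels
  sig[5:8, 5:8, 2] <- TRUE                   # 16 voxels touching at a corner
  f <- array(seq_len(prod(dm)), dm)
  cl26 <- extract_clusters(sig, f, diag(4), min_size = 10, connectivity = 26)
  cl6 <- extract_clusters(sig, f, diag(4), min_size = 10, connectivity = 6)
  expect_length(cl26, 1)
  expect_equal(cl26[[1]]$size, 32)
  expect_length(cl6, 2)
  # sorted by descending peak F
  expect_true(cl6[[1]]$peak_F >= cl6[[2]]$peak_F)
})

test_that("cluster direction follows the group coefficient at the peak", {
  dm <- c(6, 6, 6)
  sig <- array(FALSE, dm)
  sig[2:5, 2:4, 2:3] <- TRUE
  f <- array(1, dm)
  coefs <- array(-2, dm)
  cl <- extract_clusters(sig, f, diag(4), min_size = 10, group_coef = coefs)
  expect_equal(cl[[1]]$direction, -1)
})

test_that("voxel-to-world transforms follow the affine", {
  expect_equal(voxel_to_world(c(3, 4, 5), diag(4)), c(3, 4, 5))

  sc <- diag(c(2, 2, 2, 1))
  expect_equal(voxel_to_world(c(1, 1, 1), sc), c(2, 2, 2))

  mni <- rbind(c(-1, 0, 0, 90), c(0, 1, 0, -126), c(0, 0, 1.5, -72),
               c(0, 0, 0, 1))
  idx <- c(45, 60, 30)
  expect_equal(voxel_to_world(idx, mni),
               c(-1 * 45 + 90, 60 - 126, 1.5 * 30 - 72))
  # matrix form
  expect_equal(voxel_to_world(rbind(idx, idx), mni)[1, ],
               voxel_to_world(idx, mni))
  expect_error(voxel_to_world(c(1, 1, 1), matrix(0, 4, 4)), "invertible")
})
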