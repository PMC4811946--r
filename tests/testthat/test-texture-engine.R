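test_that("glcm_params enforces the distance/radius relation", {
  p <- glcm_params()
  expect_equal(p$n_levels, 8L)
  expect_equal(p$radius, 1L)
  expect_equal(p$distance, 1L)
  expect_equal(p$smoothing, 0)
  expect_error(glcm_params(distance = 3, radius = 1), "distance")
  expect_silent(glcm_params(distance = 3, radius = 2))
})

test_that("quantization maps the in-mask range onto 1..Ng", {
  m <- array(TRUE, c(2, 2, 2))
  v <- array(0:7, c(2, 2, 2))
  q <- quantize_volume(v, m, 8)
  expect_equal(as.vector(q$levels), 1:8)
  expect_length(q$bin_edges, 9)
  expect_equal(q$bin_edges[c(1, 9)], c(0, 7))

  const <- quantize_volume(array(4.2, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 8)
  expect_true(all(const$levels == 1L))

  # out-of-mask voxels become NA
  m2 <- array(TRUE, c(2, 2, 2)); m2[1, 1, 1] <- FALSE
  q2 <- quantize_volume(v, m2, 4)
  expect_true(is.na(q2$levels[1, 1, 1]))
  expect_true(all(!is.na(q2$levels[m2])))

  expect_error(quantize_volume(v, array(FALSE, c(2, 2, 2)), 8), "empty")
})

test_that("uniform draws fill the 8 levels near-evenly (binomial bounds)", {
  set.seed(414)
  v <- array(runif(1000, 0, 255), c(10, 10, 10))
  q <- quantize_volume(v, array(TRUE, c(10, 10, 10)), 8)
  counts <- tabulate(q$levels, nbins = 8)
  bounds <- qbinom(c(0.005, 0.995), 1000, 1 / 8)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("single-voxel GLCM matches hand enumeration", {
  # constant patch at level 3: all mass at p(3,3)
  q3 <- make_quantized(array(3L, c(3, 3, 3)), 8)
  g <- accumulate_plane_glcm(q3, c(2, 2, 2), "axial")
  expect_equal(g$p[3, 3], 1)
  expect_equal(sum(g$p), 1)
  expect_equal(g$pair_count, 20L)  # 12 axis-aligned + 8 diagonal pairs in a 3x3

  # 3x3 in-plane checkerboard of levels 1,2, horizontal direction only:
  # exactly 6 horizontal pairs, all between different levels
  lev <- array(NA_integer_, c(3, 3, 1))
  for (i in 1:3) for (j in 1:3) lev[i, j, 1] <- 1L + (i + j) %% 2L
  qcb <- make_quantized(lev, 8)
  ph <- glcm_params()
  ph$directions <- rbind(c(1, 0))
  gh <- accumulate_plane_glcm(qcb, c(2, 2, 1), "axial", ph)
  expect_equal(gh$pair_count, 6L)
  expect_equal(gh$p[1, 2], 0.5)
  expect_equal(gh$p[2, 1], 0.5)
  expect_equal(sum(gh$p), 1)

  # corner-of-mask center: surviving pairs equal brute-force enumeration
  set.seed(7)
  lev2 <- array(sample.int(4, 5 * 5 * 5, TRUE), c(5, 5, 5))
  msk <- array(FALSE, c(5, 5, 5)); msk[1:3, 1:3, 1:3] <- TRUE
  lev2[!msk] <- NA_integer_
  q2 <- make_quantized(lev2, 4)
  for (pl in c("axial", "coronal", "sagittal")) {
    got <- accumulate_plane_glcm(q2, c(1, 1, 1), pl)
    ref <- oracle_glcm(lev2, c(1, 1, 1), pl, 4)
    expect_equal(got$pair_count, ref$pair_count)
    expect_equal(got$p, ref$p)
  }

  expect_error(accumulate_plane_glcm(q2, c(5, 5, 5), "axial"), "mask")
})

test_that("feature formulas reproduce closed-form GLCM cases", {
  # point mass at (3,3)
  pm <- matrix(0, 8, 8); pm[3, 3] <- 1
  f <- glcm_features(list(p = pm, pair_count = 1L))
  expect_equal(unname(f), c(9, 6, 0, 0))

  # two-level symmetric mass at (1,2)/(2,1)
  tl <- matrix(0, 8, 8); tl[1, 2] <- 0.5; tl[2, 1] <- 0.5
  f2 <- glcm_features(list(p = tl, pair_count = 6L))
  expect_equal(unname(f2), c(2, 3, 0.25, 0))

  # random normalized symmetric matrix vs the literal-sum oracle
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rexp(64), 8, 8)
    m <- (m + t(m)) / 2
    m <- m / sum(m)
    expect_equal(glcm_features(list(p = m, pair_count = 10L)),
                 oracle_features(m), tolerance = 1e-10)
  }

  expect_error(glcm_features(list(p = pm * 2, pair_count = 1L)), "normalized")
  expect_error(glcm_features(list(p = pm, pair_count = 0L)), "pairs")
})

test_that("constant volumes give the analytic point-mass maps", {
  m <- array(TRUE, c(5, 5, 5))
  q <- quantize_volume(generate_toy_volume("constant", c(5, 5, 5), 7), m, 8)
  tm <- texture_maps(q)
  expect_true(all(tm$savg == 2))
  expect_true(all(tm$auto == 1))
  expect_true(all(tm$sosv == 0))
  expect_true(all(tm$svar == 0))
})

test_that("axis-permutation symmetry makes the three planes agree", {
  cb <- generate_toy_volume("checkerboard", c(5, 5, 5), c(0, 7))
  q <- quantize_volume(cb, array(TRUE, c(5, 5, 5)), 8)
  per_plane <- lapply(c("axial", "coronal", "sagittal"), function(pl)
    glcm_features(accumulate_plane_glcm(q, c(3, 3, 3), pl)))
  expect_equal(per_plane[[1]], per_plane[[2]])
  expect_equal(per_plane[[1]], per_plane[[3]])
  tm <- texture_maps(q)
  for (f in names(per_plane[[1]]))
    expect_equal(tm[[f]][3, 3, 3], per_plane[[1]][[f]])
})

test_that("engine maps equal the brute-force oracle on random volumes", {
  set.seed(2024)
  # full-mask noise volume
  v <- array(rnorm(9^3), c(9, 9, 9))
  q <- quantize_volume(v, array(TRUE, c(9, 9, 9)), 8)
  got <- texture_maps(q)
  ref <- oracle_texture_maps(q$levels, 8)
  for (f in names(ref)) expect_equal(got[[f]], ref[[f]], tolerance = 1e-10)

  # irregular mask, different Ng and r
  msk <- array(runif(7^3) > 0.3, c(7, 7, 7))
  v2 <- array(runif(7^3, 0, 100), c(7, 7, 7))
  q2 <- quantize_volume(v2, msk, 5)
  got2 <- texture_maps(q2, glcm_params(n_levels = 5, radius = 2, distance = 2))
  ref2 <- oracle_texture_maps(q2$levels, 5, r = 2, d = 2)
  for (f in names(ref2)) expect_equal(got2[[f]], ref2[[f]], tolerance = 1e-10)
})

test_that("features stay inside their theoretical bounds", {
  set.seed(99)
  ng <- 8
  for (rep in 1:3) {
    msk <- array(runif(6^3) > 0.25, c(6, 6, 6))
    if (!any(msk)) next
    v <- array(rnorm(6^3), c(6, 6, 6))
    tm <- texture_maps(quantize_volume(v, msk, ng))
    expect_true(all(tm$auto >= 1 - 1e-12 & tm$auto <= ng^2 + 1e-12, na.rm = TRUE))
    expect_true(all(tm$savg >= 2 - 1e-12 & tm$savg <= 2 * ng + 1e-12, na.rm = TRUE))
    expect_true(all(tm$sosv >= 0 & tm$sosv <= (ng - 1)^2 + 1e-12, na.rm = TRUE))
    expect_true(all(tm$svar >= 0 & tm$svar <= (2 * ng - 2)^2 + 1e-12, na.rm = TRUE))
  }
})

test_that("maps are invariant to bin-preserving intensity transforms", {
  set.seed(3)
  v <- array(sample(0:7, 6^3, TRUE) + 0.0, c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  tm1 <- texture_maps(quantize_volume(v, m, 8))
  tm2 <- texture_maps(quantize_volume(3 * v + 10, m, 8))   # affine, order- and bin-preserving
  expect_identical(tm1, tm2)
})

test_that("sosv increases with checkerboard level separation", {
  sosv_at <- function(delta) {
    lev <- generate_toy_volume("checkerboard", c(5, 5, 5), c(1L, 1L + delta))
    q <- make_quantized(array(as.integer(lev), dim(lev)), 8)
    mean(voxel_texture_map(q, "sosv"), na.rm = TRUE)
  }
  vals <- vapply(c(1L, 3L, 7L), sosv_at, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("cohort driver is order-independent and validates shapes", {
  set.seed(21)
  vols <- list(a = array(rnorm(5^3), c(5, 5, 5)),
               b = array(rnorm(5^3), c(5, 5, 5)))
  m <- array(TRUE, c(5, 5, 5))
  maps <- cohort_texture_maps(vols, m)
  expect_length(maps, 2)
  expect_length(unlist(maps, recursive = FALSE), 8)

  perm <- cohort_texture_maps(rev(vols), m)
  expect_identical(maps$a, perm$a)
  expect_identical(maps$b, perm$b)

  direct <- voxel_texture_map(quantize_volume(vols$a, m, 8), "svar")
  expect_identical(maps$a$svar, direct)

  bad <- c(vols, list(cc = array(0, c(4, 4, 4))))
  expect_error(cohort_texture_maps(bad, m), "cc")
  expect_error(cohort_texture_maps(vols, m, features = "entropy"), "unknown texture feature")
})

test_that("map smoothing only engages when requested", {
  set.seed(5)
  v <- array(rnorm(6^3), c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  q <- quantize_volume(v, m, 8)
  raw <- texture_maps(q, glcm_params(smoothing = 0))
  sm <- texture_maps(q, glcm_params(smoothing = 2))
  expect_false(identical(raw$sosv, sm$sosv))
  # smoothing reduces voxel-to-voxel variation
  expect_lt(sd(sm$sosv), sd(raw$sosv))
})
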