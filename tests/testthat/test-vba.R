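test_that("masked smoothing preserves constants and kernel mass", {
  dims <- c(12, 12, 12)
  aff <- make_affine(c(1, 1, 1))
  mask <- volume3d(array(1, dims), aff)
  const <- volume3d(array(0.42, dims), aff)
  sm <- smooth_volume(const, 1, mask)
  expect_equal(sm$grid, const$grid, tolerance = 1e-12)
  # constants preserved under an irregular mask too (boundary renormalization)
  m2 <- array(0, dims); m2[3:9, 2:11, 4:8] <- 1
  sm2 <- smooth_volume(const, 1.5, volume3d(m2, aff))
  expect_equal(sm2$grid[m2 > 0], rep(0.42, sum(m2)), tolerance = 1e-12)
  expect_true(all(sm2$grid[m2 == 0] == 0))
  # interior unit impulse integrates to one
  dims2 <- c(16, 16, 16)
  imp <- array(0, dims2); imp[8, 8, 8] <- 1
  smi <- smooth_volume(volume3d(imp, aff), 1, volume3d(array(1, dims2), aff))
  expect_equal(sum(smi$grid), 1, tolerance = 1e-6)
})

test_that("smoothing matches direct convolution with an explicit kernel", {
  set.seed(7)
  dims <- c(9, 8, 7)
  arr <- array(rnorm(prod(dims)), dims)
  vol <- volume3d(arr, make_affine(c(1, 1, 1)))
  sm <- smooth_volume(vol, 1)
  want <- oracle_convolve(arr, c(1, 1, 1))
  # compare in the interior, away from the renormalized boundary
  i <- 4:6; j <- 4:5; k <- 4:4
  direct <- want[i, j, k] / oracle_convolve(array(1, dims), c(1, 1, 1))[i, j, k]
  expect_equal(sm$grid[i, j, k], direct, tolerance = 1e-6)
  # anisotropic voxels: sigma in mm is honored per axis
  vol2 <- volume3d(arr, make_affine(c(2, 1, 1)))
  sm2 <- smooth_volume(vol2, 1)
  expect_false(isTRUE(all.equal(sm2$grid, sm$grid)))
})

test_that("voxel-wise GLM t equals brute-force least squares", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(8:14, 1); p <- 3
    dims <- c(5, 4, 3)
    X <- cbind(1, rnorm(n), rnorm(n))
    contrast <- c(0, 1, 0)
    data <- array(rnorm(prod(dims) * n), c(dims, n))
    stack <- structure(list(data = data, affine = make_affine(),
                            ids = as.character(1:n), space = "phantom"),
                       class = "fa_stack")
    mask <- volume3d(array(1, dims))
    stat <- fit_voxelwise_glm(stack, X, mask, contrast)
    Y <- matrix(data, prod(dims), n)
    want <- oracle_glm_t(t(Y), X, contrast)
    expect_equal(as.vector(stat$t), want, tolerance = 1e-8)
    expect_identical(stat$df, as.integer(n - p))
  }
})

test_that("identical group distributions give a zero t map", {
  dims <- c(5, 5, 4)
  one <- array(runif(prod(dims)), dims)
  data <- array(rep(one, 8), c(dims, 8))
  stack <- structure(list(data = data, affine = make_affine(),
                          ids = as.character(1:8), space = "phantom"),
                     class = "fa_stack")
  X <- cbind(1, rep(c(0, 1), each = 4))
  stat <- fit_voxelwise_glm(stack, X, volume3d(array(1, dims)), c(0, 1))
  expect_true(all(stat$t == 0))
})

test_that("t maps are invariant to affine rescaling of covariates", {
  set.seed(23)
  co <- small_cohort(seed = 8)
  ph <- generate_phantom(phantom_spec(seed = 8))
  fa <- generate_subject_fa(ph, co)
  d1 <- vba_design(co, "seiz-vs-hc")
  co2 <- co; co2$age <- co2$age * 12 + 7; co2$bdi <- co2$bdi / 3
  d2 <- vba_design(co2, "seiz-vs-hc")
  s1 <- fit_voxelwise_glm(fa, d1, ph$wm_mask)
  s2 <- fit_voxelwise_glm(fa, d2, ph$wm_mask)
  expect_equal(s1$t, s2$t, tolerance = 1e-8)
})

test_that("effect-size conventions reproduce published magnitudes", {
  expect_equal(cohens_d(0, n1 = 10, n2 = 10), 0)
  expect_equal(round(cohens_d(-5.76, n1 = 21, n2 = 38), 2), 1.57)
  expect_lt(abs(cohens_d(-5.76, n1 = 21, n2 = 38) - 1.56), 0.01)
  expect_equal(round(cohens_d(5.57, n = 33, type = "correlation"), 2), 0.97)
  expect_equal(round(cohens_d(-5.91, n = 33, type = "correlation"), 2), 1.03)
  # two-sample toy: matches the mean-difference definition through t
  set.seed(31)
  a <- rnorm(12, 1); b <- rnorm(15)
  sp <- sqrt(((11) * var(a) + 14 * var(b)) / (12 + 15 - 2))
  d_def <- abs(mean(a) - mean(b)) / sp
  t_obs <- unname(t.test(a, b, var.equal = TRUE)$statistic)
  expect_equal(cohens_d(t_obs, n1 = 12, n2 = 15), d_def, tolerance = 1e-8)
  expect_error(cohens_d(2, n1 = 10), "n1 and n2")
})

test_that("smoothness estimation recovers known kernels", {
  dims <- c(24, 24, 24)
  mask <- volume3d(array(1, dims))
  set.seed(41)
  # white noise: voxel-scale smoothness
  res <- t(vapply(1:8, function(i) rnorm(prod(dims)), numeric(prod(dims))))
  fw <- estimate_smoothness(res, mask)
  expect_true(all(abs(fw / 1.1774 - 1) < 0.15))
  # pre-smoothed noise: recovers the effective kernel FWHM
  sig <- 1.5
  res2 <- t(vapply(1:8, function(i)
    as.vector(smooth_array(array(rnorm(prod(dims)), dims), rep(sig, 3))),
    numeric(prod(dims))))
  fw2 <- estimate_smoothness(res2, mask)
  expect_true(all(abs(fw2 / (2.3548 * sig) - 1) < 0.15))
  # doubling voxel size doubles FWHM in mm
  mask2 <- volume3d(array(1, dims), make_affine(c(2, 2, 2)))
  fw3 <- estimate_smoothness(res2, mask2)
  expect_equal(as.numeric(fw3), as.numeric(fw2) * 2, tolerance = 1e-12)
  expect_error(estimate_smoothness(matrix(1, 3, prod(dims)), mask), "constant")
})

test_that("cluster correction retains an extreme injected cluster", {
  dims <- c(16, 16, 10)
  mask <- volume3d(array(1, dims))
  tarr <- array(rnorm(prod(dims), 0, 0.5), dims)
  tarr[5:12, 5:12, 4:7] <- 10
  stat <- structure(list(t = tarr, df = 30, mask = mask, affine = make_affine(),
                         space = "phantom", n = 32, p = 2, type = "two-sample",
                         n1 = 16, n2 = 16,
                         residuals = matrix(rnorm(4 * prod(dims)), 4),
                         mask_voxels = seq_len(prod(dims))),
                    class = "stat_map")
  cl <- cluster_correct_mc(stat, fwhm = 2.5, n_iter = 400, seed = 9)
  expect_gte(nrow(cl), 1L)
  top <- cl[1, ]
  expect_identical(top$size, 8L * 8L * 4L)
  expect_equal(top$p_corrected, 1 / 401)
  expect_true(top$retained)
  expect_identical(top$sign, 1)
  # nestedness: raising alpha never removes a retained cluster
  ne <- mc_null_extents(mask, 2.5, n_iter = 400, seed = 9)
  lo <- cluster_correct_mc(stat, fwhm = 2.5, alpha = 0.01, null_extents = ne)
  hi <- cluster_correct_mc(stat, fwhm = 2.5, alpha = 0.10, null_extents = ne)
  expect_true(all(lo$cluster[lo$retained] %in% hi$cluster[hi$retained]))
  # blob mask matches the retained voxel set
  bm <- cluster_mask(cl, mask)
  expect_equal(sum(bm$grid), sum(cl$size[cl$retained]))
})

test_that("connected-component labeling respects connectivity", {
  arr <- array(FALSE, c(6, 6, 3))
  arr[1:2, 1:2, 1] <- TRUE
  arr[4:5, 4:5, 1] <- TRUE
  lab6 <- label_components(arr, 6)
  expect_identical(sort(lab6$sizes), c(4L, 4L))
  # diagonal touch merges under 26- but not 6-connectivity
  arr2 <- array(FALSE, c(4, 4, 1))
  arr2[1, 1, 1] <- TRUE; arr2[2, 2, 1] <- TRUE
  expect_identical(length(label_components(arr2, 6)$sizes), 2L)
  expect_identical(length(label_components(arr2, 26)$sizes), 1L)
})

test_that("the synthetic blob effect is detected against its exterior", {
  sp <- phantom_spec()
  ph <- generate_phantom(sp)
  co <- small_cohort(seed = 13)
  hits <- vapply(1:10, function(s) {
    fa <- generate_subject_fa(ph, co, seed = 100 + s)
    sm <- smooth_stack(fa, 1, ph$wm_mask)
    stat <- fit_voxelwise_glm(sm, vba_design(co, "seiz-vs-hc"), ph$wm_mask)
    inblob <- min(stat$t[ph$truth$blob])
    outside <- setdiff(which(!is.na(stat$t)), ph$truth$blob)
    inblob < 0 && abs(inblob) > max(abs(stat$t[outside]))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
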