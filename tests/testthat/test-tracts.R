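test_that("tracking traverses a straight tube end to end", {
  ph <- generate_phantom(tube_phantom())
  seeds <- bundle_seeds(ph, "tube", n = 20, seed = 3)
  sls <- track_streamlines(ph$field, seeds, step_mm = 0.5)
  expect_identical(length(sls$points), 20L)
  for (p in sls$points) {
    # spans the tube length to within one step of each end
    expect_lt(min(p[, 1]), 3 + 1)
    expect_gt(max(p[, 1]), 33 - 1)
    expect_true(all(abs(diff(p[, 1])) <= 0.5 + 1e-9))
  }
  # a seed outside the mask yields no streamline, with a warning count
  far <- matrix(c(1, 1, 1), 1)
  expect_warning(out <- track_streamlines(ph$field, far), "no streamline")
  expect_identical(length(out$points), 0L)
  expect_identical(attr(out, "n_skipped"), 1L)
})

test_that("the angular gate stops tracking on curved geometry", {
  # quarter-circle tube turning ~10 degrees per voxel
  th <- seq(0, pi / 2, length.out = 10)
  r <- 9 / (pi / 2)  # ~1 voxel arc step
  line <- cbind(6 + r * sin(th), 6 + r * (1 - cos(th)), 6)
  sp <- phantom_spec(grid_shape = c(24, 24, 12),
                     bundles = list(bundle_geometry("arc", line, 1.8, 1L, 2L)),
                     blob_region = list(bundle = "arc", lo = c(0, 0, 0),
                                        hi = c(24, 24, 12)),
                     correlate_region = list(bundle = "arc", lo = c(0, 0, 0),
                                             hi = c(24, 24, 12)))
  ph <- generate_phantom(sp)
  seed1 <- matrix(line[1, ], 1)
  full <- track_streamlines(ph$field, seed1, step_mm = 0.5, max_angle_deg = 70)
  tight <- suppressWarnings(
    track_streamlines(ph$field, seed1, step_mm = 0.5, max_angle_deg = 5))
  arclen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  expect_gt(arclen(full$points[[1]]), 0.8 * 9)
  if (length(tight$points)) expect_lt(arclen(tight$points[[1]]),
                                      0.5 * arclen(full$points[[1]]))
  # downstream curvature filter at 70 degrees retains the tracked arc
  kept <- filter_curvature(full, 70)
  expect_identical(length(kept$points), 1L)
})

test_that("visitation maps equal brute-force intersection counting", {
  ref <- volume3d(array(0, c(20, 12, 8)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  one <- streamline_set(list(straight_line(2, 17, 6, 4)))
  vm1 <- visitation_map(one, ref)
  vox <- oracle_voxels(one$points[[1]], ref$affine, dim(ref$grid))
  expect_setequal(which(vm1$grid == 1), vox)
  expect_identical(sum(vm1$grid), length(vox) * 1)
  two <- streamline_set(list(straight_line(2, 17, 6, 4),
                             straight_line(2, 17, 3, 6)))
  vm2 <- visitation_map(two, ref)
  expect_setequal(unique(vm2$grid[vm2$grid > 0]), 0.5)
  # random toy set vs voxel-by-streamline counting
  set.seed(5)
  pts <- lapply(1:20, function(i) {
    p0 <- c(runif(1, 2, 6), runif(1, 2, 10), runif(1, 2, 6))
    p1 <- c(runif(1, 12, 18), runif(1, 2, 10), runif(1, 2, 6))
    rbind(p0, (p0 + p1) / 2 + rnorm(3, 0, 0.5), p1)
  })
  sls <- streamline_set(pts)
  vm <- visitation_map(sls, ref)
  counts <- numeric(prod(dim(ref$grid)))
  for (p in pts) {
    v <- oracle_voxels(p, ref$affine, dim(ref$grid))
    counts[v] <- counts[v] + 1
  }
  expect_equal(as.vector(vm$grid), counts / 20)
})

test_that("probability filtering removes strays and validates its domain", {
  ref <- volume3d(array(0, c(40, 12, 8)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  core <- lapply(1:1999, function(i) straight_line(2, 37, 6, 4))
  stray <- list(straight_line(2, 37, 9, 6))
  sls <- streamline_set(c(core, stray))
  vm <- visitation_map(sls, ref)
  kept <- filter_voxel_probability(sls, vm, 0.001)
  expect_identical(length(kept$points), 1999L)
  expect_equal(kept$points[[1]], core[[1]])
  # shared-path sets survive any threshold up to 1
  shared <- streamline_set(core[1:5])
  vms <- visitation_map(shared, ref)
  expect_identical(length(filter_voxel_probability(shared, vms, 0.999)$points), 5L)
  expect_error(filter_voxel_probability(sls, vm, 0), "min_prob")
  expect_error(filter_voxel_probability(sls, vm, 1), "min_prob")
})

test_that("curvature filtering thresholds the maximum turning angle", {
  straight <- straight_line(1, 10, 5, 5)
  hairpin <- rbind(c(2, 5, 5), c(8, 5, 5), c(8, 11, 5), c(2, 11, 5))
  gentle <- turning_line(12, 10)
  sls <- streamline_set(list(straight, hairpin, gentle))
  kept <- filter_curvature(sls, 70)
  expect_identical(length(kept$points), 2L)
  expect_equal(kept$points[[2]], gentle)
  # measured turn equals the constructed 10 degrees by the dot-product oracle
  expect_equal(oracle_max_turn(gentle), 10, tolerance = 1e-9)
  expect_equal(oracle_max_turn(hairpin), 90, tolerance = 1e-9)
  # two-point streamlines have zero curvature
  expect_identical(length(filter_curvature(streamline_set(list(straight[1:2, ])), 1)$points), 1L)
  # idempotence
  expect_identical(length(filter_curvature(kept, 70)$points), 2L)
})

test_that("crossing-fiber removal follows the direction-histogram rule", {
  ref <- volume3d(array(0, c(21, 21, 7)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  mk_x <- function(y) straight_line(1, 20, y, 3.5)
  mk_y <- function(x) { p <- straight_line(1, 20, x, 3.5); cbind(p[, 2], p[, 1], p[, 3]) }
  # 97/3 mixture: minority orthogonal population removed
  big <- lapply(rep(10.2, 32), mk_x)
  small <- list(mk_y(10.3))
  mix <- streamline_set(c(big, small))
  kept <- filter_crossing(mix, ref)
  expect_identical(length(kept$points), 32L)
  expect_true(all(vapply(kept$points, function(p) diff(range(p[, 2])) < 1, TRUE)))
  # 50/50 crossing: both populations retained
  even <- streamline_set(c(lapply(seq(9.8, 10.6, length.out = 8), mk_x),
                           lapply(seq(9.8, 10.6, length.out = 8), mk_y)))
  expect_identical(length(filter_crossing(even, ref)$points), 16L)
  # a single coherent bundle is untouched
  coh <- streamline_set(big)
  expect_identical(length(filter_crossing(coh, ref)$points), 32L)
  # idempotence on these sets
  expect_identical(length(filter_crossing(kept, ref)$points), 32L)
  # binned variant agrees here
  expect_identical(length(filter_crossing(mix, ref, method = "binned")$points), 32L)
})

test_that("filters return subsets and keep their documented order semantics", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  seeds <- rbind(bundle_seeds(ph, "bundle_x", 40, seed = 1),
                 bundle_seeds(ph, "bundle_y", 40, seed = 2))
  sls <- track_streamlines(ph$field, seeds)
  vm <- visitation_map(sls, ph$wm_mask)
  f1 <- filter_voxel_probability(sls, vm, 0.001)
  f2 <- filter_curvature(f1, 70)
  f3 <- filter_crossing(f2, ph$wm_mask)
  expect_lte(length(f3$points), length(f2$points))
  expect_lte(length(f2$points), length(f1$points))
  expect_lte(length(f1$points), length(sls$points))
  ids <- function(s) vapply(s$points, function(p) paste(p[1, ], collapse = ","), "")
  expect_true(all(ids(f3) %in% ids(sls)))
  # the crossing rule and the probability rule are not interchangeable: a
  # parallel-but-offset stray passes the direction histogram yet fails the
  # visitation-probability floor
  ref <- volume3d(array(0, c(21, 21, 7)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  mk_x <- function(y) straight_line(1, 20, y, 3.5)
  set_a <- streamline_set(c(lapply(rep(10.2, 30), mk_x), list(mk_x(14.5))))
  crossed_only <- filter_crossing(set_a, ref)
  vm_a <- visitation_map(set_a, ref)
  prob_only <- filter_voxel_probability(set_a, vm_a, 0.05)
  expect_identical(length(crossed_only$points), 31L)
  expect_identical(length(prob_only$points), 30L)
})

test_that("query selection matches endpoint/waypoint/exclusion semantics", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  seeds <- rbind(bundle_seeds(ph, "bundle_x", 30, seed = 4),
                 bundle_seeds(ph, "bundle_y", 30, seed = 5))
  sls <- track_streamlines(ph$field, seeds)
  labs <- ph$labels
  qx <- bundle_query("bundle_x", 1L, 2L)
  qy <- bundle_query("bundle_y", 3L, 4L)
  sel_x <- select_by_query(sls, labs, qx)
  sel_y <- select_by_query(sls, labs, qy)
  # ground truth from realized endpoints in the label volume
  end_label <- function(p) {
    idx <- world_to_index(labs, p[c(1, nrow(p)), , drop = FALSE])
    sort(labs$grid[voxel_linear(idx, dim(labs$grid))])
  }
  truth_x <- vapply(sls$points, function(p) identical(end_label(p), c(1L, 2L)), TRUE)
  truth_y <- vapply(sls$points, function(p) identical(end_label(p), c(3L, 4L)), TRUE)
  expect_identical(length(sel_x$points), sum(truth_x))
  expect_identical(length(sel_y$points), sum(truth_y))
  # a waypoint off the tube empties the selection
  q_off <- bundle_query("off", 1L, 2L, waypoint_labels = list(3L))
  off_sel <- select_by_query(sls, labs, q_off)
  expect_identical(length(off_sel$points), 0L)
  # exclusion removes fibers passing the crossing bundle's end labels
  expect_error(select_by_query(sls, labs, bundle_query("bad", 9L, 2L)),
               "absent")
})

test_that("bundle atlases count contributing subjects per voxel", {
  ref <- volume3d(array(0, c(20, 10, 6)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  mk <- function(y) streamline_set(list(straight_line(2, 17, y, 3)))
  subj <- list(s1 = mk(5), s2 = mk(5), s3 = mk(5), s4 = mk(8))
  atlas <- build_bundle_atlas(subj, ref)
  expect_identical(attr(atlas, "n_subjects"), 4L)
  common <- oracle_voxels(subj$s1$points[[1]], ref$affine, dim(ref$grid))
  rare <- oracle_voxels(subj$s4$points[[1]], ref$affine, dim(ref$grid))
  expect_true(all(atlas$grid[common] == 0.75))
  expect_true(all(atlas$grid[setdiff(rare, common)] == 0.25))
  # identical bundles across subjects: probability one on the path
  same <- build_bundle_atlas(subj[1:3], ref)
  expect_true(all(same$grid[common] == 1))
  expect_error(build_bundle_atlas(list(), ref), "empty")
  # jittered bundles match per-voxel subject counting
  set.seed(9)
  js <- lapply(1:10, function(i) mk(5 + runif(1, -1, 1)))
  names(js) <- paste0("s", 1:10)
  ja <- build_bundle_atlas(js, ref)
  counts <- numeric(prod(dim(ref$grid)))
  for (s in js) {
    v <- oracle_voxels(s$points[[1]], ref$affine, dim(ref$grid))
    counts[v] <- counts[v] + 1
  }
  expect_equal(as.vector(ja$grid), counts / 10)
})

test_that("blob projection applies the 25% membership rule per voxel", {
  ref <- volume3d(array(0, c(10, 10, 4)), make_affine(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  mk_atlas <- function(p) {
    g <- array(0, dim(ref$grid)); g[3:8, 3:8, 2] <- p
    volume3d(g, ref$affine, ref$space)
  }
  blob_g <- array(0, dim(ref$grid)); blob_g[4:7, 4:7, 2] <- 1
  blob <- volume3d(blob_g, ref$affine, ref$space)
  atlas <- list(a = mk_atlas(1), b = mk_atlas(0.2))
  rep1 <- project_blob_to_bundles(blob, atlas)
  expect_identical(rep1$bundle, "a")
  expect_equal(rep1$fraction, 1)
  # mixed-coverage bundle ranks by the covered fraction
  g <- array(0, dim(ref$grid)); g[4:5, 4:7, 2] <- 0.5
  atlas$c <- volume3d(g, ref$affine, ref$space)
  rep2 <- project_blob_to_bundles(blob, atlas)
  expect_identical(rep2$bundle, c("a", "c"))
  expect_equal(rep2$fraction[2], 0.5)
  expect_error(project_blob_to_bundles(volume3d(array(0, dim(ref$grid)), ref$affine),
                                       atlas), "empty blob")
})

test_that("filtered, query-selected bundles recover membership on a crossing phantom", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  seeds <- rbind(bundle_seeds(ph, "bundle_x", 100, seed = 11),
                 bundle_seeds(ph, "bundle_y", 100, seed = 12))
  sls <- track_streamlines(ph$field, seeds)
  # add ~5% stray fibers: short random jitter walks inside the mask
  set.seed(13)
  strays <- lapply(1:10, function(i) {
    p0 <- c(runif(1, 10, 26), 11, 5.5)
    steps <- matrix(rnorm(12, 0, 0.6), 4, 3)
    rbind(p0, p0 + apply(steps, 2, cumsum))
  })
  all_sls <- c(sls, streamline_set(strays))
  vm <- visitation_map(all_sls, ph$wm_mask)
  f <- filter_voxel_probability(all_sls, vm, 0.005)
  f <- filter_curvature(f, 70)
  f <- filter_crossing(f, ph$wm_mask)
  qx <- bundle_query("bundle_x", 1L, 2L)
  sel <- select_by_query(f, ph$labels, qx)
  end_label <- function(p) {
    idx <- world_to_index(ph$labels, p[c(1, nrow(p)), , drop = FALSE])
    sort(ph$labels$grid[voxel_linear(idx, dim(ph$labels$grid))])
  }
  truth_x <- vapply(all_sls$points, function(p) identical(end_label(p), c(1L, 2L)), TRUE)
  ids <- function(s) vapply(s$points, function(p) paste(round(p[1, ], 6), collapse = ","), "")
  picked <- ids(all_sls) %in% ids(sel)
  sens <- sum(picked & truth_x) / sum(truth_x)
  spec <- sum(!picked & !truth_x) / sum(!truth_x)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})
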