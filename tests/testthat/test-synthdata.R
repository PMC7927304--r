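test_that("cohort generation honors group sizes, dropout and determinism", {
  co <- generate_cohort(cohort_spec(seed = 3))
  expect_identical(nrow(co), 21L + 17L + 38L)
  expect_identical(sum(co$group == "FND-seiz"), 21L)
  expect_identical(sum(co$group == "FND-movt"), 17L)
  expect_identical(sum(co$group == "HC"), 38L)
  # exact per-group unusable-ECG bookkeeping
  expect_identical(sum(!co$usable_ecg & co$group != "HC"), 5L)
  expect_identical(sum(!co$usable_ecg & co$group == "HC"), 4L)
  # zero dropout: everyone usable
  co0 <- generate_cohort(cohort_spec(ecg_unusable = NULL, ecg_dropout = 0, seed = 3))
  expect_true(all(co0$usable_ecg))
  # determinism
  expect_identical(generate_cohort(cohort_spec(seed = 3)), co)
  expect_false(identical(generate_cohort(cohort_spec(seed = 4)), co))
  expect_error(cohort_spec(bdi = list(pat = c(20, -1), hc = c(11, 7))), "sd > 0")
})

test_that("patient depression and anxiety run higher than control scores", {
  co <- generate_cohort(cohort_spec(n_seiz = 400, n_movt = 0, n_hc = 400,
                                    ecg_unusable = NULL, ecg_dropout = 0,
                                    seed = 9))
  pat <- co$group != "HC"
  expect_gt(mean(co$bdi[pat]), mean(co$bdi[!pat]))
  expect_gt(mean(co$stai_trait[pat]), mean(co$stai_trait[!pat]))
  # covariate means within 3 SEs of the spec at large n
  sp <- cohort_spec()
  expect_lt(abs(mean(co$bmi[pat]) - sp$bmi$pat[1]),
            3 * sp$bmi$pat[2] / sqrt(400))
  expect_lt(abs(mean(co$stai_trait[!pat]) - sp$stai$hc[1]),
            3 * sp$stai$hc[2] / sqrt(400) + 0.5)  # rounding to integer scores
})

test_that("heartbeat trials follow the window set and the error model", {
  tr <- generate_htt_trials(0.7, 72, seed = 2)
  expect_identical(nrow(tr), 12L)
  expect_true(all(tr$window_s %in% c(15, 18, 21, 24, 27, 30)))
  expect_true(all(tr$rec >= 1) && all(tr$count >= 0))
  expect_true(all(tr$count == round(tr$count)))
  # perfect perceiver with no report noise scores exactly 1
  tr1 <- generate_htt_trials(1, 60, sigma_report = 0, seed = 5)
  expect_identical(tr1$rec, tr1$count)
  expect_identical(htt_score(tr1), 1)
  expect_identical(generate_htt_trials(0.7, 72, seed = 2), tr)
  expect_error(generate_htt_trials(0.7, 72, n_windows = 0), "n_windows")
  expect_error(generate_htt_trials(0.7, 72, window_lengths = rep(10, 12)),
               "window lengths")
})

test_that("mean recovered accuracy matches the generator's own error model", {
  a <- 0.7; sig <- 0.1
  # model-derived expectation: E|1 - a - e| for e ~ N(0, sig), by quadrature
  # (rounding and truncation shift it by less than the integration error here)
  mu <- 1 - a
  e_abs <- mu * (2 * pnorm(mu / sig) - 1) + 2 * sig * dnorm(mu / sig)
  expect_model <- 1 - e_abs
  n_sub <- 2000
  scores <- vapply(seq_len(n_sub), function(i) {
    htt_score(generate_htt_trials(a, runif(1, 55, 95), sigma_report = sig,
                                  seed = i))
  }, 0)
  se <- sd(scores) / sqrt(n_sub)
  expect_lt(abs(mean(scores) - expect_model), 3 * se + 0.002)
  expect_lt(abs(mean(scores) - a), 0.01)
  # noise-free recovery: mean score converges to the true accuracy
  s0 <- vapply(1:200, function(i)
    htt_score(generate_htt_trials(0.8, 70, sigma_report = 1e-6, seed = i)), 0)
  expect_lt(abs(mean(s0) - 0.8), 0.02)  # rounding granularity only
})

test_that("phantom tubes carry centerline orientations and end labels", {
  ph <- generate_phantom(tube_phantom())
  wm <- which(ph$field$mask)
  dirs <- cbind(ph$field$primary[, , , 1][wm], ph$field$primary[, , , 2][wm],
                ph$field$primary[, , , 3][wm])
  # straight x-tube: all orientations equal (1,0,0) up to sign
  expect_true(all(abs(abs(dirs[, 1]) - 1) < 1e-12))
  expect_true(all(abs(dirs[, 2:3]) < 1e-12))
  # null orientation outside the tube
  out <- which(!ph$field$mask)
  expect_true(all(ph$field$primary[, , , 1][out] == 0))
  expect_setequal(unique(ph$labels$grid[ph$labels$grid != 0]), c(1L, 2L))
  # crossing phantom records the minority population
  ph2 <- generate_phantom(phantom_spec())
  expect_false(is.null(ph2$field$secondary))
  sec <- which(rowSums(matrix(ph2$field$secondary, ncol = 3)^2) > 0)
  expect_gt(length(sec), 0)
  expect_true(all(sec %in% which(ph2$field$mask)))
  # overlapping ROI labels are a construction error
  bad <- phantom_spec(bundles = list(
    bundle_geometry("a", rbind(c(5, 18, 6), c(31, 18, 6)), 2.2, 1L, 2L),
    bundle_geometry("b", rbind(c(5, 19, 6), c(31, 19, 6)), 2.2, 1L, 3L)))
  expect_error(generate_phantom(bad), "overlapping ROI labels")
})

test_that("subject FA embeds the group effect, correlate and nuisances", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  co <- small_cohort(seed = 2)
  # zero noise: FA equals the deterministic mean field
  fa0 <- generate_subject_fa(ph, co, noise_sd = 0)
  i_hc <- which(co$group == "HC")[1]
  i_pat <- which(co$group == "FND-seiz")[1]
  blob <- ph$truth$blob
  v_hc <- as.vector(fa0$data[, , , i_hc])
  v_pat <- as.vector(fa0$data[, , , i_pat])
  sp <- ph$spec
  nuis <- function(i) sp$age_slope * (co$age[i] - mean(co$age)) +
    sp$sex_effect * (co$sex[i] == "M")
  expect_equal(unique(round(v_hc[blob] - nuis(i_hc), 10)), sp$fa_baseline)
  expect_equal(unique(round(v_pat[blob] - nuis(i_pat), 10)),
               sp$fa_baseline + sp$group_effect)
  corr <- ph$truth$correlate
  expect_equal(v_pat[corr] - nuis(i_pat),
               rep(sp$fa_baseline + sp$slope * (co$true_accuracy[i_pat] - sp$accuracy_ref),
                   length(corr)))
  # null effects: blob-mean difference stays within noise
  sp0 <- phantom_spec(group_effect = 0, slope = 0, seed = 3)
  ph0 <- generate_phantom(sp0)
  fa <- generate_subject_fa(ph0, co, seed = 11)
  bm <- apply(fa$data, 4, function(v) mean(v[blob]))
  tt <- t.test(bm[co$group != "HC"], bm[co$group == "HC"])
  expect_gt(tt$p.value, 0.001)
  expect_true(all(fa$data >= 0 & fa$data <= 1))
  expect_identical(generate_subject_fa(ph0, co, seed = 11)$data, fa$data)
})

test_that("the default group effect is recoverable at cohort size", {
  # blob-mean two-sample t recovers the negative sign in >= 95% of seeds
  sp <- phantom_spec()
  ph <- generate_phantom(sp)
  blob <- ph$truth$blob
  co <- small_cohort(seed = 1)
  pat <- co$group != "HC"
  hits <- vapply(1:40, function(s) {
    fa <- generate_subject_fa(ph, co, seed = s)
    bm <- apply(fa$data, 4, function(v) mean(v[blob]))
    tt <- t.test(bm[pat], bm[!pat])
    tt$statistic < 0 && tt$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
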