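test_that("build_group_correlation applies its rules in order", {
  atlas <- toy_atlas(pairs = 4, lobes = c("frontal", "temporal"))
  # all-zero rules -> identity
  spec0 <- cov_spec(atlas, base_correlation = 0, homologue_correlation = 0,
                    intralobe_correlation = 0,
                    affected_edges = data.frame(i = 1, j = 4),
                    affected_baseline = 0,
                    effect_size_by_group = c(NC = 0, MCI = 0, AD = 0))
  expect_equal(unname(build_group_correlation(spec0, "NC")), diag(8),
               ignore_attr = TRUE)

  spec <- cov_spec(atlas, base_correlation = 0.05,
                   homologue_correlation = 0.6,
                   intralobe_correlation = 0.25,
                   affected_edges = data.frame(i = c(1, 3), j = c(4, 6)),
                   affected_baseline = 0.5,
                   effect_size_by_group = c(NC = 0, MCI = 0.15, AD = 0.3))
  nc <- attr(build_group_correlation(spec, "NC"), "target_raw")
  ad <- attr(build_group_correlation(spec, "AD"), "target_raw")
  # groups differ only at affected edges before PD projection
  d <- abs(nc - ad) > 0
  expected <- matrix(FALSE, 8, 8)
  expected[cbind(c(1, 3), c(4, 6))] <- TRUE
  expected <- expected | t(expected)
  expect_identical(d, expected)
  expect_equal(nc[1, 4], 0.5)
  expect_equal(ad[1, 4], 0.2)
  # homologue rule wins over intralobe where no effect applies
  expect_equal(nc[1, 2], 0.6)
  # intralobe (regions 1 and 5 share the frontal lobe, not homologous)
  expect_equal(nc[1, 5], 0.25)
  # background (different lobes, no other rule)
  expect_equal(nc[2, 3], 0.05)
})

test_that("cov_spec validates effect ordering and correlation bounds", {
  atlas <- toy_atlas()
  expect_error(cov_spec(atlas, effect_size_by_group =
                          c(NC = 0.3, MCI = 0.15, AD = 0)),
               "NC <= MCI <= AD")
  expect_error(cov_spec(atlas, homologue_correlation = 1), "\\(-1, 1\\)")
  expect_error(cov_spec(atlas, affected_baseline = -0.5,
                        effect_size_by_group = c(NC = 0, MCI = 0, AD = 0.6)),
               ">= 1")
})

test_that("nearest_pd clips eigenvalues and keeps PD input untouched", {
  ok <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_lt(max(abs(nearest_pd(ok) - ok)), 1e-12)
  expect_equal(nearest_pd(diag(4)), diag(4))

  # strongly inconsistent triangle: not PD
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- nearest_pd(bad, epsilon = 1e-6)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 1e-6 - 1e-12)
  expect_equal(diag(fixed), rep(1, 3))
  expect_error(nearest_pd(matrix(1:4, 2)), "not symmetric")
})

test_that("simulate_subject attains the target correlation", {
  cfg0 <- cohort_config(n_timepoints = 50000, ar_coefficient = 0, seed = 1)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  set.seed(11)
  ts <- simulate_subject(R, cfg0)
  expect_equal(dim(ts), c(50000, 2))
  expect_lt(abs(cor(ts)[1, 2] - 0.6), 0.02)

  # AR(1) innovations leave the lag-0 cross-correlation at the target
  cfg_ar <- cohort_config(n_timepoints = 50000, ar_coefficient = 0.5, seed = 1)
  set.seed(12)
  ts_ar <- simulate_subject(R, cfg_ar)
  expect_lt(abs(cor(ts_ar)[1, 2] - 0.6), 0.02)
  # and the series really is autocorrelated
  expect_gt(cor(ts_ar[-1, 1], ts_ar[-50000, 1]), 0.4)

  # identity target: null off-diagonal correlations
  cfg2 <- cohort_config(n_timepoints = 2000, ar_coefficient = 0, seed = 1)
  set.seed(13)
  ts0 <- simulate_subject(diag(5), cfg2)
  r0 <- cor(ts0)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 3 / sqrt(2000))

  set.seed(7); a <- simulate_subject(R, cfg2)
  set.seed(7); b <- simulate_subject(R, cfg2)
  expect_identical(a, b)
  expect_error(simulate_subject(matrix(c(1, 2, 2, 1), 2), cfg2),
               "not positive definite")
})

test_that("simulate_mmse follows the linear model and clamps to [0, 30]", {
  cfg <- cohort_config(mmse_intercept = c(NC = 24, MCI = 22, AD = 18),
                       mmse_slope = 0, mmse_noise_sd = 0)
  expect_identical(simulate_mmse(0.4, "AD", cfg), 18L)
  cfg35 <- cohort_config(mmse_intercept = c(NC = 35, MCI = 22, AD = 18),
                         mmse_slope = 0, mmse_noise_sd = 0)
  expect_identical(simulate_mmse(0, "NC", cfg35), 30L)
  cfg_s <- cohort_config(mmse_slope = 10, mmse_noise_sd = 0)
  expect_gt(simulate_mmse(0.6, "NC", cfg_s), simulate_mmse(0.1, "NC", cfg_s))
})

test_that("simulate_cohort bookkeeping and determinism", {
  atlas <- toy_atlas(pairs = 3)
  spec <- cov_spec(atlas, affected_edges = data.frame(i = 1, j = 4))
  cfg <- cohort_config(group_sizes = c(NC = 3, MCI = 3, AD = 3),
                       n_timepoints = 60, seed = 5)
  co <- suppressWarnings(simulate_cohort(spec, cfg))
  expect_equal(nrow(co$covariates), 9)
  expect_length(co$series, 9)
  expect_equal(co$ground_truth$target_by_group,
               c(NC = 0.5, MCI = 0.35, AD = 0.2))
  co2 <- suppressWarnings(simulate_cohort(spec, cfg))
  expect_identical(co$covariates, co2$covariates)
  expect_identical(co$series, co2$series)

  # per-subject streams: growing AD leaves NC subjects untouched
  cfg_big <- cohort_config(group_sizes = c(NC = 3, MCI = 3, AD = 5),
                           n_timepoints = 60, seed = 5)
  co3 <- suppressWarnings(simulate_cohort(spec, cfg_big))
  expect_identical(co$series[["NC_01"]], co3$series[["NC_01"]])
  expect_identical(co$series[["MCI_03"]], co3$series[["MCI_03"]])
})

test_that("Monte-Carlo mean correlation at affected edges matches ground truth", {
  atlas <- toy_atlas(pairs = 5)
  ae <- data.frame(i = c(1, 3), j = c(6, 8))
  spec <- cov_spec(atlas, affected_edges = ae)
  cfg <- cohort_config(group_sizes = c(NC = 15, MCI = 0, AD = 15),
                       n_timepoints = 500, seed = 21)
  co <- simulate_cohort(spec, cfg)
  for (g in c("NC", "AD")) {
    ids <- co$covariates$subject_id[co$covariates$group == g]
    per_sub <- vapply(ids, function(sid) {
      r <- cor(co$series[[sid]])
      mean(r[cbind(ae$i, ae$j)])
    }, numeric(1))
    se <- sd(per_sub) / sqrt(length(per_sub))
    expect_lt(abs(mean(per_sub) - co$ground_truth$target_by_group[[g]]),
              2.5 * se + 0.01)
  }
})

test_that("render_toy_image round-trips through regional extraction", {
  atlas <- toy_atlas(pairs = 2)
  cfg <- cohort_config(n_timepoints = 40, seed = 3)
  set.seed(3)
  ts <- simulate_subject(diag(4), cfg)
  img <- render_toy_image(atlas, ts, voxels_per_region = 3, noise_sd = 0)
  got <- extract_regional_series(img$image, img$labels, atlas)
  expect_equal(unclass(got), unclass(ts), ignore_attr = TRUE,
               tolerance = 1e-12)

  # voxel noise averages down as sigma / sqrt(V)
  set.seed(4)
  imgN <- render_toy_image(atlas, ts, voxels_per_region = 25, noise_sd = 1)
  gotN <- extract_regional_series(imgN$image, imgN$labels, atlas)
  err_sd <- sd(as.numeric(gotN - ts))
  expect_lt(abs(err_sd - 1 / sqrt(25)), 0.1)
  expect_error(render_toy_image(atlas, ts, voxels_per_region = 0),
               "at least one voxel")
})
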