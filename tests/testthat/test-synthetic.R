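test_that("ground truth fields are masked, lateralized, and reproducible", {
  g <- desk_brain_grid()
  gt <- generate_ground_truth(g, seed = 3)
  expect_true(all(gt$deficit_weights[!g$mask] == 0))
  expect_true(all(gt$recovery_weights[!g$mask] == 0))
  # right-hemisphere deficit mass exceeds left (leftward-deviation bias)
  hem <- g$hemisphere
  dw <- gt$deficit_weights[g$mask_idx]
  expect_gt(sum(abs(dw[hem == "right"])), sum(abs(dw[hem == "left"])))
  # deterministic given the seed
  gt2 <- generate_ground_truth(g, seed = 3)
  expect_identical(gt$deficit_weights, gt2$deficit_weights)
  expect_identical(gt$recovery_weights, gt2$recovery_weights)

  # zero foci -> zero fields
  gt0 <- generate_ground_truth(g, ground_truth_config(n_foci_right = 0L,
                                                      n_foci_left = 0L,
                                                      recovery_total = 0),
                               seed = 1)
  expect_true(all(gt0$deficit_weights == 0))
  expect_true(all(gt0$recovery_weights == 0))

  # a single right-hemisphere focus concentrates its mass on the right
  gt1 <- generate_ground_truth(g, ground_truth_config(n_foci_right = 1L,
                                                      n_foci_left = 0L),
                               seed = 5)
  dw1 <- gt1$deficit_weights[g$mask_idx]
  expect_gt(sum(dw1[hem == "right"]), 0.8 * sum(dw1))
})

test_that("generated lesions are single 6-connected in-mask components", {
  g <- desk_brain_grid()
  for (seed in 1:10) {
    les <- generate_lesion(g, seed = seed)
    expect_true(all(les$voxels <= g$mask))
    expect_gte(lesion_volume(les)$voxels, 1)
    expect_equal(n_components_oracle(les), 1L)
  }
  one <- generate_lesion(g, volume_voxels = 1L, seed = 2)
  expect_equal(lesion_volume(one)$voxels, 1L)
  expect_error(generate_lesion(g, volume_voxels = g$n_in_mask + 1, seed = 1),
               "capacity")
})

test_that("lesion volumes follow the configured log-normal", {
  g <- desk_brain_grid()
  meanlog <- log(20); sdlog <- 0.5
  vols <- vapply(1:300, function(s)
    lesion_volume(generate_lesion(g, meanlog = meanlog, sdlog = sdlog,
                                  seed = s))$voxels, numeric(1))
  se <- sdlog / sqrt(length(vols))
  expect_lt(abs(mean(log(vols)) - meanlog), 3 * se + 0.05) # 0.05: rounding bias
})

test_that("gaze simulation follows the closed-form deficit sum", {
  g <- desk_brain_grid()
  cfg <- ground_truth_config(gaze_noise_sd_deg = 1e-12,
                             recovery_gaze_target_sd_deg = 1e-12,
                             persist_sd_deg = 1e-12)
  gt <- generate_ground_truth(g, cfg, seed = 2)
  empty <- lesion_map(g, array(FALSE, g$dims))
  gz <- simulate_gaze(empty, gt, seed = 1)
  expect_equal(gz$gaze_t1_deg, 0, tolerance = 1e-9)

  les <- generate_lesion(g, seed = 4)
  gz2 <- simulate_gaze(les, gt, seed = 1)
  expect_equal(gz2$gaze_t1_deg, -sum(gt$deficit_weights[les$voxels]),
               tolerance = 1e-9)
  expect_true(gz2$gaze_t1_deg > -180 && gz2$gaze_t1_deg <= 180)

  # zero recovery weights and zero intercept: recovery probability one half
  cfg0 <- ground_truth_config(recovery_total = 0, recovery_intercept = 0)
  gt0 <- generate_ground_truth(g, cfg0, seed = 2)
  recs <- vapply(1:400, function(s) simulate_gaze(les, gt0, seed = s)$natural_recovered,
                 logical(1))
  expect_lt(abs(mean(recs) - 0.5), 0.08) # binomial 3 SE at n = 400
})

test_that("cohorts are reproducible and their angles stay in range", {
  g <- desk_brain_grid()
  co1 <- generate_cohort(n = 30, grid = g, seed = 5)
  co2 <- generate_cohort(n = 30, grid = g, seed = 5)
  expect_identical(co1$covariates, co2$covariates)
  expect_identical(lapply(co1$lesions, `[[`, "voxels"),
                   lapply(co2$lesions, `[[`, "voxels"))
  expect_true(all(co1$covariates$gaze_t1_deg > -180 &
                  co1$covariates$gaze_t1_deg <= 180))
  expect_true(all(co1$covariates$age_years >= 18))
  one <- generate_cohort(n = 1, grid = g, seed = 9)
  expect_equal(nrow(one$covariates), 1L)
})

test_that("cohort population structure matches the design", {
  co <- tiny_cohort() # n = 220, default configuration
  cv <- co$covariates
  # admission gaze centred near the midline
  expect_lt(abs(circular_mean(cv$gaze_t1_deg)), 4)
  # substantial eligible fraction with non-trivial recovery
  expect_gt(mean(cv$eligible), 0.08)
  expect_gt(sum(cv$recovered, na.rm = TRUE), 3)
  # leftward-deviated patients carry predominantly right-hemisphere damage
  ratio <- vapply(co$lesions[cv$eligible], function(m)
    suppressWarnings(laterality_ratio(m)), numeric(1))
  expect_gt(mean(ratio, na.rm = TRUE), 0.8)
})

test_that("gaze laterality dependence has the constructed sign and is strong", {
  co <- tiny_cohort()
  cur <- gaze_laterality_curve(co)
  expect_lt(cur$slope, 0) # leftward gaze <-> right-hemisphere damage
  expect_lt(cur$slope_z, -3)
})

test_that("cohorts survive a write/read round trip", {
  g <- desk_brain_grid()
  co <- generate_cohort(n = 6, grid = g, seed = 13)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$covariates$gaze_t1_deg, co$covariates$gaze_t1_deg)
  expect_identical(lapply(back$lesions, `[[`, "voxels"),
                   lapply(co$lesions, `[[`, "voxels"))
  expect_equal(back$grid$n_in_mask, g$n_in_mask)
})
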