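test_that("the I-spline basis matches numerical integration of its derivative", {
  knots <- c(0.3, 0.6)
  xs <- seq(0, 1, by = 0.01)
  B <- ispline_basis(xs, knots, degree = 3L)
  # each basis function rises monotonically from 0 to 1
  expect_true(all(B >= -1e-12 & B <= 1 + 1e-12))
  expect_true(all(abs(B[1, ]) < 1e-12))
  expect_true(all(abs(B[length(xs), ] - 1) < 1e-12))
  expect_true(all(apply(B, 2, function(col) all(diff(col) >= -1e-12))))
  # oracle: cumulative trapezoid integration of the numerical derivative
  # reproduces each basis function
  for (j in seq_len(ncol(B))) {
    deriv <- diff(B[, j]) / diff(xs)
    recon <- c(0, cumsum((deriv) * diff(xs)))
    expect_equal(recon, B[, j], tolerance = 1e-3)
  }
})

test_that("points on the identity line give threshold 0.5", {
  pts <- data.frame(effect_size = seq(0.1, 0.9, 0.1),
                    detection_probability = seq(0.1, 0.9, 0.1))
  tf <- fit_therapeutic_function(pts)
  expect_true(tf$threshold_reached)
  expect_equal(tf$threshold, 0.5, tolerance = 0.02)
  expect_true(all(diff(predict(tf, seq(0, 1, 0.01))) >= -1e-9))
})

test_that("curves that never reach 0.5 are reported as not reached", {
  pts <- data.frame(effect_size = seq(0.1, 0.9, 0.1),
                    detection_probability = c(0.02, 0.05, 0.1, 0.15, 0.2,
                                              0.25, 0.3, 0.35, 0.4))
  tf <- fit_therapeutic_function(pts)
  expect_false(tf$threshold_reached)
  expect_true(is.na(tf$threshold))

  expect_error(fit_therapeutic_function(data.frame(
    effect_size = c(0.1, 0.5), detection_probability = c(0, 1))), "3 distinct")
})

test_that("a step between 0.6 and 0.7 pins the threshold inside the gap", {
  pts <- data.frame(effect_size = seq(0.1, 0.9, 0.1),
                    detection_probability = c(rep(0, 5), 0, 1, 1, 1))
  tf <- fit_therapeutic_function(pts)
  expect_gt(tf$threshold, 0.6)
  expect_lt(tf$threshold, 0.7)
})

test_that("threshold bisection recovers a known crossing to 1e-4", {
  # constant-1 curve: crossing at the origin
  tf1 <- fit_therapeutic_function(data.frame(
    effect_size = seq(0.1, 0.9, 0.2), detection_probability = 1))
  expect_equal(tf1$threshold, 0, tolerance = 2e-4) # bisection tolerance

  # monotone curve with an analytically known 0.5 crossing:
  # f(x) = x^2 crosses 0.5 at sqrt(0.5)
  xs <- seq(0.05, 0.95, by = 0.05)
  tf3 <- fit_therapeutic_function(data.frame(effect_size = xs,
                                             detection_probability = xs^2),
                                  robust = FALSE)
  expect_equal(tf3$threshold, sqrt(0.5), tolerance = 5e-3)
  # and the bisection itself terminates at the stated tolerance
  thr_fine <- estimate_threshold(tf3, tol = 1e-4)
  expect_lt(abs(predict(tf3, thr_fine) - 0.5), 0.01)
  expect_lt(abs(thr_fine - estimate_threshold(tf3, tol = 1e-6)), 2e-4)
})

test_that("robust reweighting resists a single outlying point", {
  xs <- seq(0.1, 0.9, 0.1)
  y <- stats::plogis((xs - 0.5) / 0.08)
  y_out <- y; y_out[2] <- 0.9 # gross outlier low in the curve
  tf_r <- fit_therapeutic_function(data.frame(effect_size = xs,
                                              detection_probability = y_out))
  tf_n <- fit_therapeutic_function(data.frame(effect_size = xs,
                                              detection_probability = y_out),
                                   robust = FALSE)
  true_thr <- 0.5
  expect_lt(abs(tf_r$threshold - true_thr), abs(tf_n$threshold - true_thr) + 0.02)
})

test_that("bootstrap threshold CIs are seeded, and degenerate data give zero width", {
  raw <- list(`0.2` = rep(FALSE, 50), `0.4` = rep(FALSE, 50),
              `0.6` = rep(TRUE, 50), `0.8` = rep(TRUE, 50))
  ci1 <- bootstrap_threshold_ci(raw, n_boot = 50, seed = 4)
  expect_equal(ci1$low, ci1$high) # zero-variance iterations -> zero width
  ci2 <- bootstrap_threshold_ci(raw, n_boot = 50, seed = 4)
  expect_identical(ci1$thresholds, ci2$thresholds)
})

test_that("mostly-unreached bootstrap replicates censor the interval", {
  withr::with_seed(10, {
    raw <- lapply(stats::setNames(seq(0.1, 0.9, 0.2), seq(0.1, 0.9, 0.2)),
                  function(e) stats::runif(40) < 0.15)
  })
  ci <- bootstrap_threshold_ci(raw, n_boot = 60, seed = 2)
  expect_true(ci$censored)
  expect_true(is.na(ci$high))
  expect_gt(ci$prop_not_reached, 0.10)
})
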