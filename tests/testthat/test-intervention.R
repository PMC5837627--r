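test_that("responder forcing hits the exact count with the documented rounding", {
  nat <- rep(FALSE, 101)
  expect_equal(sum(apply_non_altering(nat, 1, seed = 1)), 101L)
  expect_identical(apply_non_altering(nat, 0, seed = 1), nat)
  # p = 0.5 with 101 treated: round-half-up -> exactly 51 responders
  expect_equal(sum(apply_non_altering(nat, 0.5, seed = 3)), 51L)

  # forced recovery overwrites, never undoes, natural recovery
  nat2 <- rep(c(TRUE, FALSE), 25)
  out <- apply_non_altering(nat2, 0.4, seed = 5)
  expect_true(all(out[nat2]))
  expect_equal(sum(out & !nat2) <= 20, TRUE)

  # monotone in p for a fixed seed
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(p) sum(apply_non_altering(nat2, p, seed = 11)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))

  # bernoulli variant is seeded and respects p = 0/1
  expect_identical(apply_non_altering(nat, 0, seed = 1, method = "bernoulli"), nat)
  expect_equal(sum(apply_non_altering(nat, 1, seed = 1, method = "bernoulli")), 101L)
})

test_that("intervention specs validate their effect sizes", {
  s <- intervention_spec("non_altering", 0.4)
  expect_equal(s$kind, "non_altering")
  expect_error(intervention_spec("non_altering", 1.2), "effect_size")
})

# A fixture cohort with a hand-built classifier whose weights are known.
lesion_altering_fixture <- function() {
  co <- tiny_cohort()
  cv <- co$covariates
  eids <- cv$id[cv$eligible]
  model <- structure(list(
    weights = -vectorize(co$lesions[[eids[1]]]) * 0.05 +
      withr::with_seed(8, stats::rnorm(co$grid$n_in_mask, 0, 0.01)),
    bias = 0.4, training_ids = character(0), transductive = FALSE),
    class = "recovery_classifier")
  list(cohort = co, eligible = eids, model = model)
}

test_that("zero reduction under the classifier control rule is an exact null", {
  fx <- lesion_altering_fixture()
  half <- length(fx$eligible) %/% 2
  treated <- fx$eligible[seq_len(half)]
  control <- fx$eligible[-seq_len(half)]
  out <- apply_lesion_altering(fx$cohort, treated, control, 0, fx$model,
                               rule = "classifier_on_original", seed = 4)
  # both arms are scored by the same rule on unchanged lesions
  sc <- predict(fx$model, lesion_matrix(fx$cohort, c(treated, control)))
  expect_equal(out$outcome_recovered, sc$recovered)
  expect_equal(out$score, sc$score)
})

test_that("full reduction empties lesions and outcomes follow the bias sign", {
  fx <- lesion_altering_fixture()
  treated <- fx$eligible[1:5]; control <- fx$eligible[6:10]
  out <- apply_lesion_altering(fx$cohort, treated, control, 1, fx$model, seed = 2)
  tr <- out[out$treated, ]
  expect_true(all(tr$post_lesion_volume == 0))
  expect_equal(tr$outcome_recovered, rep(fx$model$bias > 0, 5))
  expect_equal(tr$score, rep(fx$model$bias, 5))
})

test_that("erosion of negative-weight voxels flips a borderline score", {
  g <- cube_grid(5)
  cube <- cuboid_lesion(g, 2:4, 2:4, 2:4)
  co <- structure(list(grid = g,
                       covariates = data.frame(id = "t1", gaze_t1_deg = -20,
                                               gaze_t2_deg = -20, eligible = TRUE,
                                               recovered = FALSE),
                       lesions = list(t1 = cube), ground_truth = NULL),
                  class = "cohort")
  w <- rep(-0.1, g$n_in_mask)
  model <- structure(list(weights = w, bias = 2.65, training_ids = character(0)),
                     class = "recovery_classifier")
  # score = 2.65 - 2.7 < 0; removing one voxel raises it above 0
  out0 <- apply_lesion_altering(co, "t1", character(0), 0, model, seed = 1)
  expect_false(out0$outcome_recovered)
  out1 <- apply_lesion_altering(co, "t1", character(0), 1 / 27, model, seed = 1)
  expect_true(out1$outcome_recovered)

  # monotone: all-negative weights mean recovery count never decreases in f
  recs <- vapply(seq(0, 1, by = 0.1), function(f)
    sum(apply_lesion_altering(co, "t1", character(0), f, model, seed = 1)$outcome_recovered),
    numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("the cached fast path agrees with explicit erosion plus prediction", {
  fx <- lesion_altering_fixture()
  treated <- fx$eligible[1:8]; control <- fx$eligible[9:12]
  cache <- therinf:::erosion_cache(fx$cohort, fx$model, c(treated, control))
  for (f in c(0.25, 0.6)) {
    fast <- apply_lesion_altering(fx$cohort, treated, control, f, fx$model,
                                  seed = 31, cache = cache)
    for (i in seq_along(treated)) {
      eroded <- erode_to_fraction(fx$cohort$lesions[[treated[i]]], f,
                                  seed = therinf:::mix_seed(31, 5L, i))
      pr <- predict(fx$model, vectorize(eroded))
      expect_equal(fast$score[i], pr$score)
      expect_equal(fast$post_lesion_volume[i], lesion_volume(eroded)$voxels)
    }
  }
})

test_that("training/trial overlap violates the independence contract", {
  fx <- lesion_altering_fixture()
  model <- fx$model
  model$training_ids <- fx$eligible[2]
  expect_error(
    apply_lesion_altering(fx$cohort, fx$eligible[1:3], fx$eligible[4:6], 0.5, model),
    "independence contract")
})

test_that("natural control rule returns observed outcomes", {
  fx <- lesion_altering_fixture()
  cvr <- fx$cohort$covariates
  control <- fx$eligible[1:6]
  out <- apply_lesion_altering(fx$cohort, fx$eligible[7:9], control, 0.3,
                               fx$model, rule = "natural", seed = 2)
  expect_equal(out$outcome_recovered[out$treated == FALSE],
               cvr$recovered[match(control, cvr$id)])
})
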