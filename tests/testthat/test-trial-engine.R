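test_that("randomization splits are exhaustive, disjoint and seeded", {
  ids <- sprintf("p%03d", 1:101)
  s <- randomize_arms(ids, 0.5, seed = 3)
  expect_equal(length(s$treated), 51L) # round-half-up of 50.5
  expect_equal(length(s$control), 50L)
  expect_length(intersect(s$treated, s$control), 0)
  expect_setequal(c(s$treated, s$control), ids)
  expect_identical(randomize_arms(ids, 0.5, seed = 3), s)

  two <- randomize_arms(c("a", "b"), 0.5, seed = 1)
  expect_length(two$treated, 1)
  expect_error(randomize_arms("a"), "at least 2")
})

test_that("identical arms give a zero intervention coefficient", {
  base <- data.frame(recovered = c(1, 0, 1, 0, 0, 1, 1, 0, 1, 0),
                     age = seq(40, 85, length.out = 10),
                     sex = rep(c(0, 1), 5),
                     volume = c(7, 3, 19, 2, 11, 30, 5, 16, 9, 22))
  df <- rbind(cbind(base, treated = 0), cbind(base, treated = 1))
  res <- fit_trial_model(df, "low_dim")
  expect_equal(res$coefficient, 0, tolerance = 1e-12)
})

test_that("a clean two-group contrast gives coefficient 1", {
  base <- data.frame(age = seq(40, 80, length.out = 10),
                     sex = rep(c(0, 1), 5),
                     volume = c(7, 3, 19, 2, 11, 30, 5, 16, 9, 22))
  df <- rbind(cbind(base, treated = 1, recovered = 1),
              cbind(base, treated = 0, recovered = 0))
  res <- fit_trial_model(df, "low_dim")
  expect_equal(res$coefficient, 1, tolerance = 1e-10)
  expect_true(res$positive)
})

test_that("OLS inference matches the closed-form oracle to 1e-10", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- 30
      df <- data.frame(recovered = rbinom(n, 1, 0.5), treated = rbinom(n, 1, 0.5),
                       age = rnorm(n, 65, 10), sex = rbinom(n, 1, 0.5),
                       volume = rpois(n, 20), score = rnorm(n))
      if (length(unique(df$treated)) < 2) next
      for (mk in c("low_dim", "high_dim")) {
        res <- fit_trial_model(df, mk)
        X <- cbind(1, df$treated, df$age, df$sex, df$volume)
        if (mk == "high_dim") X <- cbind(X, df$score)
        orc <- ols_oracle(X, df$recovered)
        expect_equal(res$coefficient, orc$coefficient, tolerance = 1e-10)
        expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)
      }
    }
  })
})

test_that("rank-deficient designs fail softly, never positively", {
  df <- data.frame(recovered = rbinom(20, 1, 0.5), treated = rep(c(0, 1), 10),
                   age = 50, sex = rep(c(0, 1), 10), volume = 7)
  df$sex <- df$treated # collinear with treatment
  df$age <- seq(30, 80, length.out = 20); df$volume <- seq(2, 40, length.out = 20)
  res <- fit_trial_model(df, "low_dim")
  expect_false(res$ok)
  expect_false(res$positive)
  expect_match(res$message, "rank")

  expect_error(fit_trial_model(df[, -1], "low_dim"), "missing columns")
})

test_that("the logistic alternative agrees with glm", {
  withr::with_seed(23, {
    df <- data.frame(recovered = rbinom(60, 1, 0.4), treated = rbinom(60, 1, 0.5),
                     age = rnorm(60, 65, 10), sex = rbinom(60, 1, 0.5),
                     volume = rpois(60, 15))
  })
  res <- fit_trial_model(df, "low_dim", family = "logistic")
  ref <- summary(stats::glm(recovered ~ treated + age + sex + volume,
                            family = stats::binomial(), data = df))$coefficients
  expect_equal(res$coefficient, ref["treated", "Estimate"], tolerance = 1e-8)
  expect_equal(res$p_value, ref["treated", "Pr(>|z|)"], tolerance = 1e-8)
})

test_that("OLS p-values track permutation p-values on small fixtures", {
  withr::with_seed(41, {
    p_ols <- p_perm <- numeric(12)
    for (i in 1:12) {
      n <- 24
      eff <- stats::runif(1, 0, 0.8)
      treated <- rep(c(1, 0), each = n / 2)
      recovered <- rbinom(n, 1, 0.3 + eff * treated * 0.5)
      df <- data.frame(recovered, treated, age = rnorm(n, 65, 10),
                       sex = rbinom(n, 1, 0.5), volume = rpois(n, 15))
      p_ols[i] <- fit_trial_model(df, "low_dim")$p_value
      X <- cbind(1, df$treated, df$age, df$sex, df$volume)
      obs <- abs(ols_oracle(X, df$recovered)$coefficient)
      perm <- replicate(400, {
        Xp <- X; Xp[, 2] <- sample(X[, 2])
        abs(ols_oracle(Xp, df$recovered)$coefficient)
      })
      p_perm[i] <- mean(perm >= obs - 1e-12)
    }
    expect_gt(stats::cor(rank(p_ols), rank(p_perm)), 0.85)
  })
})

test_that("trial batches are reproducible and pair the two model kinds", {
  co <- tiny_cohort()
  b1 <- run_trial_batch(co, "non_altering", effect_sizes = c(0.2, 0.8),
                        n_iterations = 25, master_seed = 7, cost = 0.1)
  b2 <- run_trial_batch(co, "non_altering", effect_sizes = c(0.2, 0.8),
                        n_iterations = 25, master_seed = 7, cost = 0.1)
  expect_identical(b1$table, b2$table)
  expect_identical(b1$raw, b2$raw)
  # paired design: identical iteration grid for both model kinds
  expect_equal(dim(b1$raw$low_dim), dim(b1$raw$high_dim))
  # classifier training pool is disjoint from the trial pool
  expect_length(intersect(b1$trial_ids, b1$classifier$training_ids), 0)
  # detection at a saturated effect exceeds a weak effect
  tab <- b1$table
  for (mk in c("low_dim", "high_dim")) {
    sub <- tab[tab$model_kind == mk, ]
    expect_gte(sub$detection_probability[2], sub$detection_probability[1])
  }
})

test_that("an explicitly overlapping trial pool is refused", {
  co <- tiny_cohort()
  eids <- co$covariates$id[co$covariates$eligible]
  x <- lesion_matrix(co, eids[1:15])
  y <- co$covariates$recovered[match(eids[1:15], co$covariates$id)]
  cls <- train_recovery_classifier(x, y, cost = 0.1, seed = 1)
  expect_error(
    run_trial_batch(co, "non_altering", effect_sizes = 0.5, n_iterations = 5,
                    classifier = cls, trial_ids = eids[10:25], master_seed = 1),
    "independence contract")
})

test_that("monotonicity check distinguishes ordered from shuffled curves", {
  up <- c(0.05, 0.1, 0.25, 0.4, 0.6, 0.8, 0.9, 0.97, 1)
  chk <- monotonicity_check(up, seed = 2)
  expect_true(chk$monotone)
  down <- rev(up)
  chk2 <- monotonicity_check(down, seed = 2)
  expect_false(chk2$monotone)
  # near-monotone with Monte-Carlo jitter still passes
  jit <- up + c(0, 0.01, -0.015, 0.01, 0, -0.01, 0.012, 0, 0)
  expect_true(monotonicity_check(jit, seed = 2)$monotone)
})
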