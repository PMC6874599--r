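test_that("r_squared and rmse match hand-computed examples", {
  truth <- c(0.1, 0.2, 0.3)
  pred <- c(0.1, 0.2, 0.4)
  expect_equal(r_squared(pred, truth), 0.5, tolerance = 1e-12)  # 1 - 0.01/0.02
  expect_equal(rmse(pred, truth), sqrt(0.01 / 3), tolerance = 1e-12)
  expect_equal(r_squared(truth, truth), 1)
  expect_equal(rmse(truth, truth), 0)
  expect_equal(r_squared(rep(mean(truth), 3), truth), 0)
  expect_equal(rmse(truth + 0.07, truth), 0.07)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
})

test_that("metrics agree with brute-force recomputation on random vectors", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    truth <- rnorm(n)
    if (stats::sd(truth) == 0) next
    pred <- truth + rnorm(n, sd = 0.3)
    expect_equal(r_squared(pred, truth), ref_r2(pred, truth), tolerance = 1e-12)
    expect_equal(rmse(pred, truth), ref_rmse(pred, truth), tolerance = 1e-12)
  }
})

test_that("split_within_range applies strict open bounds", {
  p <- dplyr::bind_rows(
    pulse_profile(A = 25, id = "in"),
    pulse_profile(A = 21.9, id = "edge_low"),
    pulse_profile(A = 40, id = "edge_high"),
    pulse_profile(A = 10, id = "low")
  )
  out <- split_within_range(p)
  expect_equal(out$within_range[out$impact_id == "in"], TRUE)
  expect_equal(out$within_range[out$impact_id == "edge_low"], FALSE)
  expect_equal(out$within_range[out$impact_id == "edge_high"], FALSE)
  expect_equal(out$within_range[out$impact_id == "low"], FALSE)
})

test_that("every augmented impact lies within the focused band", {
  base <- generate_profiles(profile_gen_params(n_impacts = 30, seed = 17))
  aug <- augment_dataset(base, augmentation_config(n_batches = 2, seed = 18))
  expect_true(all(split_within_range(aug)$within_range))
})

test_that("corrected_cv_ttest reproduces its closed form and conventions", {
  a <- c(0.91, 0.93, 0.90, 0.95, 0.92)
  b <- c(0.90, 0.91, 0.91, 0.92, 0.90)
  k <- 10
  got <- corrected_cv_ttest(a, b, k = k)
  # independent evaluation of the stated formula
  d <- a - b
  t_want <- mean(d) / sqrt(stats::var(d) * (1 / 5 + 1 / (k - 1)))
  expect_equal(got$statistic, t_want, tolerance = 1e-12)
  expect_equal(got$p.value, stats::pt(t_want, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$parameter, 4)

  # null conventions
  same <- corrected_cv_ttest(a, a, k = k)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 0.5)

  # the correction inflates the denominator relative to the naive paired test
  p_naive <- stats::t.test(a, b, paired = TRUE, alternative = "greater")$p.value
  expect_gte(got$p.value, p_naive)
})

test_that("welch_ttest matches Student's t for equal-variance samples", {
  set.seed(23)
  a <- rnorm(12, 1)
  b <- a - 0.4  # identical sample variance by construction
  got <- welch_ttest(a, b)
  student <- stats::t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(got$statistic, unname(student$statistic), tolerance = 1e-10)
  expect_equal(got$p.value, student$p.value, tolerance = 1e-10)
  expect_equal(got$parameter, 22, tolerance = 1e-8)

  expect_equal(welch_ttest(rep(1, 3), rep(1, 4))$p.value, 0.5)
  sep <- welch_ttest(rnorm(10, 10, 0.01), rnorm(10, 0, 0.01))
  expect_lt(sep$p.value, 0.05)
})

test_that("kfold_cv partitions correctly and is seed-reproducible", {
  set.seed(33)
  enc <- encode_profiles(scale_magnitude(random_profiles(60, T = 30), 21.9, 40))
  y <- runif(60, 0.1, 0.3)
  plan <- cv_plan(k = 3, n_trials = 2, seeds = c(101L, 202L))
  cfg <- training_config(epochs = 2, batch_size = 16)
  cv1 <- kfold_cv(enc, y, plan, config = cfg)
  expect_equal(nrow(cv1), 2)
  for (tr in 1:2) {
    pr <- cv1$predictions[[tr]]
    expect_equal(nrow(pr), 60)                     # pooled count = dataset size
    expect_equal(sort(unique(pr$fold)), 1:3)
    expect_equal(as.vector(table(pr$fold)), rep(20, 3))
  }
  # identical seeds -> identical folds and identical pooled predictions
  cv2 <- kfold_cv(enc, y, plan, config = cfg)
  expect_identical(cv1$predictions[[1]]$fold, cv2$predictions[[1]]$fold)
  expect_identical(cv1$r2, cv2$r2)
  # different trials shuffle differently
  expect_false(identical(cv1$predictions[[1]]$fold, cv1$predictions[[2]]$fold))
})
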