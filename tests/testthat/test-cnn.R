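test_that("shape arithmetic matches an enumeration oracle", {
  spec <- cnn_spec()
  sh <- cnn_shapes(spec)
  # independent route: enumerate valid kernel start positions
  w <- 201
  widths <- integer(0)
  for (l in 1:3) {
    w <- ref_conv_width(w, spec$conv_kernel[l], spec$conv_stride[l])
    widths <- c(widths, w)
  }
  expect_equal(sh$conv_widths, widths)
  expect_equal(widths, c(96, 44, 40))
  expect_equal(sh$flatten, 40 * 32)
  expect_equal(sh$flatten, 1280)
})

test_that("parameter count equals the total size of the built weights", {
  spec <- cnn_spec()
  model <- build_cnn(spec, seed = 1)
  expect_equal(cnn_shapes(spec)$n_parameters,
               sum(vapply(model$weights, length, 0L)))
  # a spec whose kernel exceeds the feature map fails at build time
  bad <- cnn_spec(conv_filters = c(8, 8), conv_kernel = c(150, 30),
                  conv_stride = c(2, 2))
  expect_error(build_cnn(bad), "kernel")
  expect_error(cnn_spec(fc_sizes = c(64, 3)), "width 1")
})

test_that("compiled forward pass agrees with the pure-R reference", {
  set.seed(31)
  spec <- cnn_spec()
  model <- build_cnn(spec, seed = 31)
  # give the zero-initialized head nonzero weights so outputs are informative
  nw <- length(model$weights)
  model$weights[[nw - 1]] <- matrix(rnorm(64, sd = 0.05), 1, 64)
  model$weights[[nw]] <- matrix(0.1, 1, 1)
  model$trained <- TRUE  # hand-weighted; silences the untrained-predict warning
  enc <- encode_profiles(scale_magnitude(random_profiles(8, T = 50), 21.9, 40))
  got <- predict(model, enc)
  expect_gt(max(got), 0)
  want <- vapply(seq_len(8), function(i) {
    ref_forward_one(model$weights, enc$inputs[i, , ], spec)
  }, 0)
  expect_equal(got, want, tolerance = 1e-4)  # single vs double precision
})

test_that("training fits constant labels and honours early stopping", {
  set.seed(41)
  enc <- encode_profiles(scale_magnitude(random_profiles(80, T = 40), 21.9, 40))
  cfg <- training_config(epochs = 15, batch_size = 16, seed = 1)
  fit <- train_cnn(build_cnn(cnn_spec(), seed = 2), enc, labels = rep(0.2, 80),
                   config = cfg)
  pr <- predict(fit, enc)
  expect_true(all(abs(pr - 0.2) / 0.2 < 0.1))
  # early-stopping contract: returned weights achieve the best validation loss
  h <- tidy(fit)
  expect_equal(min(h$val_loss), h$val_loss[fit$best_epoch])
  expect_lte(min(h$val_loss), h$val_loss[nrow(h)])
})

test_that("training reduces loss on oracle-labelled data below label variance", {
  set.seed(51)
  ds <- make_dataset(profile_gen_params(n_impacts = 40, seed = 5),
                     oracle_params(noise_sd = 0),
                     augmentation_config(n_batches = 1, seed = 6))
  y <- ds$labels$MPS_WB_95
  cfg <- training_config(epochs = 100, batch_size = 32, seed = 3)
  fit <- train_cnn(build_cnn(cnn_spec(), seed = 4), ds, labels = y, config = cfg)
  h <- tidy(fit)
  # beats the predict-the-mean baseline on held-out validation data
  expect_lt(min(h$val_loss), stats::var(y))
  # loss decreases over the first epochs (trainability)
  expect_lt(mean(tail(h$train_loss, 5)), h$train_loss[1])
})

test_that("prediction is deterministic, non-negative and batch-consistent", {
  set.seed(61)
  enc <- encode_profiles(scale_magnitude(random_profiles(70, T = 35), 21.9, 40))
  fit <- train_cnn(build_cnn(cnn_spec(), seed = 7), enc,
                   labels = runif(70, 0.1, 0.3),
                   config = training_config(epochs = 10, batch_size = 16, seed = 8))
  p1 <- predict(fit, enc)
  p2 <- predict(fit, enc)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  # batch prediction equals per-sample prediction
  singles <- vapply(seq_len(10), function(i) {
    predict(fit, enc$inputs[i, , , drop = FALSE])
  }, 0)
  expect_equal(p1[1:10], singles, tolerance = 1e-5)
  expect_error(predict(fit, matrix(0, 10, 3)), "603 rows")
})

test_that("training is reproducible from its seed", {
  set.seed(71)
  enc <- encode_profiles(scale_magnitude(random_profiles(70, T = 35), 21.9, 40))
  y <- runif(70, 0.1, 0.3)
  cfg <- training_config(epochs = 8, batch_size = 16, seed = 99)
  f1 <- train_cnn(build_cnn(cnn_spec(), seed = 9), enc, y, cfg)
  f2 <- train_cnn(build_cnn(cnn_spec(), seed = 9), enc, y, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("models survive a save/load round trip", {
  set.seed(81)
  enc <- encode_profiles(scale_magnitude(random_profiles(64, T = 30), 21.9, 40))
  fit <- train_cnn(build_cnn(cnn_spec(), seed = 10), enc,
                   labels = runif(64, 0.1, 0.3),
                   config = training_config(epochs = 5, batch_size = 16, seed = 11),
                   measure = "MPS_CC_95")
  dir <- withr::local_tempdir()
  save_cnn(fit, dir)
  back <- load_cnn(dir)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$measure, "MPS_CC_95")
  expect_equal(predict(back, enc), predict(fit, enc))
})
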