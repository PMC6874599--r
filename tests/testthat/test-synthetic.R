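test_that("generated profiles respect counts, window and peak range", {
  params <- profile_gen_params(n_impacts = 110, seed = 1)
  p <- generate_profiles(params)
  expect_equal(dplyr::n_distinct(p$impact_id), 110)
  spans <- dplyr::summarise(dplyr::group_by(p, impact_id),
                            span = max(time_ms) - min(time_ms))
  expect_true(all(spans$span <= 200))
  pk <- peak_resultant(p)$peak_magnitude
  expect_true(all(pk >= 5 & pk <= 40))
})

test_that("without reversal every resultant is unimodal", {
  p <- generate_profiles(profile_gen_params(n_impacts = 50, reversal_prob = 0,
                                            seed = 2))
  split <- strainnet:::prof_split(add_resultant(p))
  for (i in seq_along(split$ids)) {
    r <- add_resultant(p[p$impact_id == split$ids[i], ])$w_res
    k <- which.max(r)
    expect_true(all(diff(r[1:k]) >= -1e-12))
    expect_true(all(diff(r[k:length(r)]) <= 1e-12))
  }
  # with reversal_prob = 1 the resultant has a second lobe
  pr <- generate_profiles(profile_gen_params(n_impacts = 5, reversal_prob = 1,
                                             seed = 3))
  r <- add_resultant(pr[pr$impact_id == "imp001", ])$w_res
  expect_gt(length(r), 20)
})

test_that("oracle_strain evaluates its closed form exactly", {
  # single pulse, peak A = v50, direction +x, defaults a = (0.2, 0.4, 0.3)
  p <- pulse_profile(A = 30, Td = 20, dir = c(1, 0, 0))
  par <- oracle_params(noise_sd = 0)
  got <- oracle_strain(p, "MPS_WB_95", par)$MPS_WB_95
  H <- 0.5                        # A = v50
  D <- (1 + 0.2) / (1 + 0.4)      # u = (1,0,0), max weight 0.4
  S <- 1 + 0.3                    # TV = 2A for a single pulse
  expect_equal(got, 0.45 * H * D * S, tolerance = 1e-12)

  # all-zero motion has zero strain, without error
  zero <- profile_from_matrix(matrix(0, 3, 10))
  expect_equal(oracle_strain(zero, "MPS_WB_95", par)$MPS_WB_95, 0)
})

test_that("the noiseless oracle is exactly mirror-symmetric", {
  set.seed(4)
  p <- random_profiles(200, T = 25)
  par <- oracle_params(noise_sd = 0)
  for (ms in strain_measures()) {
    expect_equal(oracle_strain(mirror_profile(p), ms, par)[[ms]],
                 oracle_strain(p, ms, par)[[ms]], tolerance = 1e-14)
  }
})

test_that("the noiseless oracle increases under magnitude scaling", {
  par <- oracle_params(noise_sd = 0)
  p <- pulse_profile(A = 15, Td = 24, dir = c(1, 2, 2))
  eps <- vapply(c(1, 1.3, 2, 3), function(s) {
    q <- p
    q[c("wx", "wy", "wz")] <- q[c("wx", "wy", "wz")] * s
    oracle_strain(q, "MPS_WB_95", par)$MPS_WB_95
  }, 0)
  expect_true(all(diff(eps) > 0))
})

test_that("the oracle responds smoothly to peak amplitude", {
  par <- oracle_params(noise_sd = 0)
  A <- seq(6, 39, by = 0.5)
  eps <- vapply(A, function(a) {
    oracle_strain(pulse_profile(A = a, Td = 20, dir = c(1, 1, 1)),
                  "MPS_WB_95", par)$MPS_WB_95
  }, 0)
  grad <- diff(eps) / 0.5
  # finite-difference gradient is positive and has no jumps
  expect_true(all(grad > 0))
  expect_lt(max(abs(diff(grad))), 0.01)
})

test_that("make_dataset chains the pipeline reproducibly with bounded labels", {
  ds1 <- make_dataset(profile_gen_params(n_impacts = 10, seed = 5),
                      oracle_params(noise_sd = 0, seed = 6),
                      augmentation_config(n_batches = 2, seed = 7))
  expect_equal(length(ds1), 120)  # 10 * 6 * 2
  for (ms in strain_measures()) {
    par <- oracle_params()
    expect_true(all(ds1$labels[[ms]] >= 0))
    expect_true(all(ds1$labels[[ms]] <= par$eps_max[[ms]] * (1 + par$shape_gain)))
  }
  ds2 <- make_dataset(profile_gen_params(n_impacts = 10, seed = 5),
                      oracle_params(noise_sd = 0, seed = 6),
                      augmentation_config(n_batches = 2, seed = 7))
  expect_identical(ds1$inputs, ds2$inputs)
  expect_identical(ds1$labels, ds2$labels)
})
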