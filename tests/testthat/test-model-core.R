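test_that("time grid is evenly spaced and validates its arguments", {
  g <- time_grid(0.5, 1)
  expect_equal(g$times, c(0, 0.5, 1))
  expect_equal(time_grid(0.01, 2)$n_steps, 201L)
  expect_error(time_grid(0, 1), "positive")
  expect_error(time_grid(0.5, 0.5), "at least")
})

test_that("raised-cosine trajectory has the right peak, support and displacement", {
  g <- default_grid()
  prof <- trajectory_profile(amplitude = 60, movement_duration = 1, onset = 0.5)
  truth <- generate_trajectory(prof, g)
  tt <- g$times
  expect_true(all(truth$values[tt < 0.5 | tt > 1.5] == 0))
  expect_equal(truth$values[tt == 1.0], 60) # sin^2 peak at window midpoint
  expect_equal(max(truth$values), 60)
  # closed form: integral of A sin^2(pi t / T) over the window = A T / 2;
  # cross-checked by quadrature
  quad <- integrate(function(t) 60 * sin(pi * (t - 0.5))^2, 0.5, 1.5)$value
  expect_equal(quad, 30, tolerance = 1e-8)
  expect_equal(series_displacement(truth), 30, tolerance = 1e-4)

  zero <- generate_trajectory(trajectory_profile(amplitude = 0), g)
  expect_true(all(zero$values == 0))
  expect_error(
    generate_trajectory(trajectory_profile(onset = 1.5, movement_duration = 1), g),
    "exceeds")
})

test_that("trajectory displacement is grid-refinement consistent", {
  prof <- trajectory_profile()
  d1 <- series_displacement(generate_trajectory(prof, time_grid(0.01, 2)))
  d2 <- series_displacement(generate_trajectory(prof, time_grid(0.005, 2)))
  expect_lt(abs(d2 - d1) / abs(d1), 0.001)
})

test_that("healthy observations are truth plus calibrated Gaussian noise", {
  g <- time_grid(0.01, 1000) # 1e5 steps of zero truth
  zero <- generate_trajectory(trajectory_profile(amplitude = 0), g)
  w <- world_model("healthy", sensor_noise_sd = 5)
  y <- generate_observations(zero, w, seed = 11)$values
  n <- length(y)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(y)), 3 * 5 / sqrt(n))
  expect_lt(abs(sd(y) / 5 - 1), 0.02)

  # noiseless limit
  truth <- default_truth()
  y0 <- generate_observations(truth, world_model("healthy", sensor_noise_sd = 0),
                              seed = 1)
  expect_identical(y0$values, truth$values)
})

test_that("BVP observations are independent of the true velocity", {
  g <- time_grid(0.001, 20) # 2e4 steps, several bell cycles worth of data
  prof <- trajectory_profile(amplitude = 60, movement_duration = 10, onset = 5)
  truth <- generate_trajectory(prof, g)
  y <- generate_observations(truth, world_model("bvp", bvp_noise_sd = 2),
                             seed = 3)$values
  expect_lt(abs(cor(y, truth$values)), 3 / sqrt(length(y)))
})

test_that("observation and knowledge generation are seed-reproducible", {
  truth <- default_truth()
  w <- world_model("bvp")
  expect_identical(generate_observations(truth, w, 5)$values,
                   generate_observations(truth, w, 5)$values)
  expect_false(identical(generate_observations(truth, w, 5)$values,
                         generate_observations(truth, w, 6)$values))
  kp <- knowledge_params(knowledge_noise_sd = 2)
  expect_identical(generate_knowledge(truth, kp, TRUE, 9)$values,
                   generate_knowledge(truth, kp, TRUE, 9)$values)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_observations(default_truth(), world_model("healthy"), 1))
  expect_identical(.Random.seed, before)
})

test_that("knowledge signal respects the active/passive switch and its parameters", {
  truth <- default_truth()
  passive <- generate_knowledge(truth, knowledge_params(), FALSE, 1)
  expect_true(all(passive$values == 0))

  perfect <- generate_knowledge(truth,
                                knowledge_params(knowledge_gain = 1,
                                                 knowledge_noise_sd = 0),
                                TRUE, 1)
  expect_equal(perfect$values, truth$values)

  half <- generate_knowledge(truth,
                             knowledge_params(knowledge_gain = 0.5,
                                              knowledge_noise_sd = 0),
                             TRUE, 1)
  expect_equal(half$values, 0.5 * truth$values)
  expect_equal(max(half$values), 30)

  delayed <- generate_knowledge(truth,
                                knowledge_params(knowledge_gain = 1,
                                                 knowledge_noise_sd = 0,
                                                 knowledge_delay = 0.1),
                                TRUE, 1)
  k <- 10 # 0.1 s at dt = 0.01
  n <- truth$grid$n_steps
  expect_equal(delayed$values[(k + 1):n], truth$values[1:(n - k)])
  expect_true(all(delayed$values[1:k] == 0))
})
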