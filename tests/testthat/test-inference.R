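make_ensemble <- function(v, w) {
  structure(list(velocities = v, weights = w), class = "particle_ensemble")
}

test_that("systematic resampling is stratified and count-exact", {
  # uniform weights: every particle appears exactly once
  ens <- make_ensemble(1:5, rep(0.2, 5))
  out <- systematic_resample(ens, 0.37)
  expect_equal(sort(out$velocities), 1:5)
  expect_equal(out$weights, rep(0.2, 5))

  # one particle with all the weight: N copies of it
  ens1 <- make_ensemble(c(7, 8, 9), c(0, 1, 0))
  expect_equal(systematic_resample(ens1, 0.9)$velocities, c(8, 8, 8))

  # w = (0.5, 0.25, 0.25), N = 4: offspring counts (2, 1, 1) for every u,
  # verified by enumerating the sweep over a fine grid of offsets
  ens3 <- make_ensemble(c(10, 20, 30), c(0.5, 0.25, 0.25))
  for (u in seq(0, 0.999, by = 0.013)) {
    out4 <- systematic_resample(ens3, u, n_out = 4)
    counts <- tabulate(match(out4$velocities, ens3$velocities), 3)
    expect_equal(counts, c(2, 1, 1))
  }
  # and offspring counts never differ from N * w_i by 1 or more
  set.seed(4)
  for (i in 1:25) {
    w <- rexp(6); w <- w / sum(w)
    ens6 <- make_ensemble(1:6, w)
    out6 <- systematic_resample(ens6, runif(1))
    counts <- tabulate(match(out6$velocities, 1:6), 6)
    expect_true(all(abs(counts - 6 * w) < 1))
  }
})

test_that("exact filter reproduces the conjugate-normal closed form", {
  # static case: decay 1, no knowledge pull, no process noise, constant truth
  n <- 400
  sv <- 3
  g <- time_grid(0.01, (n - 1) * 0.01)
  m <- internal_model(decay = 1, process_noise_sd = 0, knowledge_weight = 0,
                      assumed_sensor_noise_sd = sv,
                      initial_mean = 0, initial_sd = 1000 * sv)
  truth <- vestibsim:::new_velocity_series(g, rep(15, n))
  obs <- generate_observations(truth, world_model("healthy",
                                                  sensor_noise_sd = sv), 2)
  know <- generate_knowledge(truth, knowledge_params(), FALSE, 1)
  tr <- exact_filter(obs, know, FALSE, m)
  expect_equal(tr$sd[n], sv / sqrt(n), tolerance = 0.01)
  expect_equal(tr$mean[n], mean(obs$values), tolerance = 1e-6)
})

test_that("exact filter handles the noiseless and uninformative limits", {
  truth <- default_truth()
  obs <- generate_observations(truth, world_model("healthy"), 4)
  know <- generate_knowledge(truth, knowledge_params(), FALSE, 5)

  # assumed sensor noise 0: posterior collapses onto the observations
  m0 <- internal_model(assumed_sensor_noise_sd = 0)
  tr0 <- exact_filter(obs, know, FALSE, m0)
  expect_equal(tr0$mean, obs$values)
  expect_true(all(tr0$sd == 0))

  # uninformative likelihood, zero knowledge, zero initial mean: stays at 0
  mInf <- internal_model(assumed_sensor_noise_sd = 1e6 * 6)
  trInf <- exact_filter(obs, know, FALSE, mInf)
  expect_true(max(abs(trInf$mean)) < 1e-3 * 60)
})

test_that("particle filter tracks observations in the near-noiseless limit", {
  truth <- default_truth()
  obs <- generate_observations(truth, world_model("healthy",
                                                  sensor_noise_sd = 0), 1)
  know <- generate_knowledge(truth, knowledge_params(), FALSE, 1)
  m <- internal_model(assumed_sensor_noise_sd = 0.01)
  tr <- particle_filter(obs, know, FALSE, m, n_particles = 4000, seed = 8)
  expect_lt(max(abs(tr$mean - obs$values)[-(1:3)]), 0.02)
})

test_that("particle filter agrees with the exact filter and keeps valid diagnostics", {
  res <- run_named_condition("healthy_passive", n_particles = 20000, seed = 7)
  rmse <- sqrt(mean((res$pf$mean - res$exact$mean)^2))
  expect_lt(rmse, 0.02 * 60)
  # posterior sds agree too (weighted, biased estimator vs closed form)
  expect_lt(max(abs(res$pf$sd - res$exact$sd)), 0.05 * 60)
  expect_true(all(res$pf$ess > 0 & res$pf$ess <= 20000))
  expect_true(all(res$pf$sd >= 0))
  expect_true(any(res$pf$resampled))
})

test_that("particle filter is reproducible and grid-checked", {
  truth <- default_truth()
  obs <- generate_observations(truth, world_model("bvp"), 2)
  know <- generate_knowledge(truth, knowledge_params(), FALSE, 3)
  m <- internal_model()
  a <- particle_filter(obs, know, FALSE, m, n_particles = 500, seed = 10)
  b <- particle_filter(obs, know, FALSE, m, n_particles = 500, seed = 10)
  expect_identical(a, b)
  c <- particle_filter(obs, know, FALSE, m, n_particles = 500, seed = 11)
  expect_false(identical(a$mean, c$mean))

  other <- generate_knowledge(default_truth(time_grid(0.02, 2)),
                              knowledge_params(), FALSE, 1)
  expect_error(particle_filter(obs, other, FALSE, m, seed = 1), "grid")
  expect_error(particle_filter(obs, know, FALSE, m, n_particles = 10,
                               seed = 1), ">= 100")
})

test_that("imagery runs the prediction chain without any update", {
  g <- default_grid()
  truth <- default_truth(g)
  zeros <- generate_knowledge(truth, knowledge_params(), FALSE, 1)

  m <- internal_model(initial_mean = 0)
  null_im <- run_imagery(zeros, m)
  expect_true(all(null_im$mean == 0))

  # full pull to a noiseless knowledge signal reproduces it exactly
  know <- generate_knowledge(truth,
                             knowledge_params(knowledge_gain = 1,
                                              knowledge_noise_sd = 0),
                             TRUE, 1)
  m1 <- internal_model(knowledge_weight = 1)
  expect_equal(run_imagery(know, m1)$mean, truth$values)

  # with decay 1 and no knowledge pull the variance recursion is
  # var' = var + sigma_q^2: sd never decreases
  m2 <- internal_model(decay = 1, knowledge_weight = 0, process_noise_sd = 2)
  sds <- run_imagery(zeros, m2)$sd
  expect_true(all(diff(sds) >= 0))
  expect_equal(sds[1]^2, 1 + 4) # initial_sd^2 + sigma_q^2
})

test_that("an uninformative likelihood turns the filter into imagery", {
  truth <- default_truth()
  obs <- generate_observations(truth, world_model("bvp"), 6)
  know <- generate_knowledge(truth, knowledge_params(knowledge_noise_sd = 0),
                             TRUE, 7)
  m <- apply_conventional_rehab(internal_model(), 1e6)
  tr <- exact_filter(obs, know, TRUE, m)
  im <- run_imagery(know, m)
  expect_lt(max(abs(tr$mean - im$mean)), 0.005 * 60)
})

test_that("vestib_filter front end dispatches and summarises", {
  truth <- default_truth()
  obs <- generate_observations(truth, world_model("healthy"), 1)
  know <- generate_knowledge(truth, knowledge_params(), TRUE, 2)
  fit <- vestib_filter(obs, know, TRUE, n_particles = 800, seed = 3,
                       truth = truth)
  expect_s3_class(fit, "vestib_filter")
  expect_s3_class(fit, "posterior_trace")
  expect_equal(fitted(fit), fit$mean)
  expect_equal(residuals(fit), obs$values - fit$mean)
  s <- summary(fit)
  expect_s3_class(s$metrics, "data.frame")
  expect_gt(s$metrics$displacement_gain, 0.5)

  ex <- vestib_filter(obs, know, TRUE, method = "exact")
  expect_identical(ex$method, "exact")
  df <- as.data.frame(ex)
  expect_named(df, c("time_s", "post_mean", "post_sd", "ess", "resampled"))
})
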