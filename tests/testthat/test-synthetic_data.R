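test_that("environment generation is seeded and honours the summer offset", {
  cfg <- scenario_config()
  e1 <- gen_environment(cfg, seed = 3)
  e2 <- gen_environment(cfg, seed = 3)
  expect_identical(e1, e2)
  expect_false(identical(e1$series, gen_environment(cfg, seed = 4)$series))

  # configured warming of stream 2 inside the window
  s <- e1$series
  win <- s$date >= cfg$summer_offset_window[1] &
    s$date <= cfg$summer_offset_window[2]
  d_in <- mean(s$temp_c[win & s$stream == "todd"]) -
    mean(s$temp_c[win & s$stream == "indian"])
  expect_equal(d_in, cfg$summer_offset_c, tolerance = 0.35)
  d_out <- mean(s$temp_c[!win & s$stream == "todd"]) -
    mean(s$temp_c[!win & s$stream == "indian"])
  expect_lt(abs(d_out), 0.35)

  # zero noise, zero offset: the two streams share one sinusoid
  cfg0 <- scenario_config(temp_noise_sd = 0, summer_offset_c = 0)
  e0 <- gen_environment(cfg0, seed = 5)
  expect_equal(e0$series$temp_c[e0$series$stream == "indian"],
               e0$series$temp_c[e0$series$stream == "todd"])

  # generated series pass the reader validation and look like the target
  # regime: bi-monthly gaps, seasonal span, positive levels
  expect_true(all(e1$calendar$n_days >= 48 & e1$calendar$n_days <= 70))
  expect_true(all(s$level_m > 0))
  expect_gt(max(s$temp_c), 20)
  expect_lt(min(s$temp_c), 5)
})

test_that("true parameters follow the configured variance components", {
  cfg <- scenario_config(sigma2_t = 0, sigma2_j = 0, sigma2_s = 0,
                         sigma2_js = 0)
  cal <- make_calendar(15)
  tr <- gen_parameters(cfg, cal, seed = 2)
  expect_true(all(tr$params$eps1 == 0))
  expect_true(all(tr$params$eps4 == 0))
  expect_true(all(tr$params$p >= 0.18 & tr$params$p <= 0.53))
  # with no effects, 60-day survival is the inverse-logit intercept
  expect_equal(tr$phi60[, 1], plogis(cfg$mu))

  # law of large numbers on the common temporal effect
  cal_big <- occasion_calendar(as.Date("2000-01-01") + 60 * 0:10000)
  cfg2 <- scenario_config()
  tr2 <- gen_parameters(cfg2, cal_big, seed = 3)
  expect_equal(var(tr2$params$eps1), 0.60, tolerance = 0.05)

  # seeded reproducibility
  expect_identical(gen_parameters(cfg2, cal, seed = 9),
                   gen_parameters(cfg2, cal, seed = 9))
})

test_that("capture simulation obeys degenerate survival and detection", {
  cal <- make_calendar(5)
  idx_cfg <- scenario_config(species = "A", streams = "X",
                             entry_totals = 40, entry_scale = 1,
                             n_occasions = 5, sigma2_t = 0, sigma2_j = 0,
                             sigma2_s = 0, sigma2_js = 0)

  # survival zero: nobody is seen after entry
  cfg0 <- idx_cfg; cfg0$mu <- -40
  tr0 <- gen_parameters(cfg0, cal, seed = 1)
  sim0 <- simulate_capture_histories(cfg0, tr0, cal, seed = 1)
  expect_true(all(rowSums(sim0$matrix$y) == 1))
  expect_equal(nrow(sim0$matrix$y), 40)

  # survival one, detection one: detected on every occasion from entry
  cfg1 <- idx_cfg; cfg1$mu <- 40; cfg1$detection_range <- c(1, 1) - 1e-9
  tr1 <- gen_parameters(cfg1, cal, seed = 1)
  sim1 <- simulate_capture_histories(cfg1, tr1, cal, seed = 1)
  y <- sim1$matrix$y
  first <- sim1$matrix$individuals$first_capture
  for (i in seq_len(nrow(y)))
    expect_true(all(y[i, first[i]:ncol(y)] == 1L))
})

test_that("detection-after-entry fraction matches the binomial expectation", {
  cal <- make_calendar(3)
  cfg <- scenario_config(species = "A", streams = "X",
                         entry_totals = 10000, entry_scale = 1,
                         n_occasions = 3, mu = qlogis(0.8),
                         detection_range = c(0.5, 0.5),
                         sigma2_t = 0, sigma2_j = 0, sigma2_s = 0,
                         sigma2_js = 0)
  tr <- gen_parameters(cfg, cal, seed = 6)
  sim <- simulate_capture_histories(cfg, tr, cal, seed = 6)
  entrants <- sim$matrix$individuals$first_capture == 1
  frac <- mean(sim$matrix$y[entrants, 2])
  expect_equal(frac, 0.8 * 0.5, tolerance = 0.04)
  # latent states agree with the recorded detections
  expect_true(all(sim$matrix$y[sim$states == 0 & !is.na(sim$states)] == 0))
})

test_that("full cycle: covariate-plus-random-effects fit recovers the generated signal", {
  cfg <- scenario_config(seed = 7, covariate_effect = TRUE, beta = -0.5)
  sim <- simulate_dataset(cfg)
  fit <- fit_cjs(sim$matrix,
                 model_spec("random_effects_plus_covariate",
                            covariate = "mean_temp"),
                 x = sim$x, calendar = sim$calendar,
                 settings = mcmc_settings(chains = 3, iterations = 16000,
                                          burn_in = 4000, thin = 6,
                                          seed = 5))
  b <- fit$summary[fit$summary$parameter == "beta", ]
  expect_lt(b$mean, 0)  # sign of the true effect
  # the shared effect size is identified only up to the realized
  # x-correlated component of the drawn random effects; the credible
  # interval must cover that realized shared-signal regression
  shared <- colMeans(qlogis(sim$truth$phi60))
  realized <- unname(coef(lm(shared ~ sim$x))[2])
  expect_true(b$lower <= realized && b$upper >= realized)
  expect_true(fit$rhat$pass)
})

test_that("simulated datasets pass the data-model validation end to end", {
  cfg <- scenario_config(seed = 17)
  sim <- simulate_dataset(cfg)
  expect_s3_class(sim$matrix, "capture_history_matrix")
  expect_true(all(rowSums(sim$matrix$y) >= 1))
  expect_identical(ncol(sim$matrix$y), cfg$n_occasions)
  expect_true(all(sim$calendar$n_days >= 48 & sim$calendar$n_days <= 70))
  # the generating covariate is standardized
  expect_equal(mean(sim$x), 0, tolerance = 1e-10)
  expect_equal(sd(sim$x), 1, tolerance = 1e-10)
  # reproducibility of the full dataset under the config seed
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$matrix$y, sim2$matrix$y)
  expect_identical(sim$environment, sim2$environment)
})
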