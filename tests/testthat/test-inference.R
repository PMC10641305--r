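# A tiny shared fit keeps the MCMC-dependent tests fast.
tiny_fit_data <- function(seed = 31) {
  cfg <- scenario_config(streams = "indian", entry_totals = c(150, 150, 150),
                         entry_scale = 1, n_occasions = 8,
                         sigma2_t = 0, sigma2_j = 0, sigma2_s = 0,
                         sigma2_js = 0, seed = seed)
  simulate_dataset(cfg)
}

test_that("posterior sampling is bitwise reproducible given the seed", {
  sim <- tiny_fit_data()
  spec <- model_spec("intercept_only")
  set <- mcmc_settings(chains = 2, iterations = 600, burn_in = 200,
                       thin = 2, seed = 99)
  s1 <- sample_posterior(sim$matrix, spec, calendar = sim$calendar,
                         settings = set)
  s2 <- sample_posterior(sim$matrix, spec, calendar = sim$calendar,
                         settings = set)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$deviance, s2$deviance)
  expect_false(identical(
    s1$draws,
    sample_posterior(sim$matrix, spec, calendar = sim$calendar,
                     settings = mcmc_settings(chains = 2, iterations = 600,
                                              burn_in = 200, thin = 2,
                                              seed = 100))$draws))
})

test_that("with no informative histories the sampler recovers the prior", {
  idx <- make_index(J = 1, S = 1)
  cal <- make_calendar(4)
  rec <- data.frame(id = sprintf("i%d", 1:3), species = "A", stream = "st1",
                    occasion = 4L, detected = 1L)
  m <- build_capture_histories(rec, cal, idx)
  set <- mcmc_settings(chains = 2, iterations = 22000, burn_in = 2000,
                       thin = 4, seed = 12)
  s <- sample_posterior(m, model_spec("intercept_only"), calendar = cal,
                        settings = set)
  d <- as_draws_matrix(s)
  # mu ~ Normal(0, 10), p ~ Uniform(0, 1)
  expect_lt(abs(mean(d[, "mu[A,st1]"])), 1.5)
  expect_equal(sd(d[, "mu[A,st1]"]), 10, tolerance = 0.15)
  expect_equal(mean(d[, "p[A,st1,2]"]), 0.5, tolerance = 0.05)
  expect_equal(sd(d[, "p[A,st1,3]"]), sqrt(1 / 12), tolerance = 0.05)
  expect_equal(unique(unlist(s$deviance)), 0)
})

test_that("a known covariate effect is recovered from simulated data", {
  cfg <- scenario_config(streams = "indian", entry_totals = 2000,
                         species = "A", mu = 1.4,
                         entry_scale = 1, sigma2_t = 0, sigma2_j = 0,
                         sigma2_s = 0, sigma2_js = 0,
                         covariate_effect = TRUE, beta = -0.5, seed = 61)
  sim <- simulate_dataset(cfg)
  fit <- fit_cjs(sim$matrix, model_spec("covariate", covariate = "mean_temp"),
                 x = sim$x, calendar = sim$calendar,
                 settings = mcmc_settings(chains = 2, iterations = 3000,
                                          burn_in = 1000, thin = 2,
                                          seed = 8))
  b <- fit$summary[fit$summary$parameter == "beta[A]", ]
  expect_lt(abs(b$mean - (-0.5)), 0.15)
  expect_true(b$lower <= -0.5 && b$upper >= -0.5)
  expect_true(fit$rhat$pass)
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  set.seed(5)
  mk <- function(shift) {
    m <- matrix(rnorm(3000), 1000, 3)
    m[, 3] <- m[, 3] + shift
    colnames(m) <- c("a", "b", "c")
    m
  }
  good <- compute_rhat(list(mk(0), mk(0), mk(0)))
  expect_true(good$pass)
  expect_lt(good$max_rhat, 1.05)

  bad <- compute_rhat(list(mk(0), mk(5), mk(0)))
  expect_false(bad$pass)
  expect_gt(bad$rhat$rhat[bad$rhat$parameter == "c"], 1.1)

  const <- matrix(1, 100, 1, dimnames = list(NULL, "k"))
  expect_warning(cr <- compute_rhat(list(const, const)), "zero-variance")
  expect_equal(cr$rhat$rhat, 1)
  expect_true(cr$rhat$degenerate)
})

test_that("DIC combines mean deviance with the pD penalty", {
  sim <- tiny_fit_data()
  base <- sample_posterior(sim$matrix, model_spec("intercept_only"),
                           calendar = sim$calendar,
                           settings = mcmc_settings(chains = 2,
                                                    iterations = 400,
                                                    burn_in = 100, thin = 1,
                                                    seed = 2))
  s <- base
  s$deviance <- list(c(100, 102))
  d <- compute_dic(s)
  expect_equal(d$mean_deviance, 101)
  expect_equal(d$pD, 1)           # var({100,102})/2
  expect_equal(d$DIC, 102)

  s$deviance <- list(rep(100, 50))
  expect_equal(compute_dic(s)$pD, 0)
  expect_equal(compute_dic(s)$DIC, 100)

  s$deviance <- list(rnorm(500, 200, 3))
  expect_equal(compute_dic(s)$DIC,
               {perm <- s; perm$deviance <- list(sample(s$deviance[[1]]))
                compute_dic(perm)$DIC})

  # classical estimator: deviance at posterior means, evaluated on the
  # real fit (must be finite and give pD >= 0 for a well-behaved model)
  d2 <- compute_dic(base, pd = "mean_params")
  expect_true(is.finite(d2$pD))
  expect_gt(d2$pD, 0)
  s$deviance <- list(100)
  expect_error(compute_dic(s), "at least 2")
})

test_that("credible-interval significance follows the sign rule", {
  expect_true(significance_from_cri(runif(200, 0.1, 1))$significant)
  expect_false(significance_from_cri(c(rnorm(500), -rnorm(500)))$significant)
  set.seed(7)
  s <- significance_from_cri(rnorm(20000, -0.54, 0.09))
  expect_true(s$significant)
  expect_equal(s$lower, -0.72, tolerance = 0.01)
  expect_equal(s$upper, -0.36, tolerance = 0.01)
  expect_error(significance_from_cri(rnorm(50)), "100")
})

test_that("survival series summarises the 60-day scale correctly", {
  idx <- make_index(J = 1, S = 1)
  nI <- 3
  spec <- model_spec("intercept_only")
  nm <- cjsync:::posterior_param_names(spec, idx, nI)
  d <- matrix(0, 200, length(nm), dimnames = list(NULL, nm))
  d[, grep("^p\\[", nm)] <- 0.4
  s <- fake_posterior(list(d), idx, n_days = c(48, 60, 70), spec = spec)
  ser <- summarize_survival_series(s)
  # mu = 0 with no effects: 60-day survival 0.5 on every interval,
  # regardless of interval length under baseline60 scaling
  expect_equal(ser$mean, rep(0.5, nI))
  expect_equal(ser$lower, rep(0.5, nI))

  # posthoc scaling reports the 60/n_days exponent
  specp <- model_spec("intercept_only", scaling_mode = "posthoc")
  sp <- fake_posterior(list(d), idx, n_days = c(48, 60, 70), spec = specp)
  serp <- summarize_survival_series(sp)
  expect_equal(serp$mean, 0.5^(60 / c(48, 60, 70)))
})

test_that("long-format draw export round-trips values", {
  sim <- tiny_fit_data()
  s <- sample_posterior(sim$matrix, model_spec("intercept_only"),
                        calendar = sim$calendar,
                        settings = mcmc_settings(chains = 2,
                                                 iterations = 300,
                                                 burn_in = 100, thin = 2,
                                                 seed = 3))
  f <- tempfile(fileext = ".csv")
  write_draws_csv(s, f)
  long <- read.csv(f)
  expect_setequal(unique(long$parameter),
                  c(s$param_names, "deviance"))
  v <- long$value[long$parameter == "mu[BHC,indian]" & long$chain == 2]
  expect_equal(v, unname(s$draws[[2]][, "mu[BHC,indian]"]))
})
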