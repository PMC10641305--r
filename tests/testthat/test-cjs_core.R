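test_that("60-day survival scaling follows the power transformation", {
  expect_equal(interval_survival(0.81, 30), 0.9)
  s <- runif(5)
  expect_equal(interval_survival(s, 60), s)
  expect_equal(interval_survival(1, 47), 1)
  expect_equal(survival_to_60day(interval_survival(0.7, 53), 53), 0.7)
})

test_that("survival probability evaluates each variant's linear predictor", {
  idx <- make_index(J = 2, S = 2)
  nI <- 4

  spec0 <- model_spec("intercept_only")
  par0 <- survival_parameters(spec0, idx, nI)
  expect_equal(survival_probability(par0, spec0, NULL, 1, 1, 2, 60, idx),
               0.5)
  # interval scaling applies inside the likelihood under baseline60
  expect_equal(survival_probability(par0, spec0, NULL, 1, 1, 2, 30, idx),
               sqrt(0.5))

  specc <- model_spec("covariate", covariate = "mean_temp")
  parc <- survival_parameters(specc, idx, nI)
  parc$beta <- c(-0.5, 1)
  x <- c(0, 2, 0, 0)
  expect_equal(survival_probability(parc, specc, x, 1, 1, 2, 60, idx),
               plogis(-1))
  # posthoc scaling leaves the inverse logit untouched
  specp <- model_spec("covariate", covariate = "mean_temp",
                      scaling_mode = "posthoc")
  expect_equal(survival_probability(parc, specp, x, 1, 1, 2, 31, idx),
               plogis(-1))

  # zero random effects reduce to the intercept value
  specr <- model_spec("random_effects")
  parr <- survival_parameters(specr, idx, nI)
  parr$mu <- rep(0.3, idx$G)
  expect_equal(survival_probability(parr, specr, NULL, 2, 2, 3, 60, idx),
               plogis(0.3))
  # variant/parameter mismatch is a hard error
  expect_error(survival_probability(par0, specc, x, 1, 1, 1, 60, idx),
               "beta")
  expect_error(survival_probability(parc, spec0, NULL, 1, 1, 1, 60, idx),
               "does not use")
})

test_that("chi-recursion likelihood matches hand-computed worked examples", {
  phi <- c(0.8, 0.8); p <- c(0.5, 0.5)
  expect_equal(exp(individual_log_likelihood(c(1, 0, 1), phi, p)), 0.16)
  expect_equal(exp(individual_log_likelihood(c(1, 0, 0), phi, p)),
               0.2 + 0.8 * 0.5 * (0.2 + 0.8 * 0.5))
  expect_equal(individual_log_likelihood(c(0, 0, 1), phi, p), 0)
})

test_that("marginalized likelihood equals latent-state enumeration", {
  set.seed(101)
  for (k in 1:30) {
    T <- sample(3:6, 1)
    inst <- random_instance(T, n = 4)
    for (h in inst$histories) {
      ll <- individual_log_likelihood(h, inst$phi, inst$p)
      expect_equal(ll,
                   log(oracle_history_likelihood(h, inst$phi, inst$p)),
                   tolerance = 1e-10)
    }
  }
})

test_that("post-first-capture history probabilities sum to one", {
  set.seed(102)
  for (k in 1:10) {
    T <- sample(3:6, 1)
    inst <- random_instance(T, n = 0)
    f <- sample(seq_len(T - 1), 1)
    tot <- sum(vapply(all_histories_from(T, f), function(h)
      exp(individual_log_likelihood(h, inst$phi, inst$p)), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("total likelihood sums individuals and respects equivalences", {
  idx <- make_index()
  cal <- make_calendar(4)
  spec <- model_spec("intercept_only")
  par <- survival_parameters(spec, idx, 3)
  par$mu <- 0.8
  p <- matrix(0.4, 1, 3)

  rec1 <- data.frame(id = "a", species = "A", stream = "st1",
                     occasion = c(1L, 3L), detected = 1L)
  rec2 <- rbind(rec1, transform(rec1, id = "b"))
  m1 <- build_capture_histories(rec1, cal, idx)
  m2 <- build_capture_histories(rec2, cal, idx)
  ll1 <- total_log_likelihood(m1, par, p, spec, NULL, cal)
  expect_equal(total_log_likelihood(m2, par, p, spec, NULL, cal), 2 * ll1)

  # permutation invariance
  m2r <- build_capture_histories(rec2[sample(nrow(rec2)), ], cal, idx)
  expect_equal(total_log_likelihood(m2r, par, p, spec, NULL, cal), 2 * ll1)

  # perfect detection and survival make an always-detected history certain
  par1 <- par; par1$mu <- 60  # inverse logit ~ 1
  rec3 <- data.frame(id = "c", species = "A", stream = "st1",
                     occasion = 1:4, detected = 1L)
  m3 <- build_capture_histories(rec3, cal, idx)
  expect_equal(total_log_likelihood(m3, par1, matrix(1, 1, 3), spec, NULL,
                                    cal), 0, tolerance = 1e-6)

  # random-effects variant with zero effects reproduces intercept-only
  specr <- model_spec("random_effects")
  parr <- survival_parameters(specr, idx, 3)
  parr$mu <- 0.8
  expect_equal(total_log_likelihood(m2, parr, p, specr, NULL, cal), 2 * ll1)

  # monotonicity: larger survival raises an all-detected history likelihood
  par_lo <- par; par_lo$mu <- 0.2
  expect_gt(total_log_likelihood(m3, par, matrix(0.6, 1, 3), spec, NULL, cal),
            total_log_likelihood(m3, par_lo, matrix(0.6, 1, 3), spec, NULL,
                                 cal))
})

test_that("sufficient-statistic form agrees with the per-history recursion", {
  cfg <- scenario_config(seed = 13)
  sim <- simulate_dataset(cfg)
  spec <- model_spec("random_effects")
  par <- survival_parameters(spec, sim$matrix$index, 14)
  par$mu <- cfg$mu
  par$eps1 <- sim$truth$params$eps1; par$eps2 <- sim$truth$params$eps2
  par$eps3 <- sim$truth$params$eps3; par$eps4 <- sim$truth$params$eps4
  llR <- total_log_likelihood(sim$matrix, par, sim$truth$params$p, spec,
                              NULL, sim$calendar)
  st <- cjsync:::history_sufficient_stats(sim$matrix)
  llC <- cjsync:::cjs_loglik_stats_cpp(st$A, st$D, st$N, st$C,
                                       sim$truth$phi_interval,
                                       sim$truth$params$p)
  expect_equal(llR, llC, tolerance = 1e-10)
})

test_that("log prior matches closed forms and declares support", {
  idx <- make_index()
  spec <- model_spec("intercept_only")
  par <- survival_parameters(spec, idx, 3)
  p <- matrix(0.5, 1, 3)
  expect_equal(log_prior(par, p, spec), dnorm(0, 0, 10, log = TRUE))
  expect_equal(log_prior(par, matrix(1.2, 1, 3), spec), -Inf)

  specr <- model_spec("random_effects")
  parr <- survival_parameters(specr, idx, 3)
  parr$sigma$t <- -1
  expect_equal(log_prior(parr, p, specr), -Inf)
  parr$sigma$t <- 0.5
  parr$eps1 <- c(0.1, -0.2, 0)
  lp <- log_prior(parr, p, specr)
  manual <- dnorm(0, 0, 10, log = TRUE) - 4 * log(10) +
    sum(dnorm(parr$eps1, 0, 0.5, log = TRUE)) +
    sum(dnorm(0, 0, 0.5, log = TRUE)) * 9
  expect_equal(lp, manual)
})
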