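# Shared fixture builders.

make_calendar <- function(T, gaps = 60) {
  if (length(gaps) == 1) gaps <- rep(gaps, T - 1)
  occasion_calendar(as.Date("2019-01-10") + cumsum(c(0, gaps)))
}

make_index <- function(J = 1, S = 1) {
  species_stream_index(LETTERS[seq_len(J)], paste0("st", seq_len(S)))
}

# Random small CJS instance: parameters plus simulated histories for one
# group, used by the oracle-equivalence and completeness suites.
random_instance <- function(T, n = 8) {
  phi <- runif(T - 1, 0.05, 0.95)
  p <- runif(T - 1, 0.05, 0.95)
  histories <- list()
  for (i in seq_len(n)) {
    f <- sample(seq_len(T - 1), 1)
    h <- integer(T); h[f] <- 1L
    alive <- TRUE
    for (t in f:(T - 1)) {
      alive <- alive && runif(1) < phi[t]
      if (alive && runif(1) < p[t]) h[t + 1] <- 1L
    }
    histories[[i]] <- h
  }
  list(phi = phi, p = p, histories = histories)
}

# Minimal hand-built posterior_samples object (single chain) for
# post-processing tests that do not need a real MCMC run.
fake_posterior <- function(draws_list, index, n_days, spec, x = NULL) {
  structure(list(
    draws = draws_list,
    deviance = lapply(draws_list, function(d) rep(100, nrow(d))),
    param_names = colnames(draws_list[[1]]),
    spec = spec, index = index, n_days = n_days,
    x = if (is.null(x)) numeric(length(n_days)) else x,
    occasion_dates = NULL, stats = NULL,
    settings = mcmc_settings(chains = length(draws_list), iterations = 2,
                             burn_in = 1, thin = 1, seed = 1)),
    class = "posterior_samples")
}
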