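# Posterior sampling, convergence diagnostics, DIC, survival-series
# summaries.

#' MCMC settings
#'
#' Desk-scale defaults (3 chains of 4,000 iterations, 1,000 burn-in, thinned
#' by 2) suitable for the scaled synthetic scenarios; production-size runs
#' are configured by raising `iterations`/`burn_in`.
#'
#' @param chains number of chains (>= 2 for R-hat).
#' @param iterations total iterations per chain, including burn-in.
#' @param burn_in iterations discarded from the front of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed; all chains derive from it.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, iterations = 4000, burn_in = 1000,
                          thin = 2, seed = 1) {
  stopifnot(chains >= 1, iterations > burn_in, thin >= 1, burn_in >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Internal: sufficient statistics of the marginalized CJS likelihood.
# For each group g: A[g,t] counts forced-alive transitions over interval t,
# D/N[g,t] count detections/non-detections at occasion t+1 inside histories,
# C[g,o] counts individuals last seen at occasion o.
history_sufficient_stats <- function(matrix) {
  agg <- aggregate_histories(matrix)
  G <- matrix$index$G
  T <- ncol(matrix$y)
  A <- D <- N <- base::matrix(0, G, T - 1)
  C <- base::matrix(0, G, T)
  for (k in seq_along(agg$count)) {
    h <- agg$H[k, ]; g <- agg$group[k]; w <- agg$count[k]
    f <- agg$first[k]; l <- max(which(h == 1L))
    C[g, l] <- C[g, l] + w
    if (l > f) {
      A[g, f:(l - 1)] <- A[g, f:(l - 1)] + w
      for (o in (f + 1):l) {
        if (h[o] == 1L) D[g, o - 1] <- D[g, o - 1] + w
        else N[g, o - 1] <- N[g, o - 1] + w
      }
    }
  }
  list(A = A, D = D, N = N, C = C)
}

# Internal: parameter names in the exact order the sampler writes them.
posterior_param_names <- function(spec, index, n_intervals) {
  g <- index$groups
  nm <- sprintf("mu[%s,%s]", g$species, g$stream)
  if (spec$uses_covariate)
    nm <- c(nm, if (spec$beta_shared) "beta" else
      sprintf("beta[%s]", index$species))
  for (t in seq_len(n_intervals))
    nm <- c(nm, sprintf("p[%s,%s,%d]", g$species, g$stream, t + 1L))
  if (spec$uses_random_effects) {
    nm <- c(nm, sprintf("eps1[%d]", seq_len(n_intervals)))
    for (t in seq_len(n_intervals))
      nm <- c(nm, sprintf("eps2[%s,%d]", index$species, t))
    for (t in seq_len(n_intervals))
      nm <- c(nm, sprintf("eps3[%s,%d]", index$streams, t))
    for (t in seq_len(n_intervals))
      nm <- c(nm, sprintf("eps4[%s,%s,%d]", g$species, g$stream, t))
    nm <- c(nm, "sigma2_t",
            sprintf("sigma2_j[%s]", index$species),
            sprintf("sigma2_s[%s]", index$streams),
            sprintf("sigma2_js[%s,%s]", g$species, g$stream))
  }
  nm
}

#' Draw from the posterior of a CJS model variant
#'
#' Runs an adaptive random-walk Metropolis-within-Gibbs sampler over the
#' marginalized CJS posterior (likelihood x priors of the model spec).
#' Initial values follow a fixed scheme -- intercepts and effect sizes at 0,
#' detection at the empirical recapture fraction, random-effect standard
#' deviations at 0.5, random effects at 0 -- jittered independently per
#' chain. Per-draw deviance (conditional on the random effects) is recorded.
#'
#' @param matrix a `capture_history_matrix`.
#' @param spec a [model_spec()].
#' @param x standardized covariate vector (length T-1) or NULL for variants
#'   without a covariate.
#' @param calendar an [occasion_calendar()].
#' @param settings an [mcmc_settings()].
#' @return object of class `posterior_samples`: `draws` (list of per-chain
#'   matrices with named columns), `deviance` (list of per-chain vectors),
#'   plus the spec, index, calendar, covariate and settings needed to
#'   post-process draws.
#' @export
sample_posterior <- function(matrix, spec, x = NULL, calendar, settings) {
  index <- matrix$index
  nI <- calendar$n_occasions - 1L
  if (spec$uses_covariate) {
    if (is.null(x)) stop("variant '", spec$variant, "' needs a covariate vector")
    stopifnot(length(x) == nI)
  } else x <- numeric(nI)
  stats <- history_sufficient_stats(matrix)
  pr <- spec$priors
  variant_beta <- if (!spec$uses_covariate) 0L else if (spec$beta_shared) 2L else 1L

  # empirical detection inits: recapture fraction per group x occasion
  frac_emp <- stats$D / pmax(stats$D + stats$N, 1)
  p_init <- pmin(pmax(frac_emp, 0.1), 0.9)
  p_init[stats$D + stats$N == 0] <- 0.3

  nb <- c(0L, index$J, 1L)[variant_beta + 1L]
  nm <- posterior_param_names(spec, index, nI)

  set.seed(settings$seed)
  draws <- vector("list", settings$chains)
  deviance <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    mu0 <- rnorm(index$G, 0, 0.3)
    beta0 <- if (nb > 0) rnorm(nb, 0, 0.2) else numeric(0)
    lp0 <- logit(p_init) + base::matrix(rnorm(length(p_init), 0, 0.2),
                                        nrow(p_init))
    e1_0 <- rnorm(nI, 0, 0.05)
    e2_0 <- base::matrix(rnorm(index$J * nI, 0, 0.05), index$J)
    e3_0 <- base::matrix(rnorm(index$S * nI, 0, 0.05), index$S)
    e4_0 <- base::matrix(rnorm(index$G * nI, 0, 0.05), index$G)
    sig0 <- 0.5 * runif(1 + index$J + index$S + index$G, 0.8, 1.2)
    res <- cjs_mcmc_chain_cpp(
      stats$A, stats$D, stats$N, stats$C,
      index$groups$j, index$groups$s, index$J, index$S,
      calendar$n_days / 60, x,
      variant_beta, spec$uses_random_effects,
      spec$scaling_mode == "baseline60",
      pr$mu_sd, pr$beta_sd, pr$sigma_upper,
      settings$iterations, settings$burn_in, settings$thin,
      mu0, beta0, lp0, e1_0, e2_0, e3_0, e4_0, sig0)
    colnames(res$draws) <- nm
    draws[[ch]] <- res$draws
    deviance[[ch]] <- as.numeric(res$deviance)
  }
  structure(list(draws = draws, deviance = deviance, param_names = nm,
                 spec = spec, index = index,
                 n_days = calendar$n_days, x = x,
                 occasion_dates = calendar$occasion_dates,
                 stats = stats, settings = settings),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", length(x$draws), "chain(s) x",
      nrow(x$draws[[1]]), "draws of", length(x$param_names),
      "parameters (", x$spec$variant, ")\n")
  invisible(x)
}

#' Stack all chains into one draws matrix
#'
#' @param samples a `posterior_samples`.
#' @return numeric matrix, rows = pooled draws, named columns.
#' @export
as_draws_matrix <- function(samples) {
  do.call(rbind, samples$draws)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor per scalar parameter; the
#' customary pass threshold is R-hat < 1.1 for every parameter. Parameters
#' with zero within- and between-chain variance (e.g. a pinned constant) are
#' reported as R-hat 1 with a warning flag.
#'
#' @param samples a `posterior_samples` (or list of draw matrices).
#' @param threshold pass threshold (default 1.1).
#' @return object of class `convergence_report`: data frame `rhat` with
#'   columns `parameter`, `rhat`, `degenerate`; `pass` flag; `max_rhat`.
#' @export
compute_rhat <- function(samples, threshold = 1.1) {
  chains <- if (inherits(samples, "posterior_samples")) samples$draws
            else samples
  if (length(chains) < 2) stop("R-hat needs at least 2 chains")
  n <- nrow(chains[[1]])
  half <- floor(n / 2)
  split <- list()
  for (ch in chains) {
    split <- c(split, list(ch[seq_len(half), , drop = FALSE],
                           ch[seq.int(n - half + 1, n), , drop = FALSE]))
  }
  m <- length(split)
  nn <- half
  params <- colnames(chains[[1]])
  rhat <- numeric(length(params))
  degenerate <- logical(length(params))
  for (k in seq_along(params)) {
    means <- vapply(split, function(d) mean(d[, k]), numeric(1))
    vars <- vapply(split, function(d) var(d[, k]), numeric(1))
    W <- mean(vars)
    B <- nn * var(means)
    if (!is.finite(W) || W == 0) {
      rhat[k] <- 1; degenerate[k] <- TRUE
      next
    }
    rhat[k] <- sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  if (any(degenerate))
    warning("zero-variance parameter(s): R-hat undefined, reported as 1")
  tab <- data.frame(parameter = params, rhat = rhat, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  structure(list(rhat = tab, max_rhat = max(rhat),
                 pass = all(rhat < threshold), threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence: max R-hat =", round(x$max_rhat, 4),
      if (x$pass) sprintf("(pass, all < %s)", x$threshold)
      else sprintf("(FAIL at threshold %s)", x$threshold), "\n")
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = mean(deviance) + pD`. The default effective-parameter estimator is
#' `pD = var(deviance) / 2`; the classical alternative
#' `pD = mean(deviance) - deviance(posterior means)` is available via
#' `pd = "mean_params"`. Deviance here is conditional on the random effects.
#'
#' @param samples a `posterior_samples`.
#' @param pd `"variance"` (default) or `"mean_params"`.
#' @return object of class `dic_result` with `mean_deviance`, `pD`, `DIC`,
#'   `pd_method`.
#' @export
compute_dic <- function(samples, pd = c("variance", "mean_params")) {
  pd <- match.arg(pd)
  dev <- unlist(samples$deviance)
  if (length(dev) < 2) stop("DIC needs at least 2 deviance draws")
  dbar <- mean(dev)
  if (pd == "variance") {
    pD <- var(dev) / 2
  } else {
    pD <- dbar - deviance_at_posterior_means(samples)
  }
  structure(list(mean_deviance = dbar, pD = pD, DIC = dbar + pD,
                 pd_method = pd), class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.1f (mean deviance %.1f, pD %.1f, %s estimator)\n",
              x$DIC, x$mean_deviance, x$pD, x$pd_method))
  invisible(x)
}

# Internal: deviance evaluated at the posterior means of all parameters.
deviance_at_posterior_means <- function(samples) {
  post <- colMeans(as_draws_matrix(samples))
  mats <- posterior_phi_p(samples, rbind(post))
  ll <- cjs_loglik_stats_cpp(samples$stats$A, samples$stats$D,
                             samples$stats$N, samples$stats$C,
                             mats$phi[1, , ], mats$p[1, , ])
  -2 * ll
}

# Internal: interval-scale survival and detection arrays for a set of draws.
# draws: matrix (rows x named params). Returns list of arrays
# [draw, group, interval].
posterior_phi_p <- function(samples, draws) {
  index <- samples$index; spec <- samples$spec
  nI <- length(samples$n_days)
  G <- index$G
  nd <- nrow(draws)
  gtab <- index$groups
  eta <- array(0, c(nd, G, nI))
  p <- array(0, c(nd, G, nI))
  for (g in seq_len(G)) {
    mu_col <- sprintf("mu[%s,%s]", gtab$species[g], gtab$stream[g])
    for (t in seq_len(nI)) {
      e <- draws[, mu_col]
      if (spec$uses_covariate) {
        b <- if (spec$beta_shared) draws[, "beta"] else
          draws[, sprintf("beta[%s]", gtab$species[g])]
        e <- e + b * samples$x[t]
      }
      if (spec$uses_random_effects) {
        e <- e + draws[, sprintf("eps1[%d]", t)] +
          draws[, sprintf("eps2[%s,%d]", gtab$species[g], t)] +
          draws[, sprintf("eps3[%s,%d]", gtab$stream[g], t)] +
          draws[, sprintf("eps4[%s,%s,%d]", gtab$species[g],
                          gtab$stream[g], t)]
      }
      eta[, g, t] <- e
      p[, g, t] <- draws[, sprintf("p[%s,%s,%d]", gtab$species[g],
                                   gtab$stream[g], t + 1L)]
    }
  }
  base <- 1 / (1 + exp(-eta))
  phi <- if (spec$scaling_mode == "baseline60") {
    sweep_frac <- aperm(array(samples$n_days / 60, c(nI, nd, G)), c(2, 3, 1))
    base^sweep_frac
  } else base
  # phi is interval-scale survival; base is inverse-logit(eta)
  # (60-day survival under baseline60)
  list(phi = phi, base = base, p = p)
}

#' Posterior 95% credible interval and significance flag
#'
#' A parameter is flagged significant when its central 95% credible interval
#' excludes zero (both bounds share a sign).
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @return list with `mean`, `lower`, `upper` (2.5/97.5 percentiles) and
#'   `significant`.
#' @export
significance_from_cri <- function(draws) {
  if (length(draws) < 100) stop("need at least 100 draws for a 95% CRI")
  q <- unname(quantile(draws, c(0.025, 0.975)))
  list(mean = mean(draws), lower = q[1], upper = q[2],
       significant = q[1] > 0 || q[2] < 0)
}

#' Posterior summary of the 60-day survival series
#'
#' For each draw, species, stream and interval, evaluates the linear
#' predictor and converts it to 60-day survival (under `baseline60` scaling
#' the inverse logit already is 60-day survival; under `posthoc` the
#' interval survival is raised to `60 / n_days`). Returns the posterior mean
#' and central 95% credible interval.
#'
#' @param samples a `posterior_samples`.
#' @return data frame with columns `species`, `stream`, `interval`,
#'   `n_days`, `mean`, `lower`, `upper`.
#' @export
summarize_survival_series <- function(samples) {
  draws <- as_draws_matrix(samples)
  mats <- posterior_phi_p(samples, draws)
  nI <- length(samples$n_days)
  s60 <- if (samples$spec$scaling_mode == "baseline60") mats$base else {
    ex <- aperm(array(60 / samples$n_days,
                      c(nI, dim(mats$phi)[1], dim(mats$phi)[2])), c(2, 3, 1))
    mats$phi^ex
  }
  gtab <- samples$index$groups
  out <- expand.grid(g = seq_len(samples$index$G), interval = seq_len(nI))
  res <- data.frame(
    species = gtab$species[out$g],
    stream = gtab$stream[out$g],
    interval = out$interval,
    n_days = samples$n_days[out$interval],
    mean = NA_real_, lower = NA_real_, upper = NA_real_,
    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    v <- s60[, out$g[r], out$interval[r]]
    q <- quantile(v, c(0.025, 0.975))
    res$mean[r] <- mean(v); res$lower[r] <- q[1]; res$upper[r] <- q[2]
  }
  res
}

#' Persist posterior draws as long-format CSV
#'
#' Columns: `chain`, `iteration`, `parameter`, `value`; deviance is included
#' as parameter `"deviance"`.
#'
#' @param samples a `posterior_samples`.
#' @param path file path.
#' @export
write_draws_csv <- function(samples, path) {
  pieces <- lapply(seq_along(samples$draws), function(ch) {
    d <- samples$draws[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(d)), times = ncol(d) + 1L),
               parameter = rep(c(colnames(d), "deviance"),
                               each = nrow(d)),
               value = c(as.vector(d), samples$deviance[[ch]]))
  })
  write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}
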