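# Workflow orchestration: simulate -> screen -> fit -> synchrony, with
# file artifacts and run manifests. These functions back the numbered
# driver scripts under analysis/.

pkg_version <- function() {
  as.character(utils::packageVersion("cjsync"))
}

write_manifest <- function(dir, seed, config = NULL, extra = list()) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  paths <- file.path(dir, files)
  manifest <- c(list(
    package_version = pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    checksums = as.list(setNames(unname(tools::md5sum(paths)), files))),
    extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

config_snapshot <- function(config) {
  list(species = config$index$species, streams = config$index$streams,
       n_occasions = config$n_occasions,
       start_date = format(config$start_date),
       interval_days = config$interval_days,
       entry_totals = config$entry_totals,
       entry_scale = config$entry_scale,
       mu = config$mu, beta = config$beta,
       covariate_effect = config$covariate_effect,
       sigma2_t = config$sigma2_t, sigma2_j = config$sigma2_j,
       sigma2_s = config$sigma2_s, sigma2_js = config$sigma2_js,
       detection_range = config$detection_range,
       temp_mean = config$temp_mean,
       temp_amplitude = config$temp_amplitude,
       temp_noise_sd = config$temp_noise_sd,
       temp_peak_doy = config$temp_peak_doy,
       summer_offset_c = config$summer_offset_c,
       summer_offset_window = format(config$summer_offset_window),
       level_baseline = config$level_baseline,
       seed = config$seed)
}

#' Simulate a dataset and write it to a directory
#'
#' Writes `encounters.csv`, `environment.csv`, `calendar.csv`,
#' `truth.json`, a `scenario.yaml` snapshot and a `manifest.json` with
#' checksums. The file formats are exactly those the real-data path
#' consumes, so downstream stages cannot distinguish synthetic from field
#' data.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created).
#' @return the simulated dataset list (invisibly), as from
#'   [simulate_dataset()].
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  write_encounters(sim$records, file.path(out_dir, "encounters.csv"))
  write_environment(sim$environment, file.path(out_dir, "environment.csv"))
  write_calendar(sim$calendar, file.path(out_dir, "calendar.csv"))
  snap <- config_snapshot(config)
  yaml::write_yaml(snap, file.path(out_dir, "scenario.yaml"))
  jsonlite::write_json(
    list(params = sim$truth$params, x = sim$x, phi60 = sim$truth$phi60),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, seed = config$seed, config = snap)
  invisible(sim)
}

#' Load a simulated (or field) dataset directory
#'
#' Reads the artifacts written by [run_simulate()] -- or field data in the
#' same formats -- and rebuilds the capture-history matrix. The species and
#' stream label order comes from `scenario.yaml`, not from file order.
#'
#' @param dir dataset directory.
#' @return list with `matrix`, `records`, `calendar`, `environment`,
#'   `index`, `config_snapshot`.
#' @export
load_dataset <- function(dir) {
  snap <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  index <- species_stream_index(snap$species, snap$streams)
  calendar <- read_calendar(file.path(dir, "calendar.csv"))
  records <- read_encounters(file.path(dir, "encounters.csv"))
  env <- read_environment(file.path(dir, "environment.csv"))
  matrix <- build_capture_histories(records, calendar, index)
  list(matrix = matrix, records = records, calendar = calendar,
       environment = env, index = index, config_snapshot = snap)
}

#' Covariate screen stage
#'
#' Builds the per-stream interval covariate table, screens for collinearity
#' per stream, and (optionally) writes `covariates.csv` and `screen.json`.
#'
#' @param series multi-stream daily environmental data frame.
#' @param calendar an [occasion_calendar()].
#' @param threshold collinearity threshold (default 0.50).
#' @param out_dir optional output directory.
#' @return list with `table` (the covariate table with standardized
#'   columns), and per-stream `screen` results.
#' @export
run_screen <- function(series, calendar, threshold = 0.50, out_dir = NULL) {
  tab <- interval_covariate_table(series, calendar)
  screens <- lapply(split(tab, tab$stream), screen_collinearity,
                    threshold = threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "covariates.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(screens, function(s)
        list(retained = s$retained, dropped = s$dropped,
             correlations = as.data.frame(s$correlations))),
      file.path(out_dir, "screen.json"), digits = NA)
    write_manifest(out_dir, seed = NA)
  }
  list(table = tab, screen = screens)
}

#' Fit one CJS model variant and summarize it
#'
#' Wraps [sample_posterior()] with convergence and DIC diagnostics and a
#' posterior summary table.
#'
#' @param matrix a `capture_history_matrix`.
#' @param spec a [model_spec()].
#' @param x standardized covariate vector or NULL.
#' @param calendar an [occasion_calendar()].
#' @param settings an [mcmc_settings()].
#' @return object of class `cjs_fit`: `samples`, `rhat`
#'   (a `convergence_report`), `dic`, `summary` (mean/CRI per parameter).
#' @export
fit_cjs <- function(matrix, spec, x = NULL, calendar, settings) {
  samples <- sample_posterior(matrix, spec, x, calendar, settings)
  rhat <- compute_rhat(samples)
  dic <- compute_dic(samples)
  draws <- as_draws_matrix(samples)
  qs <- t(apply(draws, 2, quantile, c(0.025, 0.975)))
  summary <- data.frame(parameter = colnames(draws),
                        mean = colMeans(draws),
                        lower = qs[, 1], upper = qs[, 2],
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(samples = samples, rhat = rhat, dic = dic,
                 summary = summary, variant = spec$variant),
            class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit (", x$variant, ")\n", sep = "")
  print(x$dic); print(x$rhat)
  invisible(x)
}

#' Write fit artifacts
#'
#' Writes `summary.csv`, `rhat.csv`, `dic.json`, `survival_series.csv`, a
#' manifest, and optionally the full long-format `draws.csv`.
#'
#' @param fit a `cjs_fit`.
#' @param out_dir output directory.
#' @param save_draws also persist every posterior draw (large).
#' @export
write_fit <- function(fit, out_dir, save_draws = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(fit$summary, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  write.csv(fit$rhat$rhat, file.path(out_dir, "rhat.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(variant = fit$variant, mean_deviance = fit$dic$mean_deviance,
         pD = fit$dic$pD, DIC = fit$dic$DIC,
         pd_method = fit$dic$pd_method,
         max_rhat = fit$rhat$max_rhat, rhat_pass = fit$rhat$pass),
    file.path(out_dir, "dic.json"), auto_unbox = TRUE, digits = NA)
  write.csv(summarize_survival_series(fit$samples),
            file.path(out_dir, "survival_series.csv"), row.names = FALSE)
  if (save_draws)
    write_draws_csv(fit$samples, file.path(out_dir, "draws.csv"))
  write_manifest(out_dir, seed = fit$samples$settings$seed,
                 extra = list(variant = fit$variant,
                              settings = unclass(fit$samples$settings)))
  invisible(out_dir)
}

#' Synchrony stage: ICC, covariate contribution, correlations, DIC table
#'
#' Combines a random-effects fit and a random-effects-plus-covariate fit
#' (plus, optionally, an intercept-only fit) into the synchrony report
#' bundle.
#'
#' @param fit_re `cjs_fit` of the random-effects variant.
#' @param fit_cov `cjs_fit` of the random-effects-plus-covariate variant
#'   (NULL to skip the contribution section).
#' @param fit_null optional intercept-only `cjs_fit` for the DIC table.
#' @param sigma2_t_source `"covariate_model"` (default) takes the sigma2_t
#'   draws entering the synchrony proportion from the covariate model
#'   itself; `"re_model"` takes them from the plain random-effects fit.
#'   Both are reported in the bundle.
#' @param out_dir optional directory for the report bundle.
#' @return a `synchrony_report` with an added `proportion_alternative`
#'   element giving the proportion under the other sigma2_t source.
#' @export
run_synchrony <- function(fit_re, fit_cov = NULL, fit_null = NULL,
                          sigma2_t_source = c("covariate_model", "re_model"),
                          out_dir = NULL) {
  sigma2_t_source <- match.arg(sigma2_t_source)
  icc <- compute_icc(fit_re$samples)
  series <- summarize_survival_series(fit_re$samples)
  correlations <- pairwise_correlations(series)
  contribution <- NULL
  alt <- NULL
  if (!is.null(fit_cov)) {
    dcov <- as_draws_matrix(fit_cov$samples)
    dre <- as_draws_matrix(fit_re$samples)
    s2cov <- covariate_variance(dcov[, "beta"], fit_cov$samples$x)
    n <- min(length(s2cov), nrow(dre))
    sources <- list(covariate_model = dcov[seq_len(n), "sigma2_t"],
                    re_model = dre[seq_len(n), "sigma2_t"])
    contribution <- synchrony_proportion(s2cov[seq_len(n)],
                                         sources[[sigma2_t_source]])
    other <- setdiff(names(sources), sigma2_t_source)
    alt <- synchrony_proportion(s2cov[seq_len(n)], sources[[other]])
    contribution$sigma2_t_source <- sigma2_t_source
  }
  dic_rows <- list()
  add_dic <- function(rows, fit, name) {
    if (is.null(fit)) return(rows)
    c(rows, list(data.frame(model = name,
                            mean_deviance = fit$dic$mean_deviance,
                            pD = fit$dic$pD, DIC = fit$dic$DIC)))
  }
  dic_rows <- add_dic(dic_rows, fit_null, "intercept_only")
  dic_rows <- add_dic(dic_rows, fit_re, "random_effects")
  dic_rows <- add_dic(dic_rows, fit_cov, "random_effects_plus_covariate")
  dic_table <- if (length(dic_rows)) do.call(rbind, dic_rows) else NULL
  report <- build_synchrony_report(icc = icc, contribution = contribution,
                                   correlations = correlations,
                                   dic_table = dic_table, dir = out_dir)
  report$proportion_alternative <- alt
  report$survival_series <- series
  if (!is.null(out_dir)) {
    write.csv(series, file.path(out_dir, "survival_series.csv"),
              row.names = FALSE)
    write_manifest(out_dir, seed = fit_re$samples$settings$seed)
  }
  report
}

#' End-to-end pipeline on a scenario
#'
#' Simulate, screen, fit the intercept-only, random-effects and
#' random-effects-plus-covariate joint models, and assemble the synchrony
#' report. The joint covariate is the cross-stream average of the top
#' retained covariate, averaged first and then standardized.
#'
#' @param config a [scenario_config()].
#' @param settings an [mcmc_settings()].
#' @param out_dir root output directory (`data/`, `screen/`, `fits/`,
#'   `synchrony/` subdirectories); NULL to skip writing.
#' @param covariate covariate family used in the joint model (default the
#'   top retained one, `mean_temp`).
#' @param settings_re settings for the two random-effects fits; these
#'   hierarchical models mix more slowly than the fixed-effects variants
#'   and default to longer chains.
#' @param save_draws persist full draw files per fit.
#' @return list with `sim`, `screen`, `fits` (named list of `cjs_fit`),
#'   `report`.
#' @export
run_pipeline <- function(config, settings, out_dir = NULL,
                         covariate = "mean_temp",
                         settings_re = mcmc_settings(
                           chains = settings$chains, iterations = 16000,
                           burn_in = 4000, thin = 6, seed = settings$seed),
                         save_draws = FALSE) {
  sim <- if (is.null(out_dir)) simulate_dataset(config) else
    run_simulate(config, file.path(out_dir, "data"))
  screen <- run_screen(sim$environment, sim$calendar,
                       out_dir = if (is.null(out_dir)) NULL else
                         file.path(out_dir, "screen"))
  covtab <- screen$table
  x <- standardize(cross_stream_average(
    split(covtab[[covariate]], covtab$stream)))
  fits <- list(
    intercept_only = fit_cjs(sim$matrix, model_spec("intercept_only"),
                             calendar = sim$calendar, settings = settings),
    random_effects = fit_cjs(sim$matrix, model_spec("random_effects"),
                             calendar = sim$calendar,
                             settings = settings_re),
    random_effects_plus_covariate = fit_cjs(
      sim$matrix,
      model_spec("random_effects_plus_covariate", covariate = covariate),
      x = x, calendar = sim$calendar, settings = settings_re))
  if (!is.null(out_dir))
    for (nm in names(fits))
      write_fit(fits[[nm]], file.path(out_dir, "fits", nm),
                save_draws = save_draws)
  report <- run_synchrony(fits$random_effects,
                          fits$random_effects_plus_covariate,
                          fits$intercept_only,
                          out_dir = if (is.null(out_dir)) NULL else
                            file.path(out_dir, "synchrony"))
  list(sim = sim, screen = screen, x = x, fits = fits, report = report)
}
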