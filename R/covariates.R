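# Interval summarisation, standardisation and collinearity screening of the
# daily environmental logger series.

#' Read / write daily environmental logger series
#'
#' File format: `stream,date,temp_c,level_m`, one row per stream-day, with
#' ISO-8601 dates, mean daily water temperature in degrees Celsius and daily
#' water level in metres.
#'
#' @param path file path.
#' @return data frame with columns `stream`, `date` (`Date`), `temp_c`,
#'   `level_m`, validated per stream: strictly increasing dates, no
#'   duplicates, temperature within (-5, 45) C, level > 0.
#' @export
read_environment <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("stream", "date", "temp_c", "level_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environment file missing columns: ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  validate_environment(df)
  df
}

#' @rdname read_environment
#' @param series daily-series data frame.
#' @export
write_environment <- function(series, path) {
  out <- series
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_environment <- function(series) {
  for (s in unique(series$stream)) {
    d <- series[series$stream == s, ]
    if (anyDuplicated(d$date)) stop("duplicate dates in stream ", s)
    if (is.unsorted(d$date, strictly = TRUE)) stop("dates not increasing in stream ", s)
    if (any(d$temp_c <= -5 | d$temp_c >= 45))
      stop("temperature outside sanity band (-5, 45) C in stream ", s)
    if (any(d$level_m <= 0)) stop("non-positive water level in stream ", s)
  }
  invisible(series)
}

#' Summarize daily series into per-interval covariates
#'
#' For each interval t between consecutive occasions, daily values for days d
#' with `occasion_date[t] < d <= occasion_date[t+1]` (half-open, so every day
#' belongs to exactly one interval) are reduced to five covariates: mean and
#' maximum daily temperature, and mean, maximum and minimum water level.
#'
#' @param series daily-series data frame for a single stream (columns `date`,
#'   `temp_c`, `level_m`; a `stream` column must be constant if present).
#' @param calendar an [occasion_calendar()].
#' @return data frame with one row per interval `t = 1..T-1` and columns
#'   `interval`, `n_days_covered`, `mean_temp`, `max_temp`, `mean_level`,
#'   `max_level`, `min_level`.
#' @export
summarize_intervals <- function(series, calendar) {
  if (!is.null(series$stream) && length(unique(series$stream)) > 1)
    stop("summarize_intervals expects a single stream; got ",
         paste(unique(series$stream), collapse = ", "))
  Tn <- calendar$n_occasions
  dates <- calendar$occasion_dates
  # expected coverage: every day in (dates[1], dates[T]]
  wanted <- seq(dates[1] + 1, dates[Tn], by = "day")
  missing_days <- wanted[!wanted %in% series$date]
  if (length(missing_days))
    stop("daily series has gaps within the study window: ",
         paste(format(head(missing_days, 5)), collapse = ", "),
         if (length(missing_days) > 5) sprintf(" (+%d more)", length(missing_days) - 5))
  out <- vector("list", Tn - 1)
  for (t in seq_len(Tn - 1)) {
    d <- series[series$date > dates[t] & series$date <= dates[t + 1], ]
    if (nrow(d) == 0) stop("interval ", t, " covers zero days")
    out[[t]] <- data.frame(
      interval = t,
      n_days_covered = nrow(d),
      mean_temp = mean(d$temp_c), max_temp = max(d$temp_c),
      mean_level = mean(d$level_m), max_level = max(d$level_m),
      min_level = min(d$level_m))
  }
  do.call(rbind, out)
}

#' Standardize a covariate vector to mean 0, sample sd 1
#'
#' Centring and scaling use the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return standardized numeric vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Screen per-interval covariates for collinearity
#'
#' Computes the pairwise Pearson correlation matrix and greedily retains
#' covariates in priority order: a covariate is kept only if its absolute
#' correlation with every already-kept covariate is at or below the
#' threshold. The default priority (mean temperature, then mean water level,
#' then the extremes) reflects the convention of preferring means over
#' extremes of the same series.
#'
#' @param covariate_table data frame of per-interval covariates (e.g. from
#'   [summarize_intervals()]); only the columns named in `priority` are
#'   screened.
#' @param threshold absolute-correlation threshold above which a pair is
#'   considered collinear (default 0.50).
#' @param priority character vector of covariate columns in retention order.
#' @param use_abs compare `|r|` (default) rather than signed `r` to the
#'   threshold; negative collinearity is equally harmful.
#' @return list with `retained` (character vector), `dropped`, and
#'   `correlations` (the Pearson correlation matrix of all screened columns).
#' @export
screen_collinearity <- function(covariate_table, threshold = 0.50,
                                priority = c("mean_temp", "mean_level",
                                             "max_temp", "max_level",
                                             "min_level"),
                                use_abs = TRUE) {
  priority <- intersect(priority, names(covariate_table))
  if (length(priority) < 2) stop("need at least 2 covariates to screen")
  X <- as.matrix(covariate_table[, priority, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 intervals to screen collinearity")
  R <- cor(X)
  retained <- character(0)
  for (v in priority) {
    r_with_kept <- R[v, retained]
    if (use_abs) r_with_kept <- abs(r_with_kept)
    if (all(r_with_kept <= threshold)) retained <- c(retained, v)
  }
  list(retained = retained,
       dropped = setdiff(priority, retained),
       correlations = R)
}

#' Average a per-interval covariate across streams
#'
#' Elementwise arithmetic mean of per-stream covariate vectors, used when a
#' single covariate series drives the joint two-stream synchrony model.
#'
#' @param x_by_stream list (or matrix with streams in columns) of numeric
#'   vectors of equal length T-1.
#' @return numeric vector of length T-1.
#' @export
cross_stream_average <- function(x_by_stream) {
  if (is.matrix(x_by_stream)) x_by_stream <- as.data.frame(x_by_stream)
  lens <- lengths(x_by_stream)
  if (length(unique(lens)) != 1)
    stop("per-stream covariate vectors differ in length: ",
         paste(lens, collapse = ", "))
  rowMeans(do.call(cbind, as.list(x_by_stream)))
}

#' Build the full interval-covariate table for all streams
#'
#' Runs [summarize_intervals()] per stream and appends standardized columns
#' (suffix `_std`), standardizing within stream over the T-1 intervals.
#'
#' @param series multi-stream daily-series data frame.
#' @param calendar an [occasion_calendar()].
#' @return data frame with one row per (stream, interval), raw and
#'   standardized covariate columns.
#' @export
interval_covariate_table <- function(series, calendar) {
  vars <- c("mean_temp", "max_temp", "mean_level", "max_level", "min_level")
  out <- lapply(unique(series$stream), function(s) {
    tab <- summarize_intervals(series[series$stream == s, ], calendar)
    tab <- cbind(stream = s, tab)
    for (v in vars) tab[[paste0(v, "_std")]] <- standardize(tab[[v]])
    tab
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
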