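#' @useDynLib cjsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile var sd cor median pt setNames
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# Species/stream index
# ---------------------------------------------------------------------------

#' Registered species and stream labels
#'
#' Parameter indexing in the multispecies models must be stable across runs,
#' so the order of species and stream labels is declared up front rather than
#' inferred from file order. Groups are the J x S species-by-stream
#' combinations, numbered column-major (species fastest).
#'
#' @param species character vector of species labels (length J), in the order
#'   parameters are indexed.
#' @param streams character vector of stream labels (length S).
#' @return An object of class `species_stream_index` with elements `species`,
#'   `streams`, `J`, `S`, `G = J * S`, and a `groups` data frame mapping group
#'   id to (species, stream).
#' @export
species_stream_index <- function(species, streams) {
  species <- as.character(species)
  streams <- as.character(streams)
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (anyDuplicated(streams)) stop("duplicate stream labels")
  J <- length(species); S <- length(streams)
  groups <- data.frame(
    group   = seq_len(J * S),
    species = rep(species, times = S),
    stream  = rep(streams, each = J),
    j       = rep(seq_len(J), times = S),
    s       = rep(seq_len(S), each = J),
    stringsAsFactors = FALSE
  )
  structure(list(species = species, streams = streams,
                 J = J, S = S, G = J * S, groups = groups),
            class = "species_stream_index")
}

#' Look up the group id of a (species, stream) pair
#'
#' @param index a [species_stream_index()].
#' @param species,stream label vectors (recycled to common length).
#' @return integer group ids in 1..J*S.
#' @export
group_id <- function(index, species, stream) {
  j <- match(as.character(species), index$species)
  s <- match(as.character(stream), index$streams)
  if (anyNA(j)) stop("unknown species label: ",
                     paste(unique(species[is.na(j)]), collapse = ", "))
  if (anyNA(s)) stop("unknown stream label: ",
                     paste(unique(stream[is.na(s)]), collapse = ", "))
  (s - 1L) * index$J + j
}

# ---------------------------------------------------------------------------
# Occasion calendar
# ---------------------------------------------------------------------------

#' Sampling-occasion calendar
#'
#' Holds the median sampling day of each bi-monthly occasion and the interval
#' lengths in days between consecutive occasions, which scale survival to its
#' 60-day basis.
#'
#' @param occasion_dates `Date` vector of median sampling days, strictly
#'   increasing, length T >= 2.
#' @return An object of class `occasion_calendar` with `occasion_dates`,
#'   `n_occasions` and `n_days` (integer vector, length T - 1).
#' @export
occasion_calendar <- function(occasion_dates) {
  occasion_dates <- as.Date(occasion_dates)
  if (anyNA(occasion_dates)) stop("calendar contains unparseable dates")
  if (length(occasion_dates) < 2) stop("calendar needs at least 2 occasions")
  n_days <- as.integer(diff(occasion_dates))
  if (any(n_days <= 0)) stop("occasion dates must be strictly increasing")
  structure(list(occasion_dates = occasion_dates,
                 n_occasions = length(occasion_dates),
                 n_days = n_days),
            class = "occasion_calendar")
}

#' @export
print.occasion_calendar <- function(x, ...) {
  cat("Occasion calendar:", x$n_occasions, "occasions,",
      format(x$occasion_dates[1]), "to",
      format(x$occasion_dates[x$n_occasions]), "\n")
  cat("Interval days:", paste(x$n_days, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an occasion calendar as CSV
#'
#' The file format is `occasion,median_date` with ISO-8601 dates.
#'
#' @param path file path.
#' @return [read_calendar()] returns an [occasion_calendar()];
#'   [write_calendar()] invisibly returns `path`.
#' @export
read_calendar <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("occasion", "median_date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calendar file missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$occasion), ]
  if (!identical(as.integer(df$occasion), seq_len(nrow(df))))
    stop("calendar occasions must be 1..T with no gaps")
  occasion_calendar(as.Date(df$median_date))
}

#' @rdname read_calendar
#' @param calendar an [occasion_calendar()].
#' @export
write_calendar <- function(calendar, path) {
  df <- data.frame(occasion = seq_len(calendar$n_occasions),
                   median_date = format(calendar$occasion_dates, "%Y-%m-%d"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Encounter records and capture histories
# ---------------------------------------------------------------------------

#' Read / write long-format encounter records
#'
#' Encounter records are one row per detection event:
#' `id,species,stream,occasion,detected` with `detected` in {0,1}. Extra
#' columns are preserved on read and ignored downstream.
#'
#' @param path file path.
#' @return [read_encounters()] returns a data frame of encounter records.
#' @export
read_encounters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "stream", "occasion", "detected")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("encounter file missing columns: ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$occasion <- as.integer(df$occasion)
  df$detected <- as.integer(df$detected)
  df
}

#' @rdname read_encounters
#' @param records encounter-record data frame.
#' @export
write_encounters <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a capture-history matrix from encounter records
#'
#' Collapses long-format encounter records to one binary row per individual
#' over the calendar's occasions: 1 for detected, 0 for not detected.
#' Multiple detections of an individual within one occasion collapse to a
#' single 1. Rows are ordered by individual id. An individual's species and
#' stream labels must be consistent across its records.
#'
#' Individuals first captured on the final occasion are retained (they are
#' part of the tagged cohort) but contribute no survival information; they
#' are flagged and excluded from likelihood evaluation.
#'
#' @param records data frame with columns `id`, `species`, `stream`,
#'   `occasion`, `detected`; rows with `detected == 0` are ignored.
#' @param calendar an [occasion_calendar()] defining T.
#' @param index a [species_stream_index()]; labels in `records` must be
#'   registered in it.
#' @return An object of class `capture_history_matrix` with elements:
#'   `y` (n x T binary matrix), `individuals` (data frame of id, species,
#'   stream, group, first_capture, informative flag), `calendar`, `index`.
#' @export
build_capture_histories <- function(records, calendar, index) {
  det <- records[records$detected == 1, , drop = FALSE]
  if (nrow(det) == 0) stop("no detections in encounter records")
  T <- calendar$n_occasions
  occ <- as.integer(det$occasion)
  if (any(occ < 1 | occ > T))
    stop("encounter occasion outside calendar range 1..", T)

  det$id <- as.character(det$id)
  ids <- sort(unique(det$id))
  # species/stream consistency per id
  lab <- unique(det[, c("id", "species", "stream")])
  dup <- lab$id[duplicated(lab$id)]
  if (length(dup))
    stop("conflicting species/stream labels for id(s): ",
         paste(unique(dup), collapse = ", "))
  lab <- lab[match(ids, lab$id), ]

  y <- matrix(0L, nrow = length(ids), ncol = T,
              dimnames = list(ids, NULL))
  y[cbind(match(det$id, ids), occ)] <- 1L
  first <- apply(y, 1L, function(r) which(r == 1L)[1])

  individuals <- data.frame(
    id = ids,
    species = as.character(lab$species),
    stream = as.character(lab$stream),
    group = group_id(index, lab$species, lab$stream),
    first_capture = as.integer(first),
    informative = first < T,
    stringsAsFactors = FALSE
  )
  structure(list(y = y, individuals = individuals,
                 calendar = calendar, index = index),
            class = "capture_history_matrix")
}

#' @export
print.capture_history_matrix <- function(x, ...) {
  cat("Capture histories:", nrow(x$y), "individuals x",
      ncol(x$y), "occasions\n")
  cat(sum(!x$individuals$informative),
      "individual(s) first captured on the final occasion",
      "(no survival information)\n")
  invisible(x)
}

#' Dump a capture-history matrix to long-format encounter records
#'
#' Inverse of [build_capture_histories()]: emits one `detected = 1` row per
#' detection, so rebuilding from the dump reproduces the matrix.
#'
#' @param matrix a `capture_history_matrix`.
#' @return encounter-record data frame.
#' @export
capture_histories_to_records <- function(matrix) {
  idx <- which(matrix$y == 1L, arr.ind = TRUE)
  ind <- matrix$individuals
  out <- data.frame(
    id = ind$id[idx[, 1]],
    species = ind$species[idx[, 1]],
    stream = ind$stream[idx[, 1]],
    occasion = as.integer(idx[, 2]),
    detected = 1L,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id, out$occasion), ]
  rownames(out) <- NULL
  out
}

#' Write a capture-history dump (`id,species,stream,h`)
#'
#' `h` is the T-character 0/1 capture-history string.
#'
#' @param matrix a `capture_history_matrix`.
#' @param path file path.
#' @export
write_capture_histories <- function(matrix, path) {
  h <- apply(matrix$y, 1L, paste, collapse = "")
  df <- data.frame(id = matrix$individuals$id,
                   species = matrix$individuals$species,
                   stream = matrix$individuals$stream,
                   h = h, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tagged-cohort summary
#'
#' Counts unique tagged individuals per species x stream combination.
#'
#' @param matrix a `capture_history_matrix`.
#' @return data frame with columns `species`, `stream`, `n_tagged`, ordered
#'   by the registered index; a total row is not included (sum the column).
#' @export
summarize_cohort <- function(matrix) {
  ind <- matrix$individuals
  g <- matrix$index$groups
  counts <- vapply(g$group, function(k) sum(ind$group == k), integer(1))
  data.frame(species = g$species, stream = g$stream, n_tagged = counts,
             stringsAsFactors = FALSE)
}

# Internal: aggregate a capture-history matrix into unique (group, history)
# rows with multiplicities, dropping individuals first captured at T.
# This is the sufficient form consumed by the likelihood and the sampler.
aggregate_histories <- function(matrix) {
  keep <- matrix$individuals$informative
  y <- matrix$y[keep, , drop = FALSE]
  grp <- matrix$individuals$group[keep]
  if (nrow(y) == 0) {
    return(list(H = matrix(0L, 0, ncol(matrix$y)), first = integer(0),
                group = integer(0), count = integer(0)))
  }
  key <- paste(grp, apply(y, 1L, paste, collapse = ""))
  u <- !duplicated(key)
  H <- y[u, , drop = FALSE]
  storage.mode(H) <- "integer"
  list(H = H,
       first = apply(H, 1L, function(r) which(r == 1L)[1]),
       group = as.integer(grp[u]),
       count = as.integer(table(key)[key[u]]))
}
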