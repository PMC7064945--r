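#' Hourly circadian call pattern of one ego
#'
#' Coarse-grains the time dimension into 24 one-hour slots and computes, for
#' one ego, the fraction of its outgoing calls placed in each slot. A call is
#' binned by its start hour.
#'
#' @param ds a `cdr` object.
#' @param ego ego identifier.
#' @return Numeric 24-vector (names `"0"`..`"23"`) summing to 1, with
#'   attribute `n_calls`; if the ego has no calls, a vector of `NA` with
#'   `n_calls = 0`.
#' @export
hourly_pattern <- function(ds, ego) {
  stopifnot(inherits(ds, "cdr"))
  sel <- ds$records$ego_id == ego
  hours <- as.POSIXlt(ds$records$timestamp[sel])$hour
  n <- length(hours)
  if (n == 0L) {
    p <- rep(NA_real_, 24L)
  } else {
    p <- tabulate(hours + 1L, nbins = 24L) / n
  }
  names(p) <- 0:23
  attr(p, "n_calls") <- n
  p
}

#' Hourly patterns of all egos as a matrix
#'
#' @param ds a `cdr` object.
#' @return Matrix with one row per ego (rownames = ego ids) and 24 columns;
#'   rows of egos without calls are `NA`. Attribute `n_calls` holds the
#'   per-ego call counts.
#' @export
hourly_patterns <- function(ds) {
  egos <- sort(unique(ds$records$ego_id))
  mat <- t(vapply(egos, function(e) as.numeric(hourly_pattern(ds, e)),
                  numeric(24L)))
  colnames(mat) <- 0:23
  attr(mat, "n_calls") <- vapply(
    egos, function(e) sum(ds$records$ego_id == e), integer(1L))
  mat
}

#' Population-average circadian pattern
#'
#' Averages per-ego hourly patterns with equal weight per ego (not pooled
#' calls), so heavy callers do not dominate and the per-hour standard
#' deviation describes between-ego variability. Empty (all-`NA`) patterns are
#' dropped.
#'
#' @param patterns matrix of per-ego patterns as from [hourly_patterns()].
#' @return List with numeric 24-vectors `mean` and `sd` and the number of
#'   contributing egos `n_egos`.
#' @export
aggregate_pattern <- function(patterns) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  keep <- stats::complete.cases(patterns)
  if (!any(keep)) stop("no non-empty patterns to aggregate", call. = FALSE)
  x <- patterns[keep, , drop = FALSE]
  list(mean = colMeans(x),
       sd = apply(x, 2L, stats::sd),
       n_egos = nrow(x))
}

#' Unity-based normalization of an hourly pattern
#'
#' Rescales a 24-vector affinely onto \[0, 1\] (minimum to 0, maximum to 1),
#' the standard display transform for comparing the shape of circadian
#' profiles across egos without letting extreme peaks set the color scale.
#' A constant vector has no shape to display and maps to all zeros, with a
#' warning.
#'
#' @param p numeric 24-vector of finite values.
#' @return Numeric 24-vector in \[0, 1\].
#' @export
unity_normalize <- function(p) {
  if (length(p) != 24L || !all(is.finite(p)))
    stop("p must be a finite 24-vector", call. = FALSE)
  rng <- range(p)
  if (rng[1L] == rng[2L]) {
    warning("constant pattern: unity normalization returns zeros")
    return(stats::setNames(rep(0, 24L), names(p)))
  }
  (p - rng[1L]) / (rng[2L] - rng[1L])
}

#' Split the observation window into successive equal periods
#'
#' Partitions the window into `n_periods` contiguous spans of (near-)equal
#' length in days, labelled `T1`, `T2`, ...; when the day count does not
#' divide evenly the trailing periods each absorb one extra day. Every record
#' is assigned to exactly one period.
#'
#' @param ds a `cdr` object.
#' @param n_periods number of periods (>= 2; default 3, i.e. 4-month periods
#'   for a 12-month window).
#' @return Named list of `cdr` objects (`T1` ... `Tn`), each with its
#'   sub-window.
#' @export
split_periods <- function(ds, n_periods = 3L) {
  stopifnot(inherits(ds, "cdr"))
  n_periods <- as.integer(n_periods)
  if (n_periods < 2L) stop("n_periods must be >= 2", call. = FALSE)
  bounds <- period_bounds(ds$window, n_periods)
  starts <- bounds$starts
  ends <- bounds$ends
  dates <- as.Date(ds$records$timestamp, tz = "UTC")
  out <- lapply(seq_len(n_periods), function(k)
    subset_cdr(ds, dates >= starts[k] & dates <= ends[k],
               window = c(starts[k], ends[k])))
  names(out) <- paste0("T", seq_len(n_periods))
  out
}

# equal-length (in days) contiguous period boundaries; trailing periods
# absorb the remainder one day each
period_bounds <- function(window, n_periods) {
  n_days <- as.integer(window[2L] - window[1L]) + 1L
  if (n_days < n_periods) stop("window shorter than n_periods days",
                               call. = FALSE)
  base <- n_days %/% n_periods
  rem <- n_days %% n_periods
  lengths <- base + as.integer(seq_len(n_periods) > n_periods - rem)
  ends <- window[1L] - 1L + cumsum(lengths)
  starts <- c(window[1L], utils::head(ends, -1L) + 1L)
  list(starts = starts, ends = ends,
       labels = paste0("T", seq_len(n_periods)))
}

#' Per-ego, per-period hourly patterns
#'
#' @param ds a `cdr` object.
#' @param n_periods number of successive periods (default 3).
#' @return Named list (one element per period label) of pattern matrices as
#'   from [hourly_patterns()], all with the same row set (the egos of `ds`).
#' @export
period_patterns <- function(ds, n_periods = 3L) {
  periods <- split_periods(ds, n_periods)
  egos <- sort(unique(ds$records$ego_id))
  lapply(periods, function(p) {
    mat <- matrix(NA_real_, nrow = length(egos), ncol = 24L,
                  dimnames = list(egos, 0:23))
    n_calls <- integer(length(egos))
    for (k in seq_along(egos)) {
      pat <- hourly_pattern(p, egos[k])
      mat[k, ] <- as.numeric(pat)
      n_calls[k] <- attr(pat, "n_calls")
    }
    attr(mat, "n_calls") <- stats::setNames(n_calls, egos)
    mat
  })
}
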