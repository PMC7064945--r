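#' Keep outgoing calls only
#'
#' The analyses in this package are defined on outgoing activity: the ego
#' decides when to place a call, so only outgoing records carry information
#' about the ego's own daily rhythm.
#'
#' @param ds a `cdr` object.
#' @return A `cdr` with only outgoing records; attribute `"report"` holds the
#'   before/after counts.
#' @export
select_outgoing <- function(ds) {
  stopifnot(inherits(ds, "cdr"))
  keep <- ds$records$direction == "outgoing"
  out <- subset_cdr(ds, keep)
  if (nrow(out$records) == 0L)
    message("select_outgoing: no outgoing records remain")
  attr(out, "report") <- list(n_before = nrow(ds$records),
                              n_after = sum(keep))
  out
}

month_index <- function(dates) {
  # months since year 0, so consecutive calendar months differ by 1
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L) * 12L + lt$mon
}

week_index <- function(dates) as.integer(as.numeric(as.Date(dates)) %/% 7L)

activity_units <- function(window, granularity) {
  switch(granularity,
         month = seq.int(month_index(window[1L]), month_index(window[2L])),
         week = seq.int(week_index(window[1L]), week_index(window[2L])),
         stop("granularity must be 'month' or 'week'", call. = FALSE))
}

#' Retain egos active throughout the observation window
#'
#' Keeps only egos that placed at least one outgoing call in every calendar
#' month (or week) of the window — the standard preprocessing step that
#' separates continuously observed participants from those whose activity
#' ceased (device change, operator change, withdrawal). A before/after summary
#' with per-ego call-count quartiles is attached as attribute `"summary"`.
#'
#' @param ds a `cdr` object (typically after [select_outgoing()]).
#' @param granularity `"month"` (default) or `"week"`: the unit in which
#'   "active throughout" is judged.
#' @return Filtered `cdr`; attribute `"summary"` is a data.frame with rows
#'   `before`/`after` and columns `n_egos`, `n_calls`, `q1`, `median`, `q3`
#'   (quartiles of per-ego call counts).
#' @export
filter_active_egos <- function(ds, granularity = c("month", "week")) {
  stopifnot(inherits(ds, "cdr"))
  granularity <- match.arg(granularity)
  units <- activity_units(ds$window, granularity)
  if (length(units) < 2L)
    stop("window spans fewer than 2 ", granularity, "s; cannot judge ",
         "continuous activity", call. = FALSE)
  dates <- as.Date(ds$records$timestamp, tz = "UTC")
  unit_of_call <- switch(granularity, month = month_index(dates),
                         week = week_index(dates))
  active <- tapply(unit_of_call, ds$records$ego_id,
                   function(u) all(units %in% u))
  keep_egos <- names(active)[active]
  out <- subset_cdr(ds, ds$records$ego_id %in% keep_egos)
  attr(out, "summary") <- rbind(
    before = ego_call_summary(ds),
    after = ego_call_summary(out))
  out
}

ego_call_summary <- function(ds) {
  counts <- as.integer(table(ds$records$ego_id))
  q <- if (length(counts) > 0L)
    stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE) else
    rep(NA_real_, 3L)
  data.frame(n_egos = length(counts), n_calls = nrow(ds$records),
             q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Trim the dataset to the best common observation window
#'
#' With staggered enrollment, egos cover different calendar spans. This picks
#' the contiguous month-aligned interval of `months` calendar months in which
#' the greatest number of egos were enrolled (an ego counts if its first and
#' last records bracket the whole interval), breaking ties by the earliest
#' start, and drops records outside it.
#'
#' @param ds a `cdr` object.
#' @param months length of the common window in calendar months (default 12).
#' @return A `cdr` trimmed to the selected window; attribute `"report"` gives
#'   the candidate starts considered and the ego count of the winner.
#' @export
select_common_window <- function(ds, months = 12L) {
  stopifnot(inherits(ds, "cdr"))
  dates <- as.Date(ds$records$timestamp, tz = "UTC")
  first_m <- tapply(month_index(dates), ds$records$ego_id, min)
  last_m <- tapply(month_index(dates), ds$records$ego_id, max)
  span <- seq.int(month_index(ds$window[1L]), month_index(ds$window[2L]))
  if (length(span) < months) {
    stop("no ", months, "-month interval available; maximal span is ",
         length(span), " month(s)", call. = FALSE)
  }
  starts <- span[seq_len(length(span) - months + 1L)]
  n_active <- vapply(starts, function(s)
    sum(first_m <= s & last_m >= s + months - 1L), integer(1L))
  best <- starts[which.max(n_active)]  # which.max takes the earliest tie
  win_start <- month_start_date(best)
  win_end <- month_start_date(best + months) - 1L
  keep <- dates >= win_start & dates <= win_end
  out <- subset_cdr(ds, keep, window = c(win_start, win_end))
  attr(out, "report") <- list(candidate_starts = month_start_date(starts),
                              egos_active = n_active,
                              selected = win_start,
                              n_egos_in_window = max(n_active))
  out
}

month_start_date <- function(mindex) {
  as.Date(sprintf("%04d-%02d-01", mindex %/% 12L, mindex %% 12L + 1L))
}

#' Full preprocessing: outgoing-only, common window, active egos
#'
#' Convenience wrapper chaining [select_outgoing()], [select_common_window()]
#' and [filter_active_egos()], returning the filtered dataset with the
#' combined report attached.
#'
#' @inheritParams filter_active_egos
#' @param months common-window length in months; `NA` to skip window
#'   selection (use when all egos already share the window).
#' @return Filtered `cdr` with attribute `"summary"` as in
#'   [filter_active_egos()].
#' @export
preprocess_cdr <- function(ds, months = NA, granularity = "month") {
  out <- select_outgoing(ds)
  if (!is.na(months)) out <- select_common_window(out, months = months)
  filter_active_egos(out, granularity = granularity)
}
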