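# Small hand-built CDR fixtures used across the test files.

# a cdr object from vectors; defaults fill in a valid single-ego record set
make_cdr <- function(ego = "e1", alter = "a1", day = 0, hour = 10,
                     minute = 0, direction = "outgoing", duration = 60,
                     start = as.Date("2019-01-01"),
                     window_days = 365, contacts = NULL) {
  n <- max(lengths(list(ego, alter, day, hour, minute, direction, duration)))
  rec <- data.frame(
    ego_id = rep_len(ego, n),
    alter_id = rep_len(alter, n),
    timestamp = as.POSIXct(start, tz = "UTC") +
      rep_len(day, n) * 86400 + rep_len(hour, n) * 3600 +
      rep_len(minute, n) * 60,
    direction = rep_len(direction, n),
    duration = rep_len(duration, n),
    stringsAsFactors = FALSE)
  cdr_dataset(rec, contacts = contacts,
              window = c(start, start + window_days - 1))
}

# one call per (ego, month) over 12 months at a fixed hour, minus any
# (ego, month) pairs listed in `skip` (list of month indices per ego name)
make_monthly_cdr <- function(egos, skip = list(), hour = 10) {
  start <- as.Date("2019-01-01")
  rows <- list()
  for (e in egos) {
    months <- setdiff(1:12, skip[[e]])
    for (m in months) {
      d <- seq(start, by = "month", length.out = 12)[m]
      rows[[length(rows) + 1L]] <- data.frame(
        ego_id = e, alter_id = paste0(e, "_a"),
        timestamp = as.POSIXct(d, tz = "UTC") + hour * 3600,
        direction = "outgoing", duration = 60, stringsAsFactors = FALSE)
    }
  }
  cdr_dataset(do.call(rbind, rows),
              window = c(start, as.Date("2019-12-31")))
}

# random probability vector over k slots
random_distribution <- function(k = 24) {
  x <- stats::rgamma(k, shape = 0.7)
  x / sum(x)
}

expect_prob_vector <- function(p) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
}
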