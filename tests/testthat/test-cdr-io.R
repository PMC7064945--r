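test_that("well-formed CSV parses to the same records it came from", {
  ds <- make_cdr(ego = c("e1", "e1", "e2"), alter = c("a1", "a2", "a1"),
                 day = c(0, 5, 10), hour = c(9, 18, 23),
                 duration = c(30, 120, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cdr(ds, path)
  back <- read_cdr(path)
  expect_equal(nrow(back$records), 3L)
  expect_equal(attr(back, "rejected"), 0L)
  # round trip preserves the record multiset
  key <- function(d) sort(with(d$records, paste(ego_id, alter_id,
                                                format(timestamp), duration)))
  expect_identical(key(back), key(ds))
})

test_that("malformed rows are rejected with a count, not an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ego_id,alter_id,timestamp,direction,duration_s",
    "e1,a1,2019-01-01T10:00:00,outgoing,60",
    "e1,a2,2019-01-02T11:00:00,outgoing,-5",
    "e1,a3,not-a-time,outgoing,60",
    "e1,e1,2019-01-03T09:00:00,outgoing,60",
    "e2,a1,2019-01-04T12:00:00,incoming,30"), path)
  expect_message(ds <- read_cdr(path), "rejected 3")
  expect_equal(nrow(ds$records), 2L)
  expect_equal(attr(ds, "rejected"), 3L)
})

test_that("a missing required column is a hard error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ego_id,alter_id,timestamp,duration_s",
               "e1,a1,2019-01-01T10:00:00,60"), path)
  expect_error(read_cdr(path), "direction")
})

test_that("contact categories are validated case-insensitively", {
  contacts <- data.frame(ego_id = c("e1", "e1"), alter_id = c("a1", "a2"),
                         category = c("Family", "HEALTH PROFESSIONALS"))
  ds <- make_cdr(ego = "e1", alter = c("a1", "a2"), day = c(0, 1),
                 contacts = contacts)
  expect_setequal(ds$contacts$category, c("family", "health_professionals"))
  bad <- data.frame(ego_id = "e1", alter_id = "a1", category = "enemy")
  expect_error(make_cdr(contacts = bad), "unknown contact category")
  dup <- data.frame(ego_id = c("e1", "e1"), alter_id = c("a1", "a1"),
                    category = c("family", "friends"))
  expect_error(make_cdr(contacts = dup), "exactly one category")
})

test_that("select_outgoing keeps only outgoing calls and is idempotent", {
  ds <- make_cdr(ego = "e1", alter = paste0("a", 1:8), day = 1:8,
                 direction = c(rep("outgoing", 5), rep("incoming", 3)))
  out <- select_outgoing(ds)
  expect_equal(nrow(out$records), 5L)
  expect_true(all(out$records$direction == "outgoing"))
  expect_equal(attr(out, "report"),
               list(n_before = 8L, n_after = 5L))
  twice <- select_outgoing(out)
  expect_identical(twice$records, out$records)
  # all-incoming input yields a valid empty dataset
  allin <- make_cdr(ego = "e1", alter = paste0("a", 1:3), day = 1:3,
                    direction = "incoming")
  expect_message(empty <- select_outgoing(allin), "no outgoing")
  expect_equal(nrow(empty$records), 0L)
})

test_that("filter_active_egos retains exactly the egos active every month", {
  ds <- make_monthly_cdr(c("e1", "e2", "e3"),
                         skip = list(e2 = 7L, e3 = c(1L, 12L)))
  kept <- filter_active_egos(ds)
  expect_setequal(unique(kept$records$ego_id), "e1")
  s <- attr(kept, "summary")
  expect_equal(s["before", "n_egos"], 3L)
  expect_equal(s["after", "n_egos"], 1L)
  # idempotent, and never increases call counts
  again <- filter_active_egos(kept)
  expect_identical(again$records, kept$records)
  expect_lte(nrow(kept$records), nrow(ds$records))
})

test_that("activity filter errors on a window too short to judge", {
  ds <- make_cdr(day = c(0, 3), window_days = 20)
  expect_error(filter_active_egos(ds), "fewer than 2")
})

test_that("per-ego call summary quartiles match a brute-force sort", {
  set.seed(42)
  counts <- c(e1 = 5L, e2 = 12L, e3 = 9L, e4 = 30L, e5 = 2L)
  ds <- make_cdr(ego = rep(names(counts), counts),
                 alter = "x", day = seq_len(sum(counts)) %% 300,
                 hour = 10)
  s <- attr(filter_active_egos(ds, granularity = "week"), "summary")
  expect_equal(s["before", "median"], sort(counts)[[3L]])
  expect_equal(s["before", "q1"],
               unname(quantile(as.numeric(counts), 0.25)))
  expect_equal(s["before", "n_calls"], sum(counts))
})

test_that("common window maximizes enrolled egos; ties go to earliest", {
  start <- as.Date("2018-01-01")
  mk <- function(ego, from, to) {
    months <- seq(from, to)
    data.frame(ego_id = ego, alter_id = "x",
               timestamp = as.POSIXct(
                 seq(start, by = "month", length.out = 30)[months],
                 tz = "UTC") + 10 * 3600,
               direction = "outgoing", duration = 60,
               stringsAsFactors = FALSE)
  }
  # e1 covers months 1-18, e2 months 4-20, e3 months 7-24
  rec <- rbind(mk("e1", 1, 18), mk("e2", 4, 20), mk("e3", 7, 24))
  ds <- cdr_dataset(rec)
  out <- select_common_window(ds, months = 12L)
  # brute-force oracle over all month-aligned 12-month starts
  spans <- list(e1 = c(1, 18), e2 = c(4, 20), e3 = c(7, 24))
  oracle <- vapply(1:13, function(s)
    sum(vapply(spans, function(sp) sp[1] <= s && sp[2] >= s + 11,
               logical(1))), integer(1))
  expect_equal(out$window[1L],
               seq(start, by = "month", length.out = 30)[which.max(oracle)])
  expect_equal(attr(out, "report")$n_egos_in_window, max(oracle))
  dates <- as.Date(out$records$timestamp, tz = "UTC")
  expect_true(all(dates >= out$window[1L] & dates <= out$window[2L]))
  # tie between two disjoint enrolment groups resolves to the earlier start
  rec_tie <- rbind(mk("e1", 1, 12), mk("e2", 13, 24))
  tie <- select_common_window(cdr_dataset(rec_tie), months = 12L)
  expect_equal(tie$window[1L], start)
  # identical spans: the window is the full common year
  ds2 <- make_monthly_cdr(c("e1", "e2"))
  out2 <- select_common_window(ds2, months = 12L)
  expect_equal(out2$window, ds2$window)
  expect_equal(nrow(out2$records), nrow(ds2$records))
})

test_that("common window errors when the span is too short", {
  ds <- make_monthly_cdr("e1")
  expect_error(select_common_window(ds, months = 24L), "maximal span is 12")
})
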