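test_that("time bins follow the half-open 6-hour convention", {
  expect_equal(time_bin(c(0, 5, 6, 11, 12, 17, 18, 23)),
               rep(c("night", "morning", "afternoon", "evening"), each = 2))
  ds <- make_cdr(alter = paste0("a", 1:4), day = 1:4,
                 hour = c(2, 9, 14, 21))
  bc <- bin_calls(ds, "e1")
  expect_equal(vapply(bc, sum, numeric(1)),
               c(night = 1, morning = 1, afternoon = 1, evening = 1))
  # boundary: 05:59 is night, 06:00 is morning
  ds2 <- make_cdr(alter = c("a1", "a2"), day = 1:2, hour = c(5, 6),
                  minute = c(59, 0))
  bc2 <- bin_calls(ds2, "e1")
  expect_equal(names(bc2$night), "a1")
  expect_equal(names(bc2$morning), "a2")
})

test_that("bin totals always sum to the period total", {
  set.seed(10)
  ds <- make_cdr(alter = sample(paste0("a", 1:6), 400, replace = TRUE),
                 day = sample(0:364, 400, replace = TRUE),
                 hour = sample(0:23, 400, replace = TRUE))
  bc <- bin_calls(ds, "e1")
  expect_equal(sum(unlist(bc)), 400)
})

test_that("origin entropy matches the direct -sum f log2 f oracle", {
  expect_equal(origin_entropy(c(A = 5)), 0)
  expect_equal(origin_entropy(c(A = 2, B = 2)), 1)
  expect_equal(origin_entropy(c(A = 3, B = 1)), 0.81128, tolerance = 1e-5)
  expect_true(is.na(origin_entropy(setNames(integer(0), character(0)))))
  expect_error(origin_entropy(c(A = -1, B = 2)), "non-negative")
  set.seed(77)
  for (i in 1:500) {
    counts <- rpois(sample(1:12, 1), lambda = 3)
    h <- origin_entropy(counts)
    total <- sum(counts)
    if (total == 0) {
      expect_true(is.na(h))
    } else {
      f <- counts[counts > 0] / total
      expect_equal(h, -sum(f * log2(f)), tolerance = 1e-12)
      # bounded by log2 of the support size, equality iff uniform
      expect_lte(h, log2(max(1, sum(counts > 0))) + 1e-12)
    }
  }
})

test_that("the shuffling null preserves its conservation laws", {
  set.seed(20)
  n <- 500
  ds <- make_cdr(alter = sample(paste0("a", 1:8), n, replace = TRUE,
                                prob = 8:1),
                 day = sample(0:364, n, replace = TRUE),
                 hour = sample(0:23, n, replace = TRUE,
                               prob = random_distribution()))
  block_of <- function(d) as.integer(as.Date(d$records$timestamp,
                                             tz = "UTC") -
                                       d$window[1]) %/% 14L
  orig_blocks <- block_of(ds)
  for (i in 1:25) {
    sh <- shuffle_null(ds, "e1", seed = i)
    # exact timestamp multiset (here even the order is fixed)
    expect_identical(sh$records$timestamp, ds$records$timestamp)
    # per-alter counts within every 14-day block
    expect_equal(table(orig_blocks, sh$records$alter_id),
                 table(orig_blocks, ds$records$alter_id))
    # durations travel with their alter labels
    expect_equal(sort(paste(sh$records$alter_id, sh$records$duration)),
                 sort(paste(ds$records$alter_id, ds$records$duration)))
  }
  # a single-call block cannot move
  one <- make_cdr(day = 0, hour = 10)
  expect_identical(shuffle_null(one, "e1", seed = 1)$records,
                   one$records)
})

test_that("reference entropy is zero for a single-alter ego and reproducible", {
  ds <- make_cdr(alter = "a1", day = seq(0, 364, by = 2),
                 hour = rep(c(3, 9, 15, 21), length.out = 183))
  h <- reference_entropy(ds, "e1", n_iter = 20, seed = 1)
  expect_equal(unname(h[!is.na(h)]), rep(0, sum(!is.na(h))))
  set.seed(2)
  ds2 <- make_cdr(alter = sample(paste0("a", 1:5), 300, replace = TRUE),
                  day = sample(0:364, 300, replace = TRUE),
                  hour = sample(0:23, 300, replace = TRUE))
  expect_identical(reference_entropy(ds2, "e1", n_iter = 30, seed = 7),
                   reference_entropy(ds2, "e1", n_iter = 30, seed = 7))
  expect_error(reference_entropy(ds2, "e1", n_iter = 0), "n_iter")
})

test_that("with flat alter use the reference entropy approaches the origin", {
  set.seed(14)
  n <- 5000
  ds <- make_cdr(alter = sample(paste0("a", 1:6), n, replace = TRUE),
                 day = sample(0:364, n, replace = TRUE),
                 hour = sample(0:23, n, replace = TRUE))
  h_ref <- reference_entropy(ds, "e1", n_iter = 50, seed = 3)
  periods <- split_periods(ds, 3)
  for (t in 1:3) {
    h_orig <- vapply(bin_calls(periods[[t]], "e1"), origin_entropy,
                     numeric(1))
    expect_equal(unname(h_ref[t, ]), unname(h_orig), tolerance = 0.02)
  }
})

test_that("relative entropy guards near-zero references as missing", {
  expect_equal(relative_entropy(0, 1.2), 0)
  expect_true(is.na(relative_entropy(0, 0)))
  expect_true(is.na(relative_entropy(1, 1e-12)))
  expect_true(is.na(relative_entropy(NA_real_, 1)))
  expect_equal(relative_entropy(c(0.5, 1), c(1, 0.5)), c(0.5, 2))
  expect_error(relative_entropy(-0.1, 1), "non-negative")
})

test_that("top-2 fractions follow counts with lexicographic tie-breaks", {
  t1 <- top2_fraction(c(A = 5, B = 3, C = 2))
  expect_equal(t1$fraction, 0.8)
  expect_setequal(t1$alters, c("A", "B"))
  expect_equal(top2_fraction(c(Z = 7))$fraction, 1)
  t3 <- top2_fraction(c(C = 2, A = 2, B = 2))
  expect_equal(t3$fraction, 2 / 3)
  expect_equal(sort(t3$alters), c("A", "B"))
  expect_true(is.na(top2_fraction(c(A = 0))$fraction))
})

test_that("entropy/top-2 correlation handles perfect and degenerate series", {
  prof <- data.frame(
    ego_id = "e1", period = rep(c("T1", "T2", "T3"), each = 4),
    bin = rep(c("night", "morning", "afternoon", "evening"), 3),
    h_relative = seq(0.1, 1.2, length.out = 12))
  prof$top2_fraction <- 1 - prof$h_relative
  corr <- entropy_top2_correlation(prof)
  expect_equal(corr$per_ego$r, -1)
  expect_equal(corr$population_r, -1)
  # constant top-2 series is undetermined
  prof$top2_fraction <- 0.5
  corr2 <- entropy_top2_correlation(prof)
  expect_true(is.na(corr2$per_ego$r))
  # fewer than min_points complete cells is undetermined
  prof$top2_fraction <- 1 - prof$h_relative
  prof$h_relative[1:10] <- NA
  expect_true(is.na(entropy_top2_correlation(prof)$per_ego$r))
})

test_that("entropy profile is internally consistent and reproducible", {
  cfg <- generator_config(n_egos = 4, calls_per_year = 300, seed = 19)
  ds <- generate_cdr(cfg)$dataset
  prof <- entropy_profile(ds, n_iter = 25, seed = 5)
  expect_equal(nrow(prof), 4 * 3 * 4)
  # per-ego totals match the dataset
  totals <- tapply(prof$n_calls, prof$ego_id, sum)
  expect_equal(as.integer(totals[sort(unique(ds$records$ego_id))]),
               as.integer(table(ds$records$ego_id)))
  # h_relative consistent with its parts
  ok <- !is.na(prof$h_relative)
  expect_equal(prof$h_relative[ok],
               (prof$h_origin / prof$h_reference)[ok])
  expect_identical(as.data.frame(entropy_profile(ds, n_iter = 25, seed = 5)),
                   as.data.frame(prof))
})

test_that("duration profiles average correctly by category and hour", {
  contacts <- data.frame(ego_id = "e1", alter_id = c("a1", "a2"),
                         category = c("family", "friends"))
  ds <- make_cdr(alter = rep(c("a1", "a2"), each = 3),
                 day = 1:6, hour = c(9, 9, 18, 9, 18, 18),
                 duration = c(100, 200, 300, 40, 60, 80),
                 contacts = contacts)
  dp <- duration_profiles(ds)
  expect_equal(dp$mean_duration[dp$category == "family" & dp$hour == 9], 150)
  expect_equal(dp$mean_duration[dp$category == "family" & dp$hour == 18], 300)
  expect_equal(dp$mean_duration[dp$category == "friends" & dp$hour == 18], 70)
  # all calls 60 s -> flat 60 s profile; unlisted alters fall under others
  ds2 <- make_cdr(alter = c("a1", "mystery"), day = 1:2, hour = c(10, 11),
                  duration = 60, contacts = contacts)
  dp2 <- duration_profiles(ds2)
  expect_true(all(dp2$mean_duration == 60))
  expect_true("others" %in% dp2$category)
  expect_error(duration_profiles(make_cdr()), "contact directory")
})

test_that("synthetic close ties talk longer than health professionals in the evening", {
  cfg <- generator_config(n_egos = 8, calls_per_year = 2000, seed = 25)
  ds <- generate_cdr(cfg)$dataset
  dp <- duration_profiles(ds)
  evening <- dp[dp$hour >= 18, ]
  fam <- with(evening, weighted.mean(mean_duration[category == "family"],
                                     n_calls[category == "family"]))
  hp <- with(evening, weighted.mean(
    mean_duration[category == "health_professionals"],
    n_calls[category == "health_professionals"]))
  expect_gt(fam, hp)
})

test_that("stronger evening concentration lowers evening relative entropy", {
  run <- function(conc_evening, seed) {
    cfg <- generator_config(
      n_egos = 5, calls_per_year = 500, nocturnal_ego = FALSE,
      concentration = c(night = 50, morning = 50, afternoon = 50,
                        evening = conc_evening),
      top2_evening_share = NA, seed = seed)
    ds <- generate_cdr(cfg)$dataset
    prof <- entropy_profile(ds, n_iter = 40, seed = seed + 1)
    ev <- prof$bin == "evening" & !is.na(prof$h_relative) &
      prof$n_calls >= 20
    c(h_rel = mean(prof$h_relative[ev]),
      top2 = mean(prof$top2_fraction[ev]))
  }
  res_diffuse <- rowMeans(vapply(1:3, function(s) run(60, s), numeric(2)))
  res_conc <- rowMeans(vapply(1:3, function(s) run(1.5, s), numeric(2)))
  expect_lt(res_conc[["h_rel"]], res_diffuse[["h_rel"]])
  expect_gt(res_conc[["top2"]], res_diffuse[["top2"]])
})
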