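BIN_LEVELS <- c("night", "morning", "afternoon", "evening")

#' Configuration for the synthetic CDR generator
#'
#' Describes a population of egos whose outgoing-call behaviour has the
#' statistical structure the analyses in this package assume: ego-specific
#' circadian profiles (a wrapped-Gaussian mixture of daily peaks over a
#' uniform floor), a Zipf-weighted alter network with time-of-day-dependent
#' alter choice, and right-skewed call durations whose scale depends on the
#' alter's social category and the hour of day.
#'
#' The defaults emulate a 12-month panel of 21 older adults: roughly 700
#' outgoing calls per ego-year (median near 680 after lognormal between-ego
#' dispersion), twin activity peaks at 10:00 and 18:00 with per-ego jitter and
#' a per-ego morning/evening preference, one nocturnal ego peaking near 02:00
#' whose night calls all go to a single alter, and evening/night call traffic
#' concentrated on each ego's top 2 alters.
#'
#' @param n_egos number of egos.
#' @param months observation length in calendar months.
#' @param start first day of the observation window (`Date` or string).
#' @param calls_per_year mean outgoing-call rate per ego-year.
#' @param rate_sd standard deviation of the per-ego lognormal rate multiplier
#'   (0 gives every ego the same rate).
#' @param peaks optional data.frame with columns `center` (hour, 0-24),
#'   `spread` (circular SD in hours; 0 collapses the peak onto one slot) and
#'   `weight`; when supplied it is used verbatim for every ego (no per-ego
#'   variation, `drift` has no effect on hours). When `NULL` (default) each
#'   ego draws its own morning/evening mixture, see the remaining arguments.
#' @param floor_weight probability mass spread uniformly over the 24 hours
#'   (background propensity to call at any time).
#' @param peak_jitter half-width (hours) of the uniform per-ego jitter on the
#'   default peak centers at 10:00 and 18:00.
#' @param morning_weight_range range of the per-ego weight of the morning
#'   peak; the evening peak receives the remaining non-floor mass.
#' @param spread_range range of the per-ego peak spread in hours.
#' @param network_size alters per ego; base popularity is Zipf (rank r gets
#'   weight proportional to 1/r).
#' @param category_weights named probabilities over the five contact
#'   categories used when assigning each alter a category.
#' @param concentration named per-bin Dirichlet concentration (total alpha)
#'   governing how strongly the bin-specific alter distribution concentrates:
#'   the per-alter alpha is `concentration[bin] * base_weight`. Low values
#'   (default: night and evening) produce bins dominated by few alters;
#'   `Inf` removes the Dirichlet noise so every bin uses the shared base
#'   distribution — the no-alter-time-association calibration setting.
#' @param top2_evening_share fraction of evening and night calls routed to
#'   the ego's top 2 base alters; `NA` disables the routing (also part of the
#'   calibration setting).
#' @param duration_model data.frame with columns `category`, `meanlog`,
#'   `sdlog`, `hour_slope`: call durations are lognormal with location
#'   `meanlog + hour_slope * (hour - 12)`, so positive slopes (family,
#'   friends) lengthen evening calls and negative slopes (associations,
#'   health professionals) shorten them.
#' @param drift if `TRUE`, each ego redraws its circadian mixture
#'   independently in every 4-month block — a persistence-breaking control.
#' @param nocturnal_ego include one ego (the last) peaking at 02:00 whose
#'   night-bin calls all go to one alter.
#' @param silent_month_egos number of egos (the first ones) given one random
#'   fully silent calendar month — a device for testing the activity filter.
#' @param seed default seed used by [generate_cdr()] when none is passed.
#' @return A validated `generator_config` object (list).
#' @seealso [generate_cdr()], [true_hourly_profile()]
#' @export
generator_config <- function(n_egos = 21L,
                             months = 12L,
                             start = "2019-01-01",
                             calls_per_year = 700,
                             rate_sd = 0.25,
                             peaks = NULL,
                             floor_weight = 0.10,
                             peak_jitter = 0.5,
                             morning_weight_range = c(0.25, 0.60),
                             spread_range = c(1.0, 2.5),
                             network_size = 15L,
                             category_weights = c(family = 0.35,
                                                  friends = 0.30,
                                                  associations = 0.15,
                                                  health_professionals = 0.10,
                                                  others = 0.10),
                             concentration = c(night = 5, morning = 50,
                                               afternoon = 50, evening = 5),
                             top2_evening_share = 0.70,
                             duration_model = default_duration_model(),
                             drift = FALSE,
                             nocturnal_ego = TRUE,
                             silent_month_egos = 0L,
                             seed = NULL) {
  config <- list(n_egos = as.integer(n_egos), months = as.integer(months),
                 start = as.Date(start), calls_per_year = calls_per_year,
                 rate_sd = rate_sd, peaks = peaks,
                 floor_weight = floor_weight, peak_jitter = peak_jitter,
                 morning_weight_range = morning_weight_range,
                 spread_range = spread_range,
                 network_size = as.integer(network_size),
                 category_weights = category_weights,
                 concentration = concentration,
                 top2_evening_share = top2_evening_share,
                 duration_model = duration_model, drift = isTRUE(drift),
                 nocturnal_ego = isTRUE(nocturnal_ego),
                 silent_month_egos = as.integer(silent_month_egos),
                 seed = seed)
  validate_generator_config(config)
  structure(config, class = "generator_config")
}

validate_generator_config <- function(config) {
  with(config, {
    if (n_egos < 1L) stop("n_egos must be >= 1", call. = FALSE)
    if (months < 1L) stop("months must be >= 1", call. = FALSE)
    if (calls_per_year <= 0) stop("calls_per_year must be > 0", call. = FALSE)
    if (rate_sd < 0) stop("rate_sd must be >= 0", call. = FALSE)
    if (floor_weight < 0 || floor_weight > 1)
      stop("floor_weight must lie in [0, 1]", call. = FALSE)
    if (network_size < 2L) stop("network_size must be >= 2", call. = FALSE)
    if (any(category_weights < 0) ||
        !setequal(names(category_weights), CONTACT_CATEGORIES))
      stop("category_weights must be non-negative and named by the five ",
           "contact categories", call. = FALSE)
    if (!setequal(names(concentration), BIN_LEVELS) ||
        any(concentration <= 0))
      stop("concentration must be positive and named by the four time bins",
           call. = FALSE)
    if (!is.na(top2_evening_share) &&
        (top2_evening_share < 0 || top2_evening_share > 1))
      stop("top2_evening_share must lie in [0, 1] or be NA", call. = FALSE)
    if (!all(c("category", "meanlog", "sdlog", "hour_slope") %in%
             names(duration_model)))
      stop("duration_model must have columns category, meanlog, sdlog, ",
           "hour_slope", call. = FALSE)
    if (!is.null(peaks)) {
      if (!all(c("center", "spread", "weight") %in% names(peaks)))
        stop("peaks must have columns center, spread, weight", call. = FALSE)
      if (any(peaks$weight < 0) || (sum(peaks$weight) + floor_weight) <= 0)
        stop("peak weights must be non-negative with positive total mass",
             call. = FALSE)
    }
    if (silent_month_egos < 0L || silent_month_egos > n_egos)
      stop("silent_month_egos must lie in [0, n_egos]", call. = FALSE)
  })
  invisible(config)
}

#' Default category-specific duration model
#'
#' Lognormal location/scale per contact category with a linear hour-of-day
#' trend on the log scale: calls to close ties (family, friends) are longer
#' overall and lengthen toward the evening; calls to associations and health
#' professionals are shorter, office-hours-bound, and shorten after midday.
#'
#' @return data.frame with columns `category`, `meanlog`, `sdlog`,
#'   `hour_slope`.
#' @export
default_duration_model <- function() {
  data.frame(
    category = c("family", "friends", "associations",
                 "health_professionals", "others"),
    meanlog = c(5.0, 4.8, 4.0, 3.8, 4.2),
    sdlog = c(0.7, 0.7, 0.5, 0.4, 0.6),
    hour_slope = c(0.035, 0.030, -0.030, -0.035, 0),
    stringsAsFactors = FALSE)
}

#' Evaluate a circadian mixture on the 24 hour slots
#'
#' Evaluates a wrapped-Gaussian mixture (plus a uniform floor) at the
#' midpoints of the 24 one-hour slots and normalizes to a probability vector.
#' A peak with `spread = 0` puts all its mass in the slot containing its
#' center.
#'
#' @param peaks data.frame with columns `center`, `spread`, `weight`.
#' @param floor_weight mass spread uniformly over all slots.
#' @return Numeric 24-vector summing to 1 (slots 0-23 by start hour).
#' @export
true_hourly_profile <- function(peaks, floor_weight = 0) {
  total <- floor_weight + if (is.null(peaks) || nrow(peaks) == 0L) 0 else
    sum(peaks$weight)
  if (total <= 0) stop("mixture has no mass", call. = FALSE)
  p <- rep(floor_weight / 24, 24L)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    mids <- 0:23 + 0.5
    for (j in seq_len(nrow(peaks))) {
      if (peaks$weight[j] <= 0) next
      if (peaks$spread[j] <= 0) {
        kernel <- numeric(24L)
        kernel[(floor(peaks$center[j]) %% 24L) + 1L] <- 1
      } else {
        center <- (peaks$center[j] %% 24) + 0.5
        kernel <- rowSums(vapply(-3:3, function(k)
          stats::dnorm(mids, center + 24 * k, peaks$spread[j]),
          numeric(24L)))
        kernel <- kernel / sum(kernel)
      }
      p <- p + peaks$weight[j] * kernel
    }
  }
  p / sum(p)
}

# deterministic per-stream seed derivation, safely inside 32-bit range
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 1009 + as.numeric(stream) * 9973 + 1) %%
               2147483629)
}

hour_bin <- function(hour) {
  BIN_LEVELS[hour %/% 6L + 1L]
}

zipf_weights <- function(m) {
  w <- 1 / seq_len(m)
  w / sum(w)
}

# draw one ego's circadian mixture (default morning/evening scheme)
draw_ego_peaks <- function(config) {
  wm <- stats::runif(1, config$morning_weight_range[1L],
                     config$morning_weight_range[2L]) *
    (1 - config$floor_weight)
  we <- (1 - config$floor_weight) - wm
  data.frame(
    center = c(10, 18) + stats::runif(2, -config$peak_jitter,
                                      config$peak_jitter),
    spread = stats::runif(2, config$spread_range[1L],
                          config$spread_range[2L]),
    weight = c(wm, we))
}

nocturnal_peaks <- function(config) {
  data.frame(center = 2, spread = 0.8, weight = 1 - config$floor_weight)
}

# per-bin alter distribution for one ego (rows = bins, cols = alters)
draw_alter_distributions <- function(config, base_w) {
  m <- length(base_w)
  out <- matrix(0, nrow = 4L, ncol = m, dimnames = list(BIN_LEVELS, NULL))
  share <- config$top2_evening_share
  for (b in BIN_LEVELS) {
    alpha_total <- config$concentration[[b]]
    p <- if (is.infinite(alpha_total)) base_w else {
      g <- stats::rgamma(m, shape = alpha_total * base_w)
      if (sum(g) <= 0) base_w else g / sum(g)
    }
    if (!is.na(share) && b %in% c("evening", "night")) {
      # route a fixed share to the two most popular base alters
      top2 <- order(base_w, decreasing = TRUE)[1:2]
      rest <- p
      rest[top2] <- 0
      rest <- if (sum(rest) > 0) rest / sum(rest) else
        rep(1 / (m - 2L), m) * as.numeric(!(seq_len(m) %in% top2))
      p <- numeric(m)
      p[top2] <- share * base_w[top2] / sum(base_w[top2])
      p <- p + (1 - share) * rest
    }
    out[b, ] <- p
  }
  out
}

#' Generate a synthetic CDR dataset with known ground truth
#'
#' Samples a full call-detail-record dataset from a [generator_config()]:
#' per ego, a Poisson total call count, call days uniform over the window,
#' hours drawn from the ego's circadian mixture, alters drawn from the
#' bin-specific alter distribution and durations from the category/hour
#' duration model. The generator is hierarchically seeded (one derived stream
#' per ego), so runs are fully reproducible and adding an ego does not
#' perturb the other egos' draws.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return List with elements `dataset` (a [cdr_dataset()] including the
#'   contact directory) and `truth` (per-ego true hourly profiles — one row
#'   per 4-month block when `drift = TRUE` — per-bin alter distributions,
#'   silent months, and flags).
#' @export
generate_cdr <- function(config, seed = config$seed) {
  validate_generator_config(config)
  if (is.null(seed)) stop("a seed is required for reproducible generation",
                          call. = FALSE)
  win_start <- config$start
  win_end <- seq(win_start, by = paste(config$months, "months"),
                 length.out = 2L)[2L] - 1L
  days <- seq(win_start, win_end, by = "day")
  day_block <- pmin(
    (month_index(days) - month_index(win_start)) %/% 4L + 1L,
    max(1L, ceiling(config$months / 4)))
  n_blocks <- if (config$drift) max(day_block) else 1L
  m <- config$network_size
  base_w <- zipf_weights(m)
  cat_names <- names(config$category_weights)

  rec_list <- vector("list", config$n_egos)
  contacts_list <- vector("list", config$n_egos)
  truth <- list(hourly = list(), alter = list(), silent_month = list(),
                drift = config$drift, nocturnal_ego = NA_character_)

  for (i in seq_len(config$n_egos)) {
    ego <- sprintf("ego%02d", i)
    set.seed(derive_seed(seed, i))
    is_nocturnal <- config$nocturnal_ego && i == config$n_egos &&
      is.null(config$peaks)
    if (is_nocturnal) truth$nocturnal_ego <- ego

    rate <- config$calls_per_year *
      stats::rlnorm(1, -config$rate_sd^2 / 2, config$rate_sd)

    profiles <- matrix(0, nrow = n_blocks, ncol = 24L,
                       dimnames = list(paste0("block", seq_len(n_blocks)),
                                       0:23))
    for (blk in seq_len(n_blocks)) {
      pk <- if (!is.null(config$peaks)) config$peaks
        else if (is_nocturnal) nocturnal_peaks(config)
        else draw_ego_peaks(config)
      profiles[blk, ] <- true_hourly_profile(pk, config$floor_weight)
    }

    alter_ids <- sprintf("%s_a%02d", ego, seq_len(m))
    alter_cat <- sample(cat_names, m, replace = TRUE,
                        prob = config$category_weights)
    adist <- draw_alter_distributions(config, base_w)
    if (is_nocturnal) {
      adist["night", ] <- 0
      adist["night", 1L] <- 1  # all nocturnal calls to one alter
    }
    colnames(adist) <- alter_ids

    n_calls <- stats::rpois(1, rate * config$months / 12)
    if (n_calls == 0L) {
      rec_list[[i]] <- data.frame(ego_id = character(0),
                                  alter_id = character(0),
                                  timestamp = as.POSIXct(character(0),
                                                         tz = "UTC"),
                                  direction = character(0),
                                  duration = numeric(0),
                                  stringsAsFactors = FALSE)
      contacts_list[[i]] <- data.frame(ego_id = ego, alter_id = alter_ids,
                                       category = alter_cat,
                                       stringsAsFactors = FALSE)
      truth$hourly[[ego]] <- profiles
      truth$alter[[ego]] <- adist
      next
    }
    day_idx <- sample.int(length(days), n_calls, replace = TRUE)
    blk_of_call <- if (config$drift) day_block[day_idx] else
      rep(1L, n_calls)
    hour <- integer(n_calls)
    for (blk in unique(blk_of_call)) {
      sel <- blk_of_call == blk
      hour[sel] <- sample(0:23, sum(sel), replace = TRUE,
                          prob = profiles[blk, ])
    }
    bin <- hour_bin(hour)
    alter_idx <- integer(n_calls)
    for (b in unique(bin)) {
      sel <- bin == b
      alter_idx[sel] <- sample.int(m, sum(sel), replace = TRUE,
                                   prob = adist[b, ])
    }
    dm <- config$duration_model
    row_of_cat <- match(alter_cat[alter_idx], dm$category)
    duration <- pmax(1, round(stats::rlnorm(
      n_calls,
      meanlog = dm$meanlog[row_of_cat] +
        dm$hour_slope[row_of_cat] * (hour - 12),
      sdlog = dm$sdlog[row_of_cat])))
    timestamp <- as.POSIXct(days[day_idx], tz = "UTC") +
      hour * 3600 + sample.int(3600, n_calls, replace = TRUE) - 1L

    rec <- data.frame(ego_id = ego, alter_id = alter_ids[alter_idx],
                      timestamp = timestamp, direction = "outgoing",
                      duration = duration, stringsAsFactors = FALSE)

    if (i <= config$silent_month_egos) {
      silent <- sample.int(config$months, 1L)
      silent_m <- month_index(win_start) + silent - 1L
      rec <- rec[month_index(as.Date(rec$timestamp, tz = "UTC")) != silent_m,
                 , drop = FALSE]
      truth$silent_month[[ego]] <- silent
    }

    rec_list[[i]] <- rec
    contacts_list[[i]] <- data.frame(ego_id = ego, alter_id = alter_ids,
                                     category = alter_cat,
                                     stringsAsFactors = FALSE)
    truth$hourly[[ego]] <- profiles
    truth$alter[[ego]] <- adist
  }

  ds <- cdr_dataset(do.call(rbind, rec_list),
                    contacts = do.call(rbind, contacts_list),
                    window = c(win_start, win_end))
  list(dataset = ds, truth = truth)
}
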