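#' Bin label of an hour of day
#'
#' Six-hour bins by start hour, half-open: night \[0, 6), morning \[6, 12),
#' afternoon \[12, 18), evening \[18, 24).
#'
#' @param hour integer hour(s) in 0-23.
#' @return Character vector of bin labels.
#' @export
time_bin <- function(hour) {
  stopifnot(all(hour >= 0 & hour <= 23))
  hour_bin(as.integer(hour))
}

#' Per-bin alter call counts for one ego
#'
#' Tallies one ego's outgoing calls to each alter within each of the four
#' 6-hour bins of `ds` (use a period subset from [split_periods()] for
#' per-period counts).
#'
#' @param ds a `cdr` object.
#' @param ego ego identifier.
#' @return Named list `night`, `morning`, `afternoon`, `evening`, each a
#'   named integer vector of per-alter call counts (empty bins give
#'   zero-length vectors).
#' @export
bin_calls <- function(ds, ego) {
  stopifnot(inherits(ds, "cdr"))
  sel <- ds$records$ego_id == ego
  hours <- as.POSIXlt(ds$records$timestamp[sel])$hour
  alters <- ds$records$alter_id[sel]
  bins <- factor(hour_bin(hours), levels = BIN_LEVELS)
  out <- lapply(split(alters, bins), function(a) {
    if (length(a) == 0L) return(stats::setNames(integer(0), character(0)))
    tab <- table(a)
    stats::setNames(as.integer(tab), names(tab))
  })
  out[BIN_LEVELS]
}

#' Origin entropy of a bin's alter distribution
#'
#' Shannon entropy (bits) of the distribution of an ego's calls over alters
#' within one time bin: 0 when all calls go to one alter (maximal
#' alter-specificity), up to `log2(m)` when calls spread uniformly over `m`
#' alters. An empty bin carries no information and returns `NA` (missing),
#' not zero.
#'
#' @param counts named non-negative vector of per-alter call counts.
#' @return Entropy in bits, or `NA_real_` for an empty bin.
#' @export
origin_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  shannon_bits(counts / total)
}

#' Time-shuffling null model for one ego
#'
#' Destroys alter-time associations while preserving everything else: within
#' each consecutive block of `block_days` days of the observation window, the
#' ego's call timestamps stay exactly where they are and the (alter,
#' duration) labels are randomly permuted across those calls. Per-alter call
#' totals within each block, the overall hourly call histogram and the
#' timestamp multiset are all conserved.
#'
#' @param ds a `cdr` object.
#' @param ego ego whose calls are shuffled (other egos' records pass through
#'   untouched).
#' @param block_days shuffle-block length in days (default 14, i.e. 2-week
#'   blocks).
#' @param seed optional integer seed.
#' @return A `cdr` object with the ego's alter/duration labels permuted.
#' @export
shuffle_null <- function(ds, ego, block_days = 14L, seed = NULL) {
  stopifnot(inherits(ds, "cdr"))
  if (!is.null(seed)) set.seed(seed)
  sel <- which(ds$records$ego_id == ego)
  if (length(sel) == 0L) stop("ego has no calls: ", ego, call. = FALSE)
  dates <- as.Date(ds$records$timestamp[sel], tz = "UTC")
  block <- as.integer(dates - ds$window[1L]) %/% as.integer(block_days)
  perm <- seq_along(sel)
  for (idx in split(seq_along(sel), block)) {
    if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
  }
  records <- ds$records
  records$alter_id[sel] <- records$alter_id[sel][perm]
  records$duration[sel] <- records$duration[sel][perm]
  out <- ds
  out$records <- records
  out
}

# integer-coded call table for one ego: cell = (period, bin), block index,
# alter index; the workhorse behind the entropy computations
ego_call_codes <- function(ds, ego, n_periods, block_days) {
  sel <- ds$records$ego_id == ego
  ts <- ds$records$timestamp[sel]
  dates <- as.Date(ts, tz = "UTC")
  bounds <- period_bounds(ds$window, n_periods)
  period <- findInterval(as.integer(dates), as.integer(bounds$starts))
  bin <- as.integer(factor(hour_bin(as.POSIXlt(ts)$hour),
                           levels = BIN_LEVELS))
  alter <- factor(ds$records$alter_id[sel])
  list(cell = (period - 1L) * 4L + bin,
       n_cells = n_periods * 4L,
       block = as.integer(dates - ds$window[1L]) %/% as.integer(block_days),
       alter = as.integer(alter),
       m = nlevels(alter),
       alter_levels = levels(alter),
       period_labels = bounds$labels)
}

# entropy (bits) of each row of a count matrix; empty rows give NA
row_entropies <- function(mat) {
  totals <- rowSums(mat)
  p <- mat / ifelse(totals > 0, totals, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[totals == 0] <- NA_real_
  h
}

cell_count_matrix <- function(cell, alter, n_cells, m) {
  matrix(tabulate(cell + n_cells * (alter - 1L), nbins = n_cells * m),
         nrow = n_cells)
}

#' Mean reference entropy under the shuffling null
#'
#' Repeats the block-wise alter shuffle of [shuffle_null()] `n_iter` times
#' and averages, per (period, bin) cell, the origin entropy of the shuffled
#' data — the expected alter diversity if no particular alter were tied to
#' any particular time of day. Cells empty in the original data stay missing.
#'
#' @param ds a `cdr` object.
#' @param ego ego identifier.
#' @param n_periods number of successive periods (default 3).
#' @param n_iter number of shuffle iterations (default 1000).
#' @param block_days shuffle-block length in days (default 14).
#' @param seed integer seed (required for reproducibility).
#' @return Matrix `n_periods` x 4 (rows `T1`..`Tn`, columns the bins) of mean
#'   reference entropies in bits; `NA` for empty cells.
#' @export
reference_entropy <- function(ds, ego, n_periods = 3L, n_iter = 1000L,
                              block_days = 14L, seed = NULL) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cc <- ego_call_codes(ds, ego, n_periods, block_days)
  if (length(cc$cell) == 0L) stop("ego has no calls: ", ego, call. = FALSE)
  blocks <- split(seq_along(cc$cell), cc$block)
  blocks <- blocks[lengths(blocks) > 1L]
  acc <- numeric(cc$n_cells)
  alter <- cc$alter
  for (iter in seq_len(n_iter)) {
    shuffled <- alter
    for (idx in blocks) shuffled[idx] <- alter[idx][sample.int(length(idx))]
    h <- row_entropies(cell_count_matrix(cc$cell, shuffled, cc$n_cells,
                                         cc$m))
    acc <- acc + ifelse(is.na(h), 0, h)
  }
  h_ref <- acc / n_iter
  h_orig <- row_entropies(cell_count_matrix(cc$cell, alter, cc$n_cells,
                                            cc$m))
  h_ref[is.na(h_orig)] <- NA_real_
  matrix(h_ref, nrow = n_periods, byrow = TRUE,
         dimnames = list(cc$period_labels, BIN_LEVELS))
}

#' Relative entropy (origin over mean reference)
#'
#' Ratio of origin to mean reference entropy for matching (ego, period, bin)
#' cells. Values near 0 indicate strong alter-specificity (the real alter
#' diversity is far below what random alter-time assignment would give);
#' values near 1 indicate none, and values above 1 are possible. When the
#' reference entropy is essentially zero (a bin fed by one alter or a single
#' call) the ratio is numerically meaningless and `NA` is returned instead.
#'
#' @param h_orig,h_ref non-negative numerics (vectorized), `NA` allowed.
#' @param eps denominator threshold in bits below which the ratio is
#'   reported missing (default `1e-9`).
#' @return `h_orig / h_ref`, or `NA` where undefined.
#' @export
relative_entropy <- function(h_orig, h_ref, eps = 1e-9) {
  if (any(h_orig < 0, na.rm = TRUE) || any(h_ref < 0, na.rm = TRUE))
    stop("entropies must be non-negative", call. = FALSE)
  out <- ifelse(!is.na(h_ref) & h_ref > eps, h_orig / h_ref, NA_real_)
  out[is.na(h_orig)] <- NA_real_
  out
}

#' Top-2 alter fraction of a bin
#'
#' Fraction of a bin's calls going to the ego's two most-called alters in
#' that bin (ties broken lexicographically by alter id). With fewer than two
#' distinct alters the fraction is 1; an empty bin is missing.
#'
#' @param counts named non-negative vector of per-alter call counts.
#' @return List with `fraction` (in \[0, 1\] or `NA`) and `alters` (the top-2
#'   ids, possibly fewer).
#' @export
top2_fraction <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(list(fraction = NA_real_, alters = character(0)))
  ord <- order(-counts, names(counts), method = "radix")
  top <- ord[seq_len(min(2L, sum(counts > 0)))]
  top <- top[counts[top] > 0]
  list(fraction = sum(counts[top]) / total,
       alters = names(counts)[top])
}

#' Full alter-specificity profile of a dataset
#'
#' For every ego, period and 6-hour bin: call count, origin entropy, mean
#' reference entropy under the shuffling null ([reference_entropy()]),
#' relative entropy and top-2 alter fraction. One derived seed per ego keeps
#' the null-model randomness reproducible and independent across egos.
#'
#' @param ds a `cdr` object.
#' @param n_periods number of successive periods (default 3).
#' @param n_iter shuffle iterations for the reference entropy (default 1000).
#' @param block_days shuffle-block length in days (default 14).
#' @param seed integer seed.
#' @param eps missing-value threshold for [relative_entropy()].
#' @return data.frame (class `entropy_profile`) with columns `ego_id`,
#'   `period`, `bin`, `n_calls`, `h_origin`, `h_reference`, `h_relative`,
#'   `top2_fraction`, `top2_alters`.
#' @export
entropy_profile <- function(ds, n_periods = 3L, n_iter = 1000L,
                            block_days = 14L, seed = 1L, eps = 1e-9) {
  stopifnot(inherits(ds, "cdr"))
  egos <- sort(unique(ds$records$ego_id))
  periods <- split_periods(ds, n_periods)
  rows <- vector("list", length(egos))
  for (k in seq_along(egos)) {
    e <- egos[k]
    h_ref <- reference_entropy(ds, e, n_periods = n_periods,
                               n_iter = n_iter, block_days = block_days,
                               seed = derive_seed(seed, k))
    per_period <- lapply(seq_len(n_periods), function(t) {
      counts <- bin_calls(periods[[t]], e)
      data.frame(
        ego_id = e,
        period = names(periods)[t],
        bin = BIN_LEVELS,
        n_calls = vapply(counts, sum, numeric(1L)),
        h_origin = vapply(counts, origin_entropy, numeric(1L)),
        h_reference = h_ref[t, ],
        top2_fraction = vapply(counts, function(cnt)
          top2_fraction(cnt)$fraction, numeric(1L)),
        top2_alters = vapply(counts, function(cnt)
          paste(top2_fraction(cnt)$alters, collapse = ";"), character(1L)),
        stringsAsFactors = FALSE, row.names = NULL)
    })
    rows[[k]] <- do.call(rbind, per_period)
  }
  out <- do.call(rbind, rows)
  out$h_relative <- relative_entropy(out$h_origin, out$h_reference,
                                     eps = eps)
  out <- out[, c("ego_id", "period", "bin", "n_calls", "h_origin",
                 "h_reference", "h_relative", "top2_fraction",
                 "top2_alters")]
  structure(out, class = c("entropy_profile", "data.frame"),
            n_iter = n_iter, block_days = block_days, seed = seed)
}

#' Correlation between relative entropy and top-2 fraction
#'
#' Per ego, Pearson correlation between relative entropy and the top-2 alter
#' fraction over the (period, bin) cells where both are defined — a strong
#' negative correlation means that the times when an ego's calls concentrate
#' on its two favourite alters are exactly the times of low alter diversity.
#' Egos with fewer than `min_points` complete cells, or with zero variance in
#' either series, are reported as undetermined (`NA`).
#'
#' @param profile an [entropy_profile()] data.frame.
#' @param min_points minimum complete (period, bin) cells per ego
#'   (default 3).
#' @return List with `per_ego` (data.frame `ego_id`, `r`, `p_value`,
#'   `n_points`) and `population_r` (mean of the defined per-ego `r`).
#' @export
entropy_top2_correlation <- function(profile, min_points = 3L) {
  per_ego <- lapply(split(profile, profile$ego_id), function(d) {
    ok <- stats::complete.cases(d$h_relative, d$top2_fraction)
    res <- data.frame(ego_id = d$ego_id[1L], r = NA_real_,
                      p_value = NA_real_, n_points = sum(ok),
                      stringsAsFactors = FALSE)
    if (sum(ok) >= min_points &&
        stats::sd(d$h_relative[ok]) > 0 &&
        stats::sd(d$top2_fraction[ok]) > 0) {
      ct <- stats::cor.test(d$h_relative[ok], d$top2_fraction[ok],
                            method = "pearson")
      res$r <- unname(ct$estimate)
      res$p_value <- ct$p.value
    }
    res
  })
  per_ego <- do.call(rbind, c(per_ego, make.row.names = FALSE))
  list(per_ego = per_ego,
       population_r = mean(per_ego$r, na.rm = TRUE))
}

#' Average call duration by contact category and hour of day
#'
#' Mean outgoing-call duration per hour slot, separately for each of the five
#' contact categories; alters absent from the contact directory fall under
#' `"others"`. Only (category, hour) cells with at least one call appear.
#'
#' @param ds a `cdr` object with a contact directory (or `contacts`
#'   supplied).
#' @param contacts optional contact data.frame overriding `ds$contacts`.
#' @return data.frame with columns `category`, `hour`, `mean_duration`,
#'   `n_calls`.
#' @export
duration_profiles <- function(ds, contacts = ds$contacts) {
  stopifnot(inherits(ds, "cdr"))
  if (is.null(contacts))
    stop("a contact directory is required for duration profiles",
         call. = FALSE)
  contacts <- validate_contacts(contacts)
  key <- paste(ds$records$ego_id, ds$records$alter_id, sep = "\r")
  lookup <- stats::setNames(contacts$category,
                            paste(contacts$ego_id, contacts$alter_id,
                                  sep = "\r"))
  category <- unname(lookup[key])
  category[is.na(category)] <- "others"
  hour <- as.POSIXlt(ds$records$timestamp)$hour
  agg <- stats::aggregate(ds$records$duration,
                          by = list(category = category, hour = hour),
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(category = agg$category, hour = agg$hour,
                    mean_duration = agg$x[, 1L],
                    n_calls = as.integer(agg$x[, 2L]),
                    stringsAsFactors = FALSE)
  out[order(out$category, out$hour), , drop = FALSE]
}
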