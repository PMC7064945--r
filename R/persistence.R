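#' Persistence of individual circadian rhythms across periods
#'
#' Quantifies how stable each ego's hourly call pattern is over time. The
#' window is split into `n_periods` successive periods; for each ego the
#' self-distance `D_self` is the pattern dissimilarity between successive
#' periods (T1-T2, T2-T3, ...), and the reference distance `D_ref` is the
#' dissimilarity between the ego and every other ego within each period. An
#' ego's rhythm is called persistent if and only if the ratio of its average
#' self-distance to its average reference distance is below 1: it resembles
#' itself over time more than it resembles its peers.
#'
#' Egos with an empty pattern in any period are excluded (and listed in
#' attribute `"excluded"`). A two-sample Kolmogorov-Smirnov comparison of the
#' raw call-hour samples of successive periods is reported per ego as a
#' complementary stability check.
#'
#' @param ds a `cdr` object (preprocessed; outgoing calls).
#' @param metric `"sqrt_jsd"` (default) or `"l2"`.
#' @param n_periods number of successive periods (default 3).
#' @return A `persistence_result` data.frame with one row per ego: `ego_id`,
#'   `mean_self`, `mean_ref`, `ratio`, `persistent`, and KS p-values
#'   `ks_p_<Ta>_<Tb>` per successive pair. Attributes: `d_self` (matrix of
#'   per-pair self-distances), `d_ref` (list of per-ego reference-distance
#'   vectors), `metric`, `excluded`.
#' @export
persistence <- function(ds, metric = c("sqrt_jsd", "l2"), n_periods = 3L) {
  metric <- match.arg(metric)
  pats <- period_patterns(ds, n_periods)
  labels <- names(pats)
  egos <- rownames(pats[[1L]])
  nonempty <- Reduce(`&`, lapply(pats, stats::complete.cases))
  excluded <- egos[!nonempty]
  egos <- egos[nonempty]
  if (length(egos) < 2L)
    stop("persistence needs at least 2 egos with calls in every period",
         call. = FALSE)

  periods <- split_periods(ds, n_periods)
  hour_samples <- lapply(periods, function(p) {
    split(as.POSIXlt(p$records$timestamp)$hour, p$records$ego_id)
  })

  n_pairs <- n_periods - 1L
  d_self <- matrix(NA_real_, nrow = length(egos), ncol = n_pairs,
                   dimnames = list(egos, paste(labels[-n_periods],
                                               labels[-1L], sep = "_")))
  ks_p <- d_self
  d_ref <- stats::setNames(vector("list", length(egos)), egos)

  for (k in seq_along(egos)) {
    e <- egos[k]
    for (j in seq_len(n_pairs)) {
      d_self[k, j] <- pattern_distance(pats[[j]][e, ], pats[[j + 1L]][e, ],
                                       metric)
      ks_p[k, j] <- ks_compare(hour_samples[[j]][[e]],
                               hour_samples[[j + 1L]][[e]])$p.value
    }
    refs <- unlist(lapply(seq_len(n_periods), function(t) {
      others <- setdiff(egos, e)
      vapply(others, function(o)
        pattern_distance(pats[[t]][e, ], pats[[t]][o, ], metric),
        numeric(1L))
    }))
    d_ref[[e]] <- refs
  }

  mean_self <- rowMeans(d_self)
  mean_ref <- vapply(d_ref, mean, numeric(1L))
  res <- data.frame(ego_id = egos,
                    mean_self = mean_self,
                    mean_ref = mean_ref,
                    ratio = mean_self / mean_ref,
                    persistent = mean_self / mean_ref < 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  ks_df <- as.data.frame(ks_p)
  names(ks_df) <- paste0("ks_p_", colnames(d_self))
  res <- cbind(res, ks_df)
  structure(res, class = c("persistence_result", "data.frame"),
            d_self = d_self, d_ref = d_ref, metric = metric,
            excluded = excluded)
}

#' @export
print.persistence_result <- function(x, ...) {
  cat("Persistence analysis (", attr(x, "metric"), " metric, ",
      nrow(x), " egos)\n", sep = "")
  cat(sprintf("  <D_self> = %.3f (SD %.3f), <D_ref> = %.3f (SD %.3f)\n",
              mean(x$mean_self), stats::sd(x$mean_self),
              mean(x$mean_ref), stats::sd(x$mean_ref)))
  cat(sprintf("  persistent egos: %d / %d\n", sum(x$persistent), nrow(x)))
  NextMethod()
}

#' Population summary of the persistence analysis
#'
#' Mean and standard deviation of the per-ego average self- and reference-
#' distances for one or both metrics — the population-level summary table of
#' a persistence analysis.
#'
#' @param ds a `cdr` object.
#' @param metrics character vector of metrics to include.
#' @param n_periods number of periods.
#' @return data.frame with columns `metric`, `distance` (`self`/`ref`),
#'   `mean`, `sd`, `n_egos`, `persistent_fraction`.
#' @export
persistence_summary <- function(ds, metrics = c("sqrt_jsd", "l2"),
                                n_periods = 3L) {
  rows <- lapply(metrics, function(m) {
    res <- persistence(ds, metric = m, n_periods = n_periods)
    data.frame(metric = m,
               distance = c("self", "ref"),
               mean = c(mean(res$mean_self), mean(res$mean_ref)),
               sd = c(stats::sd(res$mean_self), stats::sd(res$mean_ref)),
               n_egos = nrow(res),
               persistent_fraction = mean(res$persistent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kolmogorov-Smirnov comparison of two call-hour samples
#'
#' Two-sample KS test on raw hour-of-day samples (values 0-23) from two
#' periods of one ego. Hours are discrete, so ties are inevitable and the
#' asymptotic p-value is used; it is conservative under ties.
#'
#' @param hours_a,hours_b integer/numeric vectors of call start hours.
#' @return List with elements `statistic` (the KS D) and `p.value`.
#' @export
ks_compare <- function(hours_a, hours_b) {
  if (length(hours_a) == 0L || length(hours_b) == 0L)
    stop("both hour samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(hours_a, hours_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
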