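#' @keywords internal
"_PACKAGE"

CONTACT_CATEGORIES <- c("family", "friends", "associations",
                        "health_professionals", "others")

#' Construct a CDR dataset object
#'
#' Bundles call records, an optional contact directory and the observation
#' window into a `cdr` object, the container every analysis function in the
#' package consumes. Records are validated: non-negative durations, known call
#' directions, ego distinct from alter, timestamps inside the window.
#'
#' @param records data.frame with columns `ego_id`, `alter_id`, `timestamp`
#'   (POSIXct, or a string parsable as ISO-8601), `direction`
#'   (`"outgoing"`/`"incoming"`) and `duration` (seconds, >= 0).
#' @param contacts optional data.frame with columns `ego_id`, `alter_id`,
#'   `category`; categories are matched case-insensitively against
#'   `r paste(CONTACT_CATEGORIES, collapse = ", ")`.
#' @param window length-2 Date vector (closed interval). Defaults to the date
#'   range of `records`.
#' @return A `cdr` object: list with elements `records`, `contacts`, `window`
#'   and `n_egos`.
#' @seealso [read_cdr()], [select_outgoing()], [filter_active_egos()]
#' @export
cdr_dataset <- function(records, contacts = NULL, window = NULL) {
  required <- c("ego_id", "alter_id", "timestamp", "direction", "duration")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records$ego_id <- as.character(records$ego_id)
  records$alter_id <- as.character(records$alter_id)
  if (!inherits(records$timestamp, "POSIXct"))
    records$timestamp <- as.POSIXct(records$timestamp, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%S")
  records$direction <- tolower(as.character(records$direction))
  records$duration <- as.numeric(records$duration)

  bad <- is.na(records$timestamp) | is.na(records$duration) |
    records$duration < 0 |
    !(records$direction %in% c("outgoing", "incoming")) |
    records$ego_id == records$alter_id
  if (any(bad)) stop(sum(bad), " invalid record(s); use read_cdr() to parse ",
                     "files with malformed rows", call. = FALSE)

  if (is.null(window)) {
    window <- if (nrow(records) > 0L)
      range(as.Date(records$timestamp, tz = "UTC")) else
      as.Date(c("1970-01-01", "1970-01-01"))
  }
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[2L] < window[1L])
    stop("window must be two ordered dates", call. = FALSE)
  dates <- as.Date(records$timestamp, tz = "UTC")
  if (nrow(records) > 0L && (any(dates < window[1L]) || any(dates > window[2L])))
    stop("records fall outside the observation window", call. = FALSE)

  if (!is.null(contacts)) contacts <- validate_contacts(contacts)

  structure(
    list(records = records[order(records$timestamp), , drop = FALSE],
         contacts = contacts,
         window = window,
         n_egos = length(unique(records$ego_id))),
    class = "cdr")
}

validate_contacts <- function(contacts) {
  required <- c("ego_id", "alter_id", "category")
  missing_cols <- setdiff(required, names(contacts))
  if (length(missing_cols) > 0L)
    stop("contacts is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  contacts$ego_id <- as.character(contacts$ego_id)
  contacts$alter_id <- as.character(contacts$alter_id)
  cat_raw <- tolower(trimws(as.character(contacts$category)))
  # accept a few spelling variants seen in questionnaire exports
  cat_raw[cat_raw %in% c("friend")] <- "friends"
  cat_raw[cat_raw %in% c("association")] <- "associations"
  cat_raw[cat_raw %in% c("health care professionals", "health professionals",
                         "health_care_professionals",
                         "health care professional")] <- "health_professionals"
  cat_raw[cat_raw %in% c("other")] <- "others"
  unknown <- setdiff(unique(cat_raw), CONTACT_CATEGORIES)
  if (length(unknown) > 0L)
    stop("unknown contact category value(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  contacts$category <- cat_raw
  key <- paste(contacts$ego_id, contacts$alter_id, sep = "\r")
  if (anyDuplicated(key))
    stop("each (ego, alter) pair must map to exactly one category",
         call. = FALSE)
  contacts
}

#' @export
print.cdr <- function(x, ...) {
  cat("CDR dataset:", nrow(x$records), "call records,",
      x$n_egos, "egos\n")
  cat("  window:", format(x$window[1L]), "to", format(x$window[2L]), "\n")
  dirs <- table(factor(x$records$direction,
                       levels = c("outgoing", "incoming")))
  cat("  direction: ", dirs[["outgoing"]], " outgoing / ",
      dirs[["incoming"]], " incoming\n", sep = "")
  if (!is.null(x$contacts))
    cat("  contact directory:", nrow(x$contacts), "entries\n")
  invisible(x)
}

#' Read call-detail records from a delimited text file
#'
#' Parses a CSV of call records into a [cdr_dataset()]. Column names are
#' resolved through `dialect`, so operator exports with different headers can
#' be read without renaming. Malformed rows (unparsable timestamp, negative
#' duration, unknown direction, ego equal to alter) are dropped and counted;
#' the count is attached as attribute `"rejected"` and reported via a message.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector mapping the canonical fields
#'   `ego_id`, `alter_id`, `timestamp`, `direction`, `duration` to the file's
#'   column names; see [cdr_dialect()].
#' @param contacts optional path to a contacts CSV (`ego_id`, `alter_id`,
#'   `category`) or a data.frame.
#' @param sep field separator, default comma.
#' @return A `cdr` object with attribute `rejected` (number of dropped rows).
#' @export
read_cdr <- function(path, dialect = cdr_dialect(), contacts = NULL,
                     sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (field in c("ego_id", "alter_id", "timestamp", "direction", "duration")) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(raw)))
      stop("required column '", field, "' (mapped to '", col,
           "') not found in ", path, call. = FALSE)
  }
  df <- data.frame(ego_id = raw[[dialect[["ego_id"]]]],
                   alter_id = raw[[dialect[["alter_id"]]]],
                   timestamp = as.POSIXct(raw[[dialect[["timestamp"]]]],
                                          tz = "UTC",
                                          format = "%Y-%m-%dT%H:%M:%S"),
                   direction = tolower(raw[[dialect[["direction"]]]]),
                   duration = suppressWarnings(
                     as.numeric(raw[[dialect[["duration"]]]])),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$timestamp) | is.na(df$duration) | df$duration < 0 |
    !(df$direction %in% c("outgoing", "incoming")) |
    df$ego_id == df$alter_id
  n_rejected <- sum(bad)
  if (n_rejected > 0L)
    message("read_cdr: rejected ", n_rejected, " malformed row(s)")
  if (is.character(contacts)) contacts <- utils::read.csv(
    contacts, stringsAsFactors = FALSE)
  ds <- cdr_dataset(df[!bad, , drop = FALSE], contacts = contacts)
  attr(ds, "rejected") <- n_rejected
  ds
}

#' Default column mapping for CDR files
#'
#' @param ego_id,alter_id,timestamp,direction,duration column names in the
#'   file for each canonical field.
#' @return Named character vector usable as the `dialect` of [read_cdr()].
#' @export
cdr_dialect <- function(ego_id = "ego_id", alter_id = "alter_id",
                        timestamp = "timestamp", direction = "direction",
                        duration = "duration_s") {
  c(ego_id = ego_id, alter_id = alter_id, timestamp = timestamp,
    direction = direction, duration = duration)
}

#' Write call-detail records to CSV
#'
#' Inverse of [read_cdr()] under the same dialect: timestamps are written as
#' ISO-8601 and durations under the column name the dialect maps to.
#'
#' @param ds a `cdr` object.
#' @param path output file path.
#' @param dialect column mapping, see [cdr_dialect()].
#' @return `path`, invisibly.
#' @export
write_cdr <- function(ds, path, dialect = cdr_dialect()) {
  stopifnot(inherits(ds, "cdr"))
  out <- data.frame(
    ds$records$ego_id, ds$records$alter_id,
    format(ds$records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    ds$records$direction, ds$records$duration,
    stringsAsFactors = FALSE)
  names(out) <- dialect[c("ego_id", "alter_id", "timestamp", "direction",
                          "duration")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subset a cdr by a logical/integer index on records, keeping metadata
subset_cdr <- function(ds, idx, window = ds$window) {
  structure(
    list(records = ds$records[idx, , drop = FALSE],
         contacts = ds$contacts,
         window = as.Date(window),
         n_egos = length(unique(ds$records$ego_id[idx]))),
    class = "cdr")
}
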