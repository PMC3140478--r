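#' Behavioural event logs
#'
#' An event log is the tidy record of one group's observation data: scan
#' samples (nearest-neighbour records taken at fixed intervals) and
#' all-occurrence behavioural bouts (allogrooming, contact sitting, play,
#' aggression, submission and cooperation attempts at the feeders). Each
#' record carries a timestamp, the individuals involved, and where relevant
#' the nearest-neighbour distance and the distance from the feeders.
#' Records are bucketed into sampling periods, one per calendar day by
#' default.
#'
#' @name event_log
NULL

EVENT_BEHAVIOURS <- c("proximity", "allogroom", "contact_sit", "play",
                      "aggression", "submission", "coop_attempt")
AFFILIATIVE_BEHAVIOURS <- c("allogroom", "contact_sit", "play")

#' Construct an event log from a data.frame
#'
#' @param x a data.frame with columns \code{timestamp} (ISO-8601 datetime),
#'   \code{kind} (\code{"scan"} or \code{"bout"}), \code{behaviour},
#'   \code{actor}, \code{recipient} (may be empty for solo scans),
#'   \code{neighbour_distance_m} and \code{feeder_distance_m} (may be empty;
#'   an empty feeder distance means no feeders were present).
#' @param roster optional \code{vnet_roster}; ids not on the roster are
#'   reported and their records dropped.
#' @param period one of \code{"day"} (default) or \code{"none"}; how
#'   timestamps are bucketed into sampling periods.
#' @return a \code{vnet_event_log} data.frame with added columns
#'   \code{date}, \code{time_s} (seconds from local midnight) and
#'   \code{sampling_period} (1-based day index).
#' @export
as_event_log <- function(x, roster = NULL, period = c("day", "none")) {
  period <- match.arg(period)
  stopifnot(is.data.frame(x))
  needed <- c("timestamp", "kind", "behaviour", "actor", "recipient")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("event log is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("neighbour_distance_m", "feeder_distance_m")) {
    if (is.null(x[[col]])) x[[col]] <- NA_real_
    x[[col]] <- as.numeric(x[[col]])
  }
  x$actor <- as.character(x$actor)
  x$recipient <- as.character(x$recipient)
  x$recipient[!is.na(x$recipient) & !nzchar(x$recipient)] <- NA_character_

  same <- !is.na(x$recipient) & x$actor == x$recipient
  if (any(same)) {
    stop("actor equals recipient on line(s): ",
         paste(which(same), collapse = ", "))
  }
  bad_kind <- !x$kind %in% c("scan", "bout")
  if (any(bad_kind)) stop("invalid kind value(s): ",
                          paste(unique(x$kind[bad_kind]), collapse = ", "))
  bad_beh <- !x$behaviour %in% EVENT_BEHAVIOURS
  if (any(bad_beh)) stop("invalid behaviour value(s): ",
                         paste(unique(x$behaviour[bad_beh]), collapse = ", "))

  ts <- as.POSIXct(x$timestamp, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamp on line(s): ",
                      paste(which(is.na(ts)), collapse = ", "))
  x$date <- as.Date(ts)
  x$time_s <- as.numeric(ts) - as.numeric(as.POSIXct(paste(x$date, "00:00:00"),
                                                     tz = "UTC"))
  if (period == "day") {
    days <- sort(unique(x$date))
    x$sampling_period <- match(x$date, days)
  } else {
    x$sampling_period <- 1L
  }
  # timestamps must be non-decreasing within a day (one observer's stream)
  ord <- order(x$sampling_period, x$time_s)
  x <- x[ord, , drop = FALSE]

  if (!is.null(roster)) {
    known <- roster$id
    ids <- unique(c(x$actor, x$recipient[!is.na(x$recipient)]))
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      message("dropping records for ", length(unknown),
              " id(s) not on roster: ", paste(unknown, collapse = ", "))
      keep <- x$actor %in% known &
        (is.na(x$recipient) | x$recipient %in% known)
      x <- x[keep, , drop = FALSE]
    }
  }
  rownames(x) <- NULL
  class(x) <- c("vnet_event_log", "data.frame")
  x
}

#' Read an event log from CSV
#'
#' @inheritParams as_event_log
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a \code{vnet_event_log}, see [as_event_log()].
#' @export
read_event_log <- function(path, roster = NULL, period = c("day", "none")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(timestamp = "character"))
  as_event_log(x, roster = roster, period = period)
}

#' Write an event log to CSV
#'
#' @param log a \code{vnet_event_log}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_event_log <- function(log, path) {
  keep <- c("timestamp", "kind", "behaviour", "actor", "recipient",
            "neighbour_distance_m", "feeder_distance_m")
  utils::write.csv(as.data.frame(log)[, keep], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Segment a continuous observation stream into behavioural bouts
#'
#' A bout is a maximal run of observations of the same behaviour between
#' the same actor and recipient in which consecutive observations are less
#' than \code{gap_s} seconds apart. A silence of \code{gap_s} seconds or
#' more, a change of behaviour, or a partner exchange ends the bout and
#' any further observation starts a new one. Each bout keeps its starting
#' time, so downstream analyses work with bout frequencies, not durations.
#'
#' @param stream a data.frame from one observer with columns \code{time_s}
#'   (seconds, sorted non-decreasing within each day), \code{behaviour},
#'   \code{actor}, \code{recipient}, and optionally \code{date},
#'   \code{feeder_distance_m}, \code{sampling_period}.
#' @param gap_s gap (seconds) at or beyond which a bout is considered
#'   ended; 5 by default.
#' @return a data.frame of bouts, one row per bout, carrying the start
#'   time and the grouping columns of the first observation of the bout.
#' @export
segment_bouts <- function(stream, gap_s = 5) {
  stopifnot(is.data.frame(stream), gap_s > 0)
  needed <- c("time_s", "behaviour", "actor", "recipient")
  missing_cols <- setdiff(needed, names(stream))
  if (length(missing_cols)) {
    stop("stream is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(stream) == 0) return(stream)
  day <- if (!is.null(stream$date)) as.character(stream$date)
         else rep("", nrow(stream))
  if (is.unsorted(order(day, stream$time_s))) {
    stop("stream is not time-sorted within days")
  }
  n <- nrow(stream)
  rec <- ifelse(is.na(stream$recipient), "", stream$recipient)
  new_bout <- c(TRUE, day[-1] != day[-n] |
                  stream$behaviour[-1] != stream$behaviour[-n] |
                  stream$actor[-1] != stream$actor[-n] |
                  rec[-1] != rec[-n] |
                  (stream$time_s[-1] - stream$time_s[-n]) >= gap_s)
  out <- stream[new_bout, , drop = FALSE]
  rownames(out) <- NULL
  out
}
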