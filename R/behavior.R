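#' Parse a behavioral event log into state intervals
#'
#' Reads an event-scoring log of `(timestamp_s, code)` rows, where each code
#' opens or closes a named behavioral state (`open:<state>` /
#' `close:<state>`, as written by event-scoring software exports adapted to
#' this schema). States left open at the end of the trial are closed at
#' `span_s` with a warning.
#'
#' @param path CSV file with columns `timestamp_s`, `code`, or a data.frame
#'   of the same shape.
#' @param span_s Trial span used to close dangling states (seconds).
#' @return data.frame with `behavior`, `start_s`, `end_s` (half-open
#'   intervals, sorted by start).
#' @export
parse_event_log <- function(path, span_s) {
  log <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("timestamp_s", "code") %in% names(log))) {
    stop("event log needs columns timestamp_s, code")
  }
  empty <- data.frame(behavior = character(0), start_s = numeric(0),
                      end_s = numeric(0))
  if (nrow(log) == 0) return(empty)
  if (is.unsorted(log$timestamp_s)) {
    stop("event log timestamps must be non-decreasing")
  }
  ok <- grepl("^(open|close):.+$", log$code)
  if (any(!ok)) {
    stop("unknown event code(s): ",
         paste(unique(log$code[!ok]), collapse = ", "))
  }
  action <- sub(":.*$", "", log$code)
  state <- sub("^[a-z]+:", "", log$code)
  open_at <- list()
  rows <- list()
  for (i in seq_len(nrow(log))) {
    s <- state[i]
    if (action[i] == "open") {
      if (!is.null(open_at[[s]])) {
        stop("state '", s, "' opened twice at ", log$timestamp_s[i])
      }
      open_at[[s]] <- log$timestamp_s[i]
    } else {
      if (is.null(open_at[[s]])) {
        stop("state '", s, "' closed at ", log$timestamp_s[i],
             " without being open")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        behavior = s, start_s = open_at[[s]], end_s = log$timestamp_s[i])
      open_at[[s]] <- NULL
    }
  }
  for (s in names(open_at)) {
    if (!is.null(open_at[[s]])) {
      warning("state '", s, "' never closed; closed at trial end (",
              span_s, " s)")
      rows[[length(rows) + 1L]] <- data.frame(
        behavior = s, start_s = open_at[[s]], end_s = span_s)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[out$end_s > out$start_s, , drop = FALSE][order(out$start_s), ]
}

#' Social preference ratio
#'
#' `(time on partner side - time on stranger side) /
#'  (time on partner side + time on stranger side)`, bounded in `[-1, 1]`.
#' Undefined (NA, flagged) when the subject spent no time on either side.
#'
#' @param trial A `preference_trial` (see [generate_preference_trial()]) or
#'   any list/data.frame row with `time_partner_side_s`,
#'   `time_stranger_side_s` and the side-by-side fields.
#' @return data.frame with `subject_id`, `arm`, side and side-by-side times,
#'   `ratio`, `undefined`.
#' @export
#' @examples
#' preference_ratio(list(subject_id = "s1", arm = "mCherry_saline",
#'   time_partner_side_s = 150, time_stranger_side_s = 50,
#'   side_by_side_partner_s = 60, side_by_side_stranger_s = 10))$ratio  # 0.5
preference_ratio <- function(trial) {
  p <- trial$time_partner_side_s
  s <- trial$time_stranger_side_s
  if (any(c(p, s) < 0)) stop("side times must be non-negative")
  tot <- p + s
  data.frame(
    subject_id = trial$subject_id %||% NA_character_,
    arm = trial$arm %||% NA_character_,
    time_partner_side_s = p,
    time_stranger_side_s = s,
    side_by_side_partner_s = trial$side_by_side_partner_s %||% NA_real_,
    side_by_side_stranger_s = trial$side_by_side_stranger_s %||% NA_real_,
    ratio = ifelse(tot > 0, (p - s) / tot, NA_real_),
    undefined = tot <= 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total duration per behavioral state
#'
#' Interval-union length per behavior, so overlapping annotations of the
#' same state are not double counted.
#'
#' @param bouts data.frame with `behavior`, `start_s`, `end_s`.
#' @return Named numeric vector of seconds per behavior.
#' @export
state_durations <- function(bouts) {
  vapply(split(bouts, bouts$behavior), function(b) {
    b <- b[order(b$start_s), ]
    tot <- 0
    cur_s <- NA_real_
    cur_e <- NA_real_
    for (i in seq_len(nrow(b))) {
      if (is.na(cur_s)) {
        cur_s <- b$start_s[i]
        cur_e <- b$end_s[i]
      } else if (b$start_s[i] > cur_e) {
        tot <- tot + cur_e - cur_s
        cur_s <- b$start_s[i]
        cur_e <- b$end_s[i]
      } else {
        cur_e <- max(cur_e, b$end_s[i])
      }
    }
    if (!is.na(cur_s)) tot <- tot + cur_e - cur_s
    tot
  }, numeric(1))
}
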