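#' Impute missing epochs by a centred moving median
#'
#' Replaces every missing epoch with the median of the observed values inside
#' a centred window of `window_minutes` epochs around it (the window is
#' truncated at the ends of the recording). Observed values are never
#' altered; the imputation is a no-op on a complete series. If every
#' neighbour inside the window is itself missing, the nearest observed value
#' is used instead, so the operation is total for the ~1% gap rates typical
#' of week-long wrist recordings.
#'
#' @param series An [epoch_series()].
#' @param window_minutes Window length in epochs (default 30); for even
#'   lengths the window extends one epoch further into the past.
#' @return An [epoch_series()] with no missing values.
#' @export
impute_moving_median <- function(series, window_minutes = 30L) {
  stopifnot(inherits(series, "epoch_series"), window_minutes >= 1)
  counts <- series$counts
  if (all(is.na(counts))) {
    stop("cannot impute an all-missing series", call. = FALSE)
  }
  miss <- which(is.na(counts))
  if (length(miss) == 0L) {
    return(series)
  }
  n <- length(counts)
  half_lo <- ceiling((window_minutes - 1) / 2)
  half_hi <- floor((window_minutes - 1) / 2)
  obs_idx <- which(!is.na(counts))
  filled <- counts
  for (i in miss) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    neighbours <- counts[lo:hi]
    if (all(is.na(neighbours))) {
      nearest <- obs_idx[which.min(abs(obs_idx - i))]
      filled[i] <- counts[nearest]
    } else {
      filled[i] <- stats::median(neighbours, na.rm = TRUE)
    }
  }
  epoch_series(series$subject_id, series$group, series$times, filled)
}

#' One complete daytime day
#'
#' @param subject_id Subject identifier.
#' @param date Calendar `Date` of the day.
#' @param counts Numeric vector of exactly 840 non-missing counts, one per
#'   minute of the daytime window.
#' @return A list of class `daytime_day` with `subject_id`, `date`,
#'   `day_type` (`"weekend"` iff the date is a Saturday or Sunday, else
#'   `"weekday"`) and `counts`.
#' @export
daytime_day <- function(subject_id, date, counts) {
  stopifnot(inherits(date, "Date"), length(counts) == DAY_MINUTES,
            !anyNA(counts), all(counts >= 0))
  wd <- format(date, "%u") # ISO weekday, 6 = Sat, 7 = Sun
  structure(
    list(
      subject_id = subject_id, date = date,
      day_type = if (wd %in% c("6", "7")) "weekend" else "weekday",
      counts = as.numeric(counts)
    ),
    class = "daytime_day"
  )
}

#' @export
print.daytime_day <- function(x, ...) {
  cat(sprintf("<daytime_day> %s %s (%s): 840 epochs, mean %.1f cpm\n",
              x$subject_id, format(x$date), x$day_type, mean(x$counts)))
  invisible(x)
}

parse_clock_minutes <- function(clock) {
  parts <- as.integer(strsplit(clock, ":", fixed = TRUE)[[1L]])
  stopifnot(length(parts) == 2L)
  parts[1L] * 60L + parts[2L]
}

#' Carve an imputed series into complete daytime days
#'
#' Splits a gap-free epoch series into calendar days and keeps, for each day,
#' the half-open wall-clock window `[start, end)` (defaults 08:00-22:00, i.e.
#' exactly 840 one-minute epochs). Days whose window is only partially
#' covered by the recording are dropped; their dates are attached as the
#' `"dropped"` attribute so callers can log them.
#'
#' @param series An [epoch_series()] with no missing values (run
#'   [impute_moving_median()] first).
#' @param start,end Window bounds as `"HH:MM"` wall-clock strings.
#' @return A list of [daytime_day()] objects, ordered by date.
#' @export
carve_daytime_days <- function(series, start = DEFAULT_WINDOW_START,
                               end = DEFAULT_WINDOW_END) {
  stopifnot(inherits(series, "epoch_series"))
  if (anyNA(series$counts)) {
    stop("series still contains missing epochs; impute before carving",
         call. = FALSE)
  }
  start_min <- parse_clock_minutes(start)
  end_min <- parse_clock_minutes(end)
  stopifnot(start_min < end_min)
  width <- end_min - start_min
  if (width != DAY_MINUTES) {
    stop(sprintf("daytime window must span exactly %d minutes, got %d",
                 DAY_MINUTES, width), call. = FALSE)
  }

  # wall-clock arithmetic: timestamps are stored as UTC-encoded wall time,
  # so minute-of-day and calendar date fall out of integer division
  secs <- as.numeric(series$times)
  minute_of_day <- as.integer((secs %/% 60) %% 1440)
  date <- as.Date(floor(secs / 86400), origin = "1970-01-01")
  in_window <- minute_of_day >= start_min & minute_of_day < end_min

  days <- list()
  dropped <- as.Date(character())
  for (d in split(which(in_window), date[in_window])) {
    this_date <- date[d[1L]]
    if (length(d) == width) {
      days[[length(days) + 1L]] <-
        daytime_day(series$subject_id, this_date, series$counts[d])
    } else {
      dropped <- c(dropped, this_date)
    }
  }
  structure(days, dropped = dropped)
}
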