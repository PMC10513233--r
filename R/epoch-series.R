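#' Per-minute actigraphy series for one subject
#'
#' An `epoch_series` holds one subject's activity-count signal: a strictly
#' increasing run of timestamps at exact 1-minute spacing and one non-negative
#' integer count per epoch. Epochs absent from the source are stored as `NA`
#' and exposed through the missingness mask; all other values are observed
#' device output.
#'
#' @param subject_id Single string identifying the subject.
#' @param group Group label, `"AI"` (acute insomnia) or `"HC"` (healthy
#'   control).
#' @param times `POSIXct` vector of epoch start times, strictly increasing at
#'   60-second spacing.
#' @param counts Numeric vector of activity counts per minute (cpm), same
#'   length as `times`; `NA` marks a missing epoch, observed values must be
#'   non-negative.
#'
#' @return An object of class `epoch_series`: a list with elements
#'   `subject_id`, `group`, `times`, `counts`.
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-01-01 08:00", tz = "UTC")
#' es <- epoch_series("s1", "HC", t0 + 60 * (0:4), c(10, NA, 30, 0, 250))
#' missing_mask(es)
epoch_series <- function(subject_id, group, times, counts) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  group <- match.arg(group, c("AI", "HC"))
  if (!inherits(times, "POSIXct")) {
    stop("`times` must be POSIXct", call. = FALSE)
  }
  if (length(times) != length(counts)) {
    stop("`times` and `counts` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("an epoch series must contain at least one epoch", call. = FALSE)
  }
  if (length(times) > 1L) {
    dt <- as.numeric(diff(times), units = "secs")
    if (any(dt <= 0)) {
      stop("epoch timestamps must be strictly increasing", call. = FALSE)
    }
    if (any(abs(dt - 60) > 1e-6)) {
      bad <- which(abs(dt - 60) > 1e-6)[1L]
      stop(sprintf(
        "epoch spacing must be exactly 60 s; found %.0f s between epochs %d and %d",
        dt[bad], bad, bad + 1L
      ), call. = FALSE)
    }
  }
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("activity counts must be non-negative", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, group = group, times = times,
         counts = counts),
    class = "epoch_series"
  )
}

#' @rdname epoch_series
#' @param x An `epoch_series`.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "epoch_series"))
  is.na(x$counts)
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf(
    "<epoch_series> subject %s (%s): %d one-minute epochs\n  %s .. %s\n  missing: %d (%.2f%%)\n",
    x$subject_id, x$group, n,
    format(x$times[1L], "%Y-%m-%d %H:%M"),
    format(x$times[n], "%Y-%m-%d %H:%M"),
    sum(is.na(x$counts)), 100 * mean(is.na(x$counts))
  ))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' @export
as_tibble.epoch_series <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, group = x$group,
    timestamp = x$times, count = x$counts
  )
}
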