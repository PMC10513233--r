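#' Epoch CSV dialect
#'
#' Describes the column names and timestamp format of an epoch-level CSV so
#' that layouts produced by different export tools can be mapped onto the
#' canonical reader. The canonical interchange format used throughout the
#' package is a header row `timestamp,count` with ISO-8601 timestamps at
#' minute precision (`2024-01-01T08:00`) and integer counts, an empty field
#' marking a missing epoch.
#'
#' @param timestamp_col Name of the timestamp column.
#' @param count_col Name of the activity-count column.
#' @param ts_format `strptime()` format string for timestamps.
#' @return A list of class `epoch_dialect`.
#' @export
epoch_dialect <- function(timestamp_col = "timestamp", count_col = "count",
                          ts_format = "%Y-%m-%dT%H:%M") {
  structure(
    list(timestamp_col = timestamp_col, count_col = count_col,
         ts_format = ts_format),
    class = "epoch_dialect"
  )
}

#' Read a per-minute epoch CSV
#'
#' Parses one subject's epoch-level file into an [epoch_series()]. Rows whose
#' count field is empty or `NA` become missing epochs; timestamps must parse
#' under the dialect's format, be strictly increasing, and sit at exact
#' 1-minute spacing. Both Unix and Windows line endings are accepted.
#'
#' @param path Path to the CSV file.
#' @param dialect An [epoch_dialect()].
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param group Group label (`"AI"` or `"HC"`).
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, dialect = epoch_dialect(),
                           subject_id = NULL, group = "HC") {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  for (col in c(dialect$timestamp_col, dialect$count_col)) {
    if (!col %in% names(raw)) {
      stop(sprintf("epoch CSV %s lacks required column '%s'", path, col),
           call. = FALSE)
    }
  }
  ts_raw <- raw[[dialect$timestamp_col]]
  times <- as.POSIXct(ts_raw, format = dialect$ts_format, tz = "UTC")
  if (anyNA(times)) {
    bad <- which(is.na(times))[1L]
    stop(sprintf(
      "malformed timestamp '%s' at line %d of %s (expected format %s)",
      ts_raw[bad], bad + 1L, path, dialect$ts_format
    ), call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop(sprintf("timestamps in %s are not strictly increasing", path),
         call. = FALSE)
  }
  cnt_raw <- trimws(raw[[dialect$count_col]])
  missing <- is.na(cnt_raw) | cnt_raw == ""
  counts <- rep(NA_real_, length(cnt_raw))
  parsed <- suppressWarnings(as.numeric(cnt_raw[!missing]))
  if (anyNA(parsed)) {
    bad <- which(!missing)[which(is.na(parsed))[1L]]
    stop(sprintf("non-numeric count '%s' at line %d of %s",
                 cnt_raw[bad], bad + 1L, path), call. = FALSE)
  }
  if (any(parsed < 0)) {
    bad <- which(!missing)[which(parsed < 0)[1L]]
    stop(sprintf("negative count at line %d of %s", bad + 1L, path),
         call. = FALSE)
  }
  counts[!missing] <- parsed
  epoch_series(subject_id, group, times, counts)
}

#' Write a per-minute epoch CSV
#'
#' Inverse of [read_epoch_csv()]: emits the canonical `timestamp,count`
#' layout (UTF-8, Unix line endings), missing epochs as empty count fields.
#' `read_epoch_csv(write_epoch_csv(x))` reproduces counts, mask and
#' minute-precision timestamps exactly.
#'
#' @param x An [epoch_series()].
#' @param path Output file path.
#' @param dialect An [epoch_dialect()].
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(x, path, dialect = epoch_dialect()) {
  stopifnot(inherits(x, "epoch_series"))
  ts <- format(x$times, dialect$ts_format, tz = "UTC")
  cnt <- ifelse(is.na(x$counts), "",
                format(x$counts, scientific = FALSE, trim = TRUE))
  lines <- c(
    paste(dialect$timestamp_col, dialect$count_col, sep = ","),
    paste(ts, cnt, sep = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and write the subject manifest
#'
#' The manifest is a CSV with columns
#' `subject_id,group,age,sex,n_days,file`: one row per subject, `group` in
#' \{AI, HC\}, `sex` in \{male, female, unknown\}, and `file` the path of the
#' subject's epoch CSV relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with one row per subject.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      n_days = readr::col_integer(),
      file = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  bad <- setdiff(unique(m$group), c("AI", "HC"))
  if (length(bad) > 0) {
    stop(sprintf("manifest %s has unknown group label(s): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(m$age < 0, na.rm = TRUE)) {
    stop("manifest ages must be non-negative", call. = FALSE)
  }
  if (any(m$n_days < 1, na.rm = TRUE)) {
    stop("manifest n_days must be >= 1", call. = FALSE)
  }
  m
}

#' @rdname read_manifest
#' @param manifest Tibble/data frame of subject records.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, eol = "\n")
  invisible(path)
}

#' Filter subject records to an age band
#'
#' Keeps subjects with `min_age <= age <= max_age` (both bounds inclusive),
#' preserving order. The default band [20, 40] is the age-balancing window
#' typically used when the groups being compared have no older participants.
#'
#' @param records Data frame of subject records with an `age` column.
#' @param min_age,max_age Inclusive age bounds in years.
#' @return The filtered records, order preserved.
#' @export
#' @examples
#' recs <- tibble::tibble(subject_id = letters[1:4], age = c(19, 20, 40, 41))
#' filter_cohort(recs)$age
filter_cohort <- function(records, min_age = 20, max_age = 40) {
  stopifnot(min_age <= max_age)
  records[records$age >= min_age & records$age <= max_age, , drop = FALSE]
}
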