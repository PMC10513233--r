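#' Sedentary bout-duration bin scheme
#'
#' The standard duration classes for daytime sedentary bouts: short (1-3 and
#' 4-5 min), medium (6-30 and 31-60 min) and long (>60 min). Bounds are
#' inclusive integer minutes; the bins partition the positive integers.
#'
#' @param lower Integer lower bounds of the bins.
#' @param upper Integer upper bounds (`Inf` for the open-ended last bin).
#' @param labels Column-name labels, one per bin.
#' @return A list of class `bin_scheme`.
#' @export
bin_scheme <- function(lower = c(1L, 4L, 6L, 31L, 61L),
                       upper = c(3L, 5L, 30L, 60L, Inf),
                       labels = c("sed_bouts_1_3", "sed_bouts_4_5",
                                  "sed_bouts_6_30", "sed_bouts_31_60",
                                  "sed_bouts_gt60")) {
  stopifnot(length(lower) == length(upper),
            length(labels) == length(lower),
            all(lower <= upper),
            lower[1L] == 1L,
            all(lower[-1L] == head(upper, -1L) + 1L),
            is.infinite(tail(upper, 1L)))
  structure(list(lower = lower, upper = upper, labels = labels),
            class = "bin_scheme")
}

#' Classify epochs as sedentary
#'
#' An epoch is sedentary when its activity count is strictly below the
#' cut-point (default 100 cpm, the conventional accelerometer threshold for
#' sedentary behaviour); a count equal to the cut-point is active.
#'
#' @param counts Non-negative counts, no missing values.
#' @param threshold Sedentary cut-point in cpm.
#' @return Logical vector, `TRUE` = sedentary.
#' @export
#' @examples
#' classify_sedentary(c(0, 99, 100, 250))
classify_sedentary <- function(counts, threshold = DEFAULT_THRESHOLD_CPM) {
  stopifnot(!anyNA(counts), all(counts >= 0))
  counts < threshold
}

#' Extract maximal bouts by run-length encoding
#'
#' Segments a sedentary/active mask into maximal runs of equal state. The
#' runs tile the day: durations sum to the day length, and consecutive bouts
#' alternate state. Bouts touching the day boundary are reported at their
#' observed (possibly truncated) duration.
#'
#' @param mask Logical vector, `TRUE` = sedentary.
#' @return A tibble with columns `start_index` (0-based minute offset),
#'   `duration` (minutes) and `state` (`"sedentary"` or `"active"`).
#' @export
extract_bouts <- function(mask) {
  stopifnot(is.logical(mask), !anyNA(mask), length(mask) >= 1L)
  r <- rle(mask)
  len <- r$lengths
  tibble::tibble(
    start_index = cumsum(c(0L, head(len, -1L))),
    duration = as.integer(len),
    state = ifelse(r$values, "sedentary", "active")
  )
}

#' Bin sedentary bout durations
#'
#' Each sedentary bout contributes its full duration to exactly one duration
#' bin; active bouts are ignored.
#'
#' @param bouts Tibble from [extract_bouts()].
#' @param scheme A [bin_scheme()].
#' @return A list with `time` (minutes per bin) and `count` (bouts per bin),
#'   both named by the scheme labels.
#' @export
bin_sedentary_time <- function(bouts, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  dur <- bouts$duration[bouts$state == "sedentary"]
  k <- length(scheme$lower)
  time <- numeric(k)
  count <- integer(k)
  for (b in seq_len(k)) {
    in_bin <- dur >= scheme$lower[b] & dur <= scheme$upper[b]
    time[b] <- sum(dur[in_bin])
    count[b] <- sum(in_bin)
  }
  list(time = setNames(time, scheme$labels),
       count = setNames(count, scheme$labels))
}

TWO_HOUR_SLOTS <- c("h08_10", "h10_12", "h12_14", "h14_16", "h16_18",
                    "h18_20", "h20_22")

two_hour_slot_labels <- function() TWO_HOUR_SLOTS

#' Summarize one daytime day
#'
#' Computes the full per-day sedentary/active accounting: time and bout
#' counts per duration bin, total sedentary (`sed_total`) and total active
#' (`wake_total`) minutes, and the seven 2-hour slot aggregates (sedentary /
#' active minutes and mean cpm per slot; a slot mean is `NA` when the slot
#' has no epochs of that state). On every complete day
#' `sed_total + wake_total = 840` and the five bin times sum to `sed_total`.
#'
#' @param day A [daytime_day()].
#' @param threshold Sedentary cut-point in cpm.
#' @param scheme A [bin_scheme()].
#' @return A one-row tibble.
#' @export
summarize_day <- function(day, threshold = DEFAULT_THRESHOLD_CPM,
                          scheme = bin_scheme()) {
  stopifnot(inherits(day, "daytime_day"))
  counts <- day$counts
  sed <- classify_sedentary(counts, threshold)
  bouts <- extract_bouts(sed)
  bins <- bin_sedentary_time(bouts, scheme)

  slot <- rep(seq_len(7L), each = 120L)
  slot_stat <- function(keep) {
    time <- tabulate(slot[keep], nbins = 7L)
    sums <- numeric(7L)
    if (any(keep)) {
      rs <- rowsum(counts[keep], slot[keep])
      sums[as.integer(rownames(rs))] <- rs[, 1L]
    }
    list(time = as.numeric(time),
         mean = ifelse(time > 0, sums / time, NA_real_))
  }
  s_sed <- slot_stat(sed)
  s_act <- slot_stat(!sed)
  slots <- two_hour_slot_labels()

  vals <- c(
    list(subject_id = day$subject_id, date = day$date,
         day_type = day$day_type),
    setNames(as.list(bins$time), scheme$labels),
    setNames(as.list(as.numeric(bins$count)), paste0("n_", scheme$labels)),
    list(sed_total = as.numeric(sum(sed)),
         wake_total = as.numeric(sum(!sed))),
    setNames(as.list(s_sed$time), paste0("sed_time_", slots)),
    setNames(as.list(s_sed$mean), paste0("sed_mean_", slots)),
    setNames(as.list(s_act$time), paste0("act_time_", slots)),
    setNames(as.list(s_act$mean), paste0("act_mean_", slots))
  )
  tibble::new_tibble(vals, nrow = 1L)
}

day_subset_dates <- function(day_type, subset) {
  switch(subset,
    all7 = rep(TRUE, length(day_type)),
    weekday = day_type == "weekday",
    weekend = day_type == "weekend",
    stop(sprintf("unknown day subset '%s'", subset), call. = FALSE)
  )
}

#' Average daily summaries into per-subject features
#'
#' Per-day arithmetic means of every daily-summary field over the chosen day
#' subset (`all7`, `weekday` or `weekend`), plus descriptive statistics of
#' the raw counts pooled over all epochs of the subset's days: mean/sd
#' overall, over sedentary epochs (cpm < threshold) and over active epochs.
#' Slot means that are undefined on some days (no epochs of that state) are
#' excluded from the cross-day average.
#'
#' @param summaries Tibble of daily summaries ([summarize_day()] rows) for
#'   one subject.
#' @param raw_days List of the corresponding [daytime_day()] objects.
#' @param subset `"all7"`, `"weekday"` or `"weekend"`.
#' @param group Group label carried through to the output.
#' @param threshold Sedentary cut-point used for the descriptive statistics.
#' @return A one-row tibble of per-subject features.
#' @export
average_features <- function(summaries, raw_days, subset = "all7",
                             group = NA_character_,
                             threshold = DEFAULT_THRESHOLD_CPM) {
  stopifnot(nrow(summaries) == length(raw_days))
  keep <- day_subset_dates(summaries$day_type, subset)
  if (!any(keep)) {
    stop(sprintf("no days in subset '%s' for subject %s", subset,
                 summaries$subject_id[1L]), call. = FALSE)
  }
  sub <- summaries[keep, , drop = FALSE]
  num <- vapply(sub, is.numeric, logical(1))
  means <- lapply(sub[num], mean, na.rm = TRUE)

  pooled <- unlist(lapply(raw_days[keep], function(d) d$counts))
  sed <- pooled < threshold
  desc <- list(
    mean_cpm = mean(pooled), sd_cpm = stats::sd(pooled),
    mean_sed_cpm = if (any(sed)) mean(pooled[sed]) else NA_real_,
    sd_sed_cpm = if (sum(sed) > 1) stats::sd(pooled[sed]) else NA_real_,
    mean_act_cpm = if (any(!sed)) mean(pooled[!sed]) else NA_real_,
    sd_act_cpm = if (sum(!sed) > 1) stats::sd(pooled[!sed]) else NA_real_
  )

  out <- tibble::tibble(
    subject_id = sub$subject_id[1L],
    group = group,
    day_subset = subset,
    n_days = sum(keep)
  )
  out[names(means)] <- means
  out[names(desc)] <- desc
  out
}

#' Group-mean feature table
#'
#' Arithmetic mean over subjects of every numeric per-subject feature, for
#' one group and day subset.
#'
#' @param features Tibble of per-subject features ([average_features()]
#'   rows).
#' @param group `"AI"` or `"HC"`.
#' @param subset Day subset to keep (default all rows).
#' @return A one-row tibble of group means.
#' @export
group_table <- function(features, group, subset = NULL) {
  rows <- features[features$group == group, , drop = FALSE]
  if (!is.null(subset)) {
    rows <- rows[rows$day_subset == subset, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    stop(sprintf("no subjects in group '%s'", group), call. = FALSE)
  }
  num <- vapply(rows, is.numeric, logical(1))
  out <- tibble::tibble(group = group, n_subjects = nrow(rows))
  out[names(rows)[num]] <- lapply(rows[num], mean, na.rm = TRUE)
  out
}
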