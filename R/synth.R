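#' Group preset for the synthetic actigraphy generator
#'
#' Parameters of the alternating-renewal bout model used to emulate one
#' study group: exponential dwell-time means for the sedentary and active
#' states, mean count levels conditional on state (sedentary strictly below
#' the 100 cpm cut-point, active at or above it), a missingness fraction,
#' and the wall-clock hour at which active intensity peaks.
#'
#' @param group `"AI"` or `"HC"`.
#' @param mean_sed_bout Mean sedentary dwell time in minutes (> 0).
#' @param mean_act_bout Mean active dwell time in minutes; `0` is the
#'   degenerate limit in which the active state is absent and every day is a
#'   single 840-minute sedentary bout.
#' @param sed_count_level Mean cpm of sedentary epochs, in `[0, 100)`.
#' @param act_count_level Mean cpm of active epochs, `>= 100`.
#' @param missing_frac Fraction of epochs masked as missing, in `[0, 0.1)`.
#' @param diurnal_peak Hour of day (0-24) of maximum active intensity.
#' @return A list of class `group_preset`.
#' @export
group_preset <- function(group, mean_sed_bout, mean_act_bout,
                         sed_count_level, act_count_level,
                         missing_frac = 0.01, diurnal_peak = 15) {
  group <- match.arg(group, c("AI", "HC"))
  stopifnot(
    mean_sed_bout > 0, mean_act_bout >= 0,
    sed_count_level >= 0, sed_count_level < 100,
    act_count_level >= 100,
    missing_frac >= 0, missing_frac < 0.1,
    diurnal_peak >= 0, diurnal_peak <= 24
  )
  structure(
    list(group = group, mean_sed_bout = mean_sed_bout,
         mean_act_bout = mean_act_bout, sed_count_level = sed_count_level,
         act_count_level = act_count_level, missing_frac = missing_frac,
         diurnal_peak = diurnal_peak),
    class = "group_preset"
  )
}

#' Default group presets
#'
#' Calibrated so that cohort-level pipeline output lands near the group
#' contrasts typical of acute-insomnia actigraphy: AI sedentary occupancy
#' around 540 min/day against roughly 460 for healthy controls, AI
#' accumulating more time in medium (6-30, 31-60 min) and long (>60 min)
#' bouts, HC more in the short bins and more total active time, sedentary
#' epochs averaging ~19 cpm (AI) and ~23 cpm (HC), active epochs ~333 and
#' ~355 cpm, activity peaking in the early evening for AI and mid-afternoon
#' for HC. Missingness defaults to 1% of epochs.
#'
#' The dwell means follow from the renewal identities of the minute-rounded
#' model: the stationary sedentary fraction is
#' `E[ceil(Exp(ms))] / (E[ceil(Exp(ms))] + E[ceil(Exp(ma))])` with
#' `E[ceil(Exp(m))] = 1/(1 - exp(-1/m))`, and the expected time a bout
#' spends in a duration bin `[a, b]` is proportional to
#' `(a/m + 1) exp(-a/m) - (b/m + 1) exp(-b/m)`. Solving those for the
#' target occupancies and bin orderings gives sedentary dwell means of 12
#' (AI) vs 4.5 (HC) minutes and active dwell means of 6.5 vs 3.6 minutes:
#' healthy controls break sedentary time often with short active
#' interludes, insomnia subjects settle into fewer, longer sedentary runs.
#'
#' @return Named list with elements `AI` and `HC`, each a [group_preset()].
#' @export
default_presets <- function() {
  list(
    AI = group_preset("AI", mean_sed_bout = 12, mean_act_bout = 6.5,
                      sed_count_level = 19, act_count_level = 333,
                      missing_frac = 0.01, diurnal_peak = 19),
    HC = group_preset("HC", mean_sed_bout = 4.5, mean_act_bout = 3.6,
                      sed_count_level = 23, act_count_level = 355,
                      missing_frac = 0.01, diurnal_peak = 15)
  )
}

# Discretized gamma count draw clamped to a state's support. Sedentary
# epochs use a heavy-tailed shape (cv > 1, matching wrist-count dispersion
# below the cut-point); active epochs a moderate shape. Clamping preserves
# the state partition exactly, which keeps classification invertible.
draw_sed_counts <- function(n, mean_level) {
  if (n == 0L) return(numeric(0))
  shape <- 0.6
  x <- round(stats::rgamma(n, shape = shape, scale = mean_level / shape))
  pmin(pmax(x, 0), 99)
}

draw_act_counts <- function(n, mean_levels) {
  if (n == 0L) return(numeric(0))
  shape <- 2
  x <- round(stats::rgamma(n, shape = shape, scale = mean_levels / shape))
  pmin(pmax(x, 100), 1500)
}

# Alternating-renewal dwell sequence covering `total` minutes. Dwells are
# exponential with the given means, rounded up to whole minutes (minimum 1);
# the initial state is drawn with the stationary occupancy probability.
draw_dwell_sequence <- function(mean_sed, mean_act, total = DAY_MINUTES) {
  if (mean_act == 0) {
    return(tibble::tibble(start_index = 0L, duration = as.integer(total),
                          state = "sedentary"))
  }
  p_sed <- mean_sed / (mean_sed + mean_act)
  sed_first <- stats::runif(1) < p_sed
  durs <- integer(0)
  covered <- 0L
  while (covered < total) {
    # draw dwell pairs in batches; alternation starts with sed_first
    n_new <- max(8L, ceiling(2 * (total - covered) / (mean_sed + mean_act)))
    k <- length(durs)
    is_sed <- (seq_len(n_new) + k) %% 2L == as.integer(sed_first)
    means <- ifelse(is_sed, mean_sed, mean_act)
    d <- pmax(1L, as.integer(ceiling(stats::rexp(n_new, rate = 1) * means)))
    durs <- c(durs, d)
    covered <- covered + sum(d)
  }
  ends <- cumsum(durs)
  n_keep <- which(ends >= total)[1L]
  durs <- durs[seq_len(n_keep)]
  durs[n_keep] <- durs[n_keep] - (ends[n_keep] - total)
  is_sed <- seq_len(n_keep) %% 2L == as.integer(sed_first)
  tibble::tibble(
    start_index = as.integer(cumsum(c(0L, durs[-n_keep]))),
    duration = as.integer(durs),
    state = ifelse(is_sed, "sedentary", "active")
  )
}

diurnal_factor <- function(hour, peak) {
  1 + 0.3 * cos(2 * pi * (hour - peak) / 24)
}

#' Simulate one daytime day of actigraphy
#'
#' Draws an alternating sedentary/active renewal day over the 840-minute
#' daytime window: exponential dwell times (rounded up to whole minutes,
#' minimum 1) with the preset means, then per-epoch counts conditional on
#' state - sedentary counts on `[0, 99]` with the preset mean, active counts
#' on `[100, 1500]` with the preset mean scaled by a cosine diurnal factor
#' peaking at `diurnal_peak`. Because the count supports respect the 100 cpm
#' partition, classifying and re-segmenting the simulated counts recovers
#' the generated bout sequence exactly.
#'
#' @param preset A [group_preset()].
#' @param rng_seed Optional integer seed; if supplied the day is fully
#'   reproducible.
#' @param date Calendar date of the day.
#' @param subject_id Subject identifier attached to the day.
#' @return A list with `day` (a [daytime_day()]) and `bouts` (the
#'   ground-truth segmentation, same columns as [extract_bouts()]).
#' @export
simulate_day <- function(preset, rng_seed = NULL,
                         date = as.Date("2024-01-01"),
                         subject_id = "sim") {
  stopifnot(inherits(preset, "group_preset"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed %% 2147483647))
  bouts <- draw_dwell_sequence(preset$mean_sed_bout, preset$mean_act_bout)
  state_per_min <- rep(bouts$state == "sedentary", bouts$duration)
  counts <- numeric(DAY_MINUTES)
  n_sed <- sum(state_per_min)
  counts[state_per_min] <- draw_sed_counts(n_sed, preset$sed_count_level)
  if (n_sed < DAY_MINUTES) {
    hour <- 8 + (which(!state_per_min) - 1L) / 60
    means <- preset$act_count_level * diurnal_factor(hour, preset$diurnal_peak)
    counts[!state_per_min] <- draw_act_counts(DAY_MINUTES - n_sed, means)
  }
  list(day = daytime_day(subject_id, date, counts), bouts = bouts)
}

subject_seed <- function(rng_seed, i) {
  as.integer((as.numeric(rng_seed) + 104729 * i) %% 2147483647)
}

#' Simulate a full two-group actigraphy cohort
#'
#' Generates a manifest plus one week-long epoch series per subject. Each
#' subject perturbs its group preset by independent log-normal multipliers
#' (sd `subject_sd` on the log scale) on both dwell means, modelling
#' between-subject variability. Recordings start on a Monday at 00:00 so a
#' 7-day week always contains 5 weekdays and 2 weekend days; night epochs
#' (outside 08:00-22:00) carry low sedentary-level counts and are not part
#' of the analysed window. Missingness is injected at the preset fraction
#' uniformly over each series. Subjects use seed substreams derived from
#' `rng_seed` by counter, so the cohort is bit-reproducible and subjects are
#' independent.
#'
#' @param n_ai,n_hc Group sizes (defaults 15 and 22).
#' @param n_days Days per subject (default 7).
#' @param presets Named list with `AI` and `HC` [group_preset()]s.
#' @param rng_seed Integer master seed.
#' @param start_date First recording date; default `2024-01-01`, a Monday.
#' @param subject_sd Log-scale sd of the per-subject dwell-mean multipliers.
#' @return A list of class `synthetic_cohort`: `manifest` (tibble with
#'   subject_id, group, age, sex, n_days, file), `series` (named list of
#'   [epoch_series()], missing epochs as `NA`), `truth` (named list: per
#'   subject, one ground-truth bout tibble per day, computed before
#'   missingness injection) and `rng_seed`.
#' @export
simulate_cohort <- function(n_ai = 15L, n_hc = 22L, n_days = 7L,
                            presets = default_presets(), rng_seed = 1L,
                            start_date = as.Date("2024-01-01"),
                            subject_sd = 0.2) {
  stopifnot(n_ai >= 1L, n_hc >= 1L, n_days >= 1L)
  ids <- c(sprintf("AI%02d", seq_len(n_ai)), sprintf("HC%02d", seq_len(n_hc)))
  groups <- c(rep("AI", n_ai), rep("HC", n_hc))
  series <- list()
  truth <- list()
  ages <- integer(length(ids))
  sexes <- character(length(ids))
  day_min <- parse_clock_minutes(DEFAULT_WINDOW_START)

  for (i in seq_along(ids)) {
    set.seed(subject_seed(rng_seed, i))
    preset <- presets[[groups[i]]]
    mult <- exp(stats::rnorm(2, 0, subject_sd))
    subj_preset <- preset
    subj_preset$mean_sed_bout <- preset$mean_sed_bout * mult[1L]
    subj_preset$mean_act_bout <- preset$mean_act_bout * mult[2L]
    ages[i] <- sample(20:40, 1L)
    sexes[i] <- sample(c("male", "female"), 1L)

    counts <- numeric(n_days * 1440L)
    day_truth <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      sim <- simulate_day(subj_preset, rng_seed = NULL,
                          date = start_date + (d - 1L),
                          subject_id = ids[i])
      idx <- (d - 1L) * 1440L + day_min + seq_len(DAY_MINUTES)
      counts[idx] <- sim$day$counts
      night_idx <- setdiff((d - 1L) * 1440L + seq_len(1440L), idx)
      counts[night_idx] <- draw_sed_counts(length(night_idx),
                                           subj_preset$sed_count_level)
      day_truth[[d]] <- sim$bouts
    }
    if (preset$missing_frac > 0) {
      n_miss <- round(preset$missing_frac * length(counts))
      counts[sample.int(length(counts), n_miss)] <- NA_real_
    }
    times <- as.POSIXct(paste(start_date, "00:00"), tz = "UTC") +
      60 * (seq_along(counts) - 1L)
    series[[ids[i]]] <- epoch_series(ids[i], groups[i], times, counts)
    names(day_truth) <- as.character(start_date + seq_len(n_days) - 1L)
    truth[[ids[i]]] <- day_truth
  }

  manifest <- tibble::tibble(
    subject_id = ids, group = groups, age = ages, sex = sexes,
    n_days = as.integer(n_days),
    file = file.path("epochs", paste0(ids, ".csv"))
  )
  structure(
    list(manifest = manifest, series = series, truth = truth,
         rng_seed = rng_seed, start_date = start_date),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the canonical interchange layout: `manifest.csv`, one epoch CSV per
#' subject under `epochs/`, and `ground_truth.json` holding the generator's
#' bout segmentation per subject-day.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  for (id in names(cohort$series)) {
    write_epoch_csv(cohort$series[[id]],
                    file.path(dir, "epochs", paste0(id, ".csv")))
  }
  truth <- lapply(cohort$truth, function(days) {
    lapply(days, function(b) as.data.frame(b))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = FALSE)
  invisible(dir)
}
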