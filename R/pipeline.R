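#' Pipeline run configuration
#'
#' Collects every tunable of the analysis with its default: sedentary
#' cut-point 100 cpm, daytime window 08:00-22:00, 30-minute imputation
#' window, the standard bout-duration bin scheme, all three day subsets, and
#' K-S/exponential statistics computed on per-subject averaged features
#' (`ks_granularity = "subject"`; `"subject_day"` switches to per-day
#' values).
#'
#' @param manifest Path to the subject manifest CSV (or `NULL` when the
#'   pipeline is run on an in-memory cohort).
#' @param out_dir Output directory for the report bundle.
#' @param threshold_cpm Sedentary cut-point.
#' @param window_start,window_end Daytime window, `"HH:MM"`.
#' @param imputation_window Moving-median window in minutes.
#' @param bins A [bin_scheme()].
#' @param day_subsets Subsets to report (`"all7"`, `"weekday"`, `"weekend"`).
#' @param ks_granularity `"subject"` or `"subject_day"`.
#' @param min_age,max_age Inclusive cohort age filter in years.
#' @param report_precision Decimal places for display rounding in reports.
#' @param seed Seed passed through to synthetic-data generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = NULL,
                       threshold_cpm = DEFAULT_THRESHOLD_CPM,
                       window_start = DEFAULT_WINDOW_START,
                       window_end = DEFAULT_WINDOW_END,
                       imputation_window = 30L,
                       bins = bin_scheme(),
                       day_subsets = c("all7", "weekday", "weekend"),
                       ks_granularity = c("subject", "subject_day"),
                       min_age = 20, max_age = 40,
                       report_precision = 2L,
                       seed = 1L) {
  ks_granularity <- match.arg(ks_granularity)
  stopifnot(inherits(bins, "bin_scheme"),
            all(day_subsets %in% c("all7", "weekday", "weekend")))
  structure(
    list(manifest = manifest, out_dir = out_dir,
         threshold_cpm = threshold_cpm, window_start = window_start,
         window_end = window_end, imputation_window = imputation_window,
         bins = bins, day_subsets = day_subsets,
         ks_granularity = ks_granularity,
         min_age = min_age, max_age = max_age,
         report_precision = report_precision, seed = seed),
    class = "run_config"
  )
}

#' Load a run configuration from a flat YAML file
#'
#' Recognised keys mirror the [run_config()] arguments (`threshold_cpm`,
#' `window_start`, `window_end`, `imputation_window`, `day_subsets`,
#' `ks_granularity`, `min_age`, `max_age`, `report_precision`, `seed`);
#' unknown keys raise an error rather than being silently ignored.
#'
#' @param path YAML file path.
#' @param manifest,out_dir Paths, overriding any values in the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, manifest = NULL, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  allowed <- c("manifest", "out_dir", "threshold_cpm", "window_start",
               "window_end", "imputation_window", "day_subsets",
               "ks_granularity", "min_age", "max_age", "report_precision",
               "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(manifest)) raw$manifest <- manifest
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw)
}

feature_columns <- function(config) {
  c(config$bins$labels, "sed_total", "wake_total")
}

#' Per-subject features from one epoch series
#'
#' Runs imputation, daytime carving and daily summarisation for one subject
#' and averages the days into per-subject features for each requested day
#' subset.
#'
#' @param series An [epoch_series()].
#' @param config A [run_config()].
#' @param group Group label carried into the feature rows.
#' @return A list with `features` (one row per day subset present),
#'   `summaries` (tibble of daily summaries) and `n_dropped_days`.
#' @export
subject_features <- function(series, config = run_config(), group = NULL) {
  group <- group %||% series$group
  imputed <- impute_moving_median(series, config$imputation_window)
  days <- carve_daytime_days(imputed, config$window_start, config$window_end)
  if (length(days) == 0L) {
    stop(sprintf("subject %s has no complete daytime day", series$subject_id),
         call. = FALSE)
  }
  summaries <- dplyr::bind_rows(
    lapply(days, summarize_day, threshold = config$threshold_cpm,
           scheme = config$bins)
  )
  feats <- list()
  for (subset in config$day_subsets) {
    if (any(day_subset_dates(summaries$day_type, subset))) {
      feats[[subset]] <- average_features(
        summaries, days, subset = subset, group = group,
        threshold = config$threshold_cpm
      )
    }
  }
  list(features = dplyr::bind_rows(feats), summaries = summaries,
       n_dropped_days = length(attr(days, "dropped")))
}

#' Cohort-level feature extraction
#'
#' Applies [subject_features()] to every series of a cohort and stacks the
#' results. Subjects whose series fails to process are skipped with a
#' message collected into the `skipped` element, so one malformed file does
#' not abort a cohort run.
#'
#' @param series_list Named list of [epoch_series()].
#' @param manifest Manifest tibble; used for the group labels.
#' @param config A [run_config()].
#' @return A list with `features`, `summaries` (both tibbles, summaries
#'   carrying a `group` column) and `skipped` (character).
#' @export
cohort_features <- function(series_list, manifest, config = run_config()) {
  features <- list()
  summaries <- list()
  skipped <- character(0)
  for (id in names(series_list)) {
    grp <- manifest$group[match(id, manifest$subject_id)]
    res <- tryCatch(
      subject_features(series_list[[id]], config, group = grp),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", id, conditionMessage(res)))
      next
    }
    features[[id]] <- res$features
    res$summaries$group <- grp
    summaries[[id]] <- res$summaries
  }
  list(features = dplyr::bind_rows(features),
       summaries = dplyr::bind_rows(summaries),
       skipped = skipped)
}

#' Group comparison report (bout features)
#'
#' For each bout feature (five bin times, `sed_total`, `wake_total`):
#' exponential fits with 95% chi-square bounds per group and the two-sample
#' K-S test between the groups. At the default granularity the samples are
#' per-subject averaged features (one value per subject); `"subject_day"`
#' uses per-day values instead. Non-positive values cannot enter an
#' exponential fit and are dropped from it (the count kept is reported);
#' the K-S test always uses the full samples.
#'
#' @param features Per-subject feature tibble ([cohort_features()]).
#' @param summaries Daily-summary tibble, needed for `"subject_day"`.
#' @param subset Day subset to compare.
#' @param config A [run_config()].
#' @return A tibble: one row per feature with group means, CI bounds,
#'   sample sizes used in the fits, `ks_D` and `ks_p`.
#' @export
compare_groups <- function(features, summaries = NULL, subset = "all7",
                           config = run_config()) {
  cols <- feature_columns(config)
  if (config$ks_granularity == "subject") {
    data <- features[features$day_subset == subset, , drop = FALSE]
  } else {
    stopifnot(!is.null(summaries))
    keep <- day_subset_dates(summaries$day_type, subset)
    data <- summaries[keep, , drop = FALSE]
  }
  rows <- lapply(cols, function(col) {
    x_ai <- data[[col]][data$group == "AI"]
    x_hc <- data[[col]][data$group == "HC"]
    fit_or_na <- function(v) {
      v <- v[v > 0]
      if (length(v) >= 2L) fit_exponential(v) else
        list(n = length(v), mean_hat = NA_real_, ci_lower = NA_real_,
             ci_upper = NA_real_)
    }
    f_ai <- fit_or_na(x_ai)
    f_hc <- fit_or_na(x_hc)
    ks <- ks_two_sample(x_ai, x_hc)
    tibble::tibble(
      feature = col, day_subset = subset,
      ai_mean = mean(x_ai), ai_ci_lower = f_ai$ci_lower,
      ai_ci_upper = f_ai$ci_upper, ai_n_fit = f_ai$n,
      hc_mean = mean(x_hc), hc_ci_lower = f_hc$ci_lower,
      hc_ci_upper = f_hc$ci_upper, hc_n_fit = f_hc$n,
      ks_D = ks$D, ks_p = ks$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Descriptive raw-count statistics per group
#'
#' The classic first table of an actigraphy comparison: per-subject mean and
#' sd of the raw counts (overall, sedentary epochs only, active epochs
#' only), averaged over subjects in each group with the between-subject sd,
#' plus a two-sample K-S p-value comparing the per-subject values between
#' groups.
#'
#' @param features Per-subject feature tibble, `all7` rows used.
#' @return A tibble with one row per statistic.
#' @export
descriptive_table <- function(features) {
  data <- features[features$day_subset == "all7", , drop = FALSE]
  stats_cols <- c(mean = "mean_cpm", sd = "sd_cpm",
                  `mean (cpm <100)` = "mean_sed_cpm",
                  `sd (cpm <100)` = "sd_sed_cpm",
                  `mean (cpm >=100)` = "mean_act_cpm",
                  `sd (cpm >=100)` = "sd_act_cpm")
  rows <- lapply(seq_along(stats_cols), function(i) {
    col <- stats_cols[[i]]
    x_ai <- data[[col]][data$group == "AI"]
    x_hc <- data[[col]][data$group == "HC"]
    x_ai <- x_ai[!is.na(x_ai)]
    x_hc <- x_hc[!is.na(x_hc)]
    ks <- ks_two_sample(x_ai, x_hc)
    tibble::tibble(
      statistic = names(stats_cols)[i],
      ai_mean = mean(x_ai), ai_sd = stats::sd(x_ai),
      hc_mean = mean(x_hc), hc_sd = stats::sd(x_hc),
      ks_p = ks$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Two-hour aggregate report
#'
#' Group means of the per-subject 2-hour slot aggregates (sedentary and
#' active minutes and mean cpm per slot), the quantities usually drawn as
#' box plots over the seven daytime slots.
#'
#' @param features Per-subject feature tibble.
#' @param subset Day subset.
#' @return A tibble: one row per slot x group with the four aggregates.
#' @export
two_hour_table <- function(features, subset = "all7") {
  data <- features[features$day_subset == subset, , drop = FALSE]
  slots <- two_hour_slot_labels()
  rows <- list()
  for (grp in unique(data$group)) {
    gd <- data[data$group == grp, , drop = FALSE]
    for (s in slots) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = grp, day_subset = subset, slot = s,
        sed_time = mean(gd[[paste0("sed_time_", s)]], na.rm = TRUE),
        sed_mean_cpm = mean(gd[[paste0("sed_mean_", s)]], na.rm = TRUE),
        act_time = mean(gd[[paste0("act_time_", s)]], na.rm = TRUE),
        act_mean_cpm = mean(gd[[paste0("act_mean_", s)]], na.rm = TRUE)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Logistic regression of group on bout features
#'
#' Fits the group label (1 = HC, 0 = AI) on the five per-subject
#' bout-duration bin features for the chosen day subset.
#'
#' @param features Per-subject feature tibble.
#' @param subset Day subset (default `"all7"`, the 7-day averages).
#' @param config A [run_config()].
#' @return A [fit_logistic()] result.
#' @export
logistic_on_features <- function(features, subset = "all7",
                                 config = run_config()) {
  data <- features[features$day_subset == subset, , drop = FALSE]
  X <- as.matrix(data[, config$bins$labels, drop = FALSE])
  y <- as.numeric(data$group == "HC")
  fit_logistic(X, y)
}

format_p <- function(p, precision = 2L) {
  ifelse(p < 1e-4, sprintf("%.1E", p), sprintf("%.4f", round(p, 4)))
}

#' Bin-decomposition check on a group-mean table
#'
#' The report layer's internal-consistency summation: for each (subset,
#' group) row set of a long-format group-mean table, the sum of the five
#' bout-bin mean times is compared with the reported `sed_total` mean. Used
#' both on pipeline output and on published reference means.
#'
#' @param means Long tibble with columns `day_subset`, `group`, `feature`,
#'   `mean`.
#' @return A tibble with `day_subset`, `group`, `bin_sum`, `sed_total`,
#'   `shortfall` (= sed_total - bin_sum).
#' @export
bin_decomposition <- function(means) {
  bin_feats <- bin_scheme()$labels
  means |>
    dplyr::group_by(.data$day_subset, .data$group) |>
    dplyr::summarise(
      bin_sum = sum(.data$mean[.data$feature %in% bin_feats]),
      sed_total = .data$mean[.data$feature == "sed_total"][1L],
      .groups = "drop"
    ) |>
    dplyr::mutate(shortfall = .data$sed_total - .data$bin_sum)
}

#' Published reference group means
#'
#' Group-level mean bout-bin times, total sedentary and total active minutes
#' (minutes/day) reported for a 37-subject acute-insomnia vs healthy-control
#' actigraphy cohort, for the all-7-day, weekday and weekend subsets. These
#' are published summary values shipped as a reference fixture for
#' internal-consistency checks (e.g. the bin-sum decomposition); they are
#' not an output of this package.
#'
#' @return Long tibble with columns `day_subset`, `group`, `feature`,
#'   `mean`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "reference_group_means.csv",
                      package = "sedbouts", mustWork = TRUE)
  readr::read_csv(path, col_types = "cccd", progress = FALSE,
                  show_col_types = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates manifest reading, cohort age filtering, preprocessing,
#' feature extraction and every report: per-subject features, descriptive
#' statistics, group comparisons for each day subset, the logistic
#' coefficient table, 2-hour aggregates, and a run log (configuration echo,
#' skipped subjects, dropped days, conservation shortfalls). Machine CSVs
#' are written at full precision; display-rounded companions use
#' `report_precision` decimals.
#'
#' @param config A [run_config()] with `manifest` and `out_dir` set, or with
#'   `cohort` supplied in-memory.
#' @param cohort Optional [simulate_cohort()] result to analyse instead of
#'   reading files from disk.
#' @return Invisibly, a list with all report tibbles (`features`,
#'   `summaries`, `descriptive`, `comparisons`, `logistic`, `two_hour`,
#'   `log_lines`).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(
    sprintf("sedbouts %s", as.character(utils::packageVersion("sedbouts"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("threshold_cpm=%s window=[%s,%s) imputation_window=%s",
            config$threshold_cpm, config$window_start, config$window_end,
            config$imputation_window),
    sprintf("ks_granularity=%s age_band=[%s,%s] seed=%s",
            config$ks_granularity, config$min_age, config$max_age,
            config$seed)
  )

  if (is.null(cohort)) {
    stopifnot(!is.null(config$manifest))
    manifest <- read_manifest(config$manifest)
    base_dir <- dirname(config$manifest)
    manifest <- filter_cohort(manifest, config$min_age, config$max_age)
    series_list <- list()
    for (i in seq_len(nrow(manifest))) {
      path <- file.path(base_dir, manifest$file[i])
      res <- tryCatch(
        read_epoch_csv(path, subject_id = manifest$subject_id[i],
                       group = manifest$group[i]),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        log_lines <- c(log_lines, sprintf("skipped %s: %s",
                                          manifest$subject_id[i],
                                          conditionMessage(res)))
        next
      }
      series_list[[manifest$subject_id[i]]] <- res
    }
  } else {
    manifest <- filter_cohort(cohort$manifest, config$min_age, config$max_age)
    series_list <- cohort$series[manifest$subject_id]
  }

  cf <- cohort_features(series_list, manifest, config)
  log_lines <- c(log_lines, cf$skipped)

  # conservation audit on complete days
  total <- cf$summaries$sed_total + cf$summaries$wake_total
  if (any(total != DAY_MINUTES)) {
    log_lines <- c(log_lines, sprintf(
      "conservation shortfall on %d day(s): mean sed+wake = %.2f min",
      sum(total != DAY_MINUTES), mean(total)
    ))
  }

  have_both <- all(c("AI", "HC") %in% cf$features$group)
  comparisons <- NULL
  logistic <- NULL
  descriptive <- NULL
  if (have_both) {
    comparisons <- dplyr::bind_rows(lapply(
      intersect(config$day_subsets, unique(cf$features$day_subset)),
      function(s) compare_groups(cf$features, cf$summaries, s, config)
    ))
    descriptive <- descriptive_table(cf$features)
    logistic <- logistic_on_features(cf$features, "all7", config)
  } else {
    log_lines <- c(log_lines,
                   "only one group present: comparison stages skipped")
  }
  two_hour <- dplyr::bind_rows(lapply(
    intersect(config$day_subsets, unique(cf$features$day_subset)),
    function(s) two_hour_table(cf$features, s)
  ))

  out <- list(features = cf$features, summaries = cf$summaries,
              descriptive = descriptive, comparisons = comparisons,
              logistic = logistic, two_hour = two_hour,
              log_lines = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) {
      if (!is.null(x)) {
        readr::write_csv(x, file.path(config$out_dir, name), eol = "\n")
      }
    }
    w(cf$features, "features.csv")
    w(cf$summaries, "daily_summaries.csv")
    w(descriptive, "descriptive_stats.csv")
    if (!is.null(comparisons)) {
      w(comparisons, "group_comparison.csv")
      disp <- comparisons
      num <- vapply(disp, is.numeric, logical(1))
      disp[num] <- lapply(disp[num], round, digits = config$report_precision)
      disp$ks_p <- format_p(comparisons$ks_p, config$report_precision)
      w(disp, "group_comparison_display.csv")
    }
    if (!is.null(logistic)) {
      w(coefficient_table(logistic), "logistic_coefficients.csv")
    }
    w(two_hour, "two_hour_aggregates.csv")
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(out)
}
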