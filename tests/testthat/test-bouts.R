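make_day <- function(counts, date = as.Date("2024-01-01"), id = "d1") {
  daytime_day(id, date, counts)
}

test_that("sedentary classification uses a strict cut-point", {
  expect_equal(classify_sedentary(c(0, 99, 100, 250)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(classify_sedentary(rep(0, 840))))
  expect_false(any(classify_sedentary(rep(100, 840))))
  expect_error(classify_sedentary(c(1, NA)))
})

test_that("bout extraction returns maximal alternating runs tiling the day", {
  b <- extract_bouts(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(b$start_index, c(0L, 3L, 4L))
  expect_equal(b$duration, c(3L, 1L, 2L))
  expect_equal(b$state, c("sedentary", "active", "sedentary"))

  b <- extract_bouts(rep(TRUE, 840))
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 840L)

  for (seed in 1:40) {
    set.seed(seed)
    mask <- runif(840) < runif(1)
    got <- extract_bouts(mask)
    expect_equal(as.data.frame(got), oracle_rle(mask))
    expect_equal(sum(got$duration), 840L)
  }
})

test_that("duration binning respects the inclusive integer bin edges", {
  mk <- function(durs) {
    tibble::tibble(start_index = 0L, duration = as.integer(durs),
                   state = "sedentary")
  }
  one_each <- bin_sedentary_time(mk(c(2, 5, 10, 45, 120)))
  expect_equal(unname(one_each$time), c(2, 5, 10, 45, 120))
  expect_equal(unname(one_each$count), rep(1L, 5))

  edges <- bin_sedentary_time(mk(c(3, 4, 6, 30, 31, 60, 61)))
  expect_equal(unname(edges$time), c(3, 4, 36, 91, 61))
  expect_equal(unname(edges$count), c(1L, 1L, 2L, 2L, 1L))

  none <- bin_sedentary_time(tibble::tibble(
    start_index = 0L, duration = 840L, state = "active"))
  expect_equal(unname(none$time), rep(0, 5))
  expect_equal(unname(none$count), rep(0L, 5))
})

test_that("daily summary fields satisfy the accounting identities", {
  # constant 50 cpm: one all-day sedentary bout
  s <- summarize_day(make_day(rep(50, 840)))
  expect_equal(s$sed_total, 840)
  expect_equal(s$wake_total, 0)
  expect_equal(s$sed_bouts_gt60, 840)
  expect_equal(s$n_sed_bouts_gt60, 1)
  expect_equal(unlist(s[paste0("sed_time_", two_hour_slot_labels())],
                      use.names = FALSE), rep(120, 7))
  expect_equal(unlist(s[paste0("sed_mean_", two_hour_slot_labels())],
                      use.names = FALSE), rep(50, 7))
  expect_true(all(is.na(unlist(s[paste0("act_mean_", two_hour_slot_labels())]))))

  # alternating 50/150: 420 one-minute sedentary bouts
  s <- summarize_day(make_day(rep(c(50, 150), 420)))
  expect_equal(s$sed_total, 420)
  expect_equal(s$wake_total, 420)
  expect_equal(s$sed_bouts_1_3, 420)
  expect_equal(s$n_sed_bouts_1_3, 420)
  expect_equal(s$sed_bouts_4_5 + s$sed_bouts_6_30 + s$sed_bouts_31_60 +
                 s$sed_bouts_gt60, 0)
})

test_that("daily summary equals independent recomposition from the primitives", {
  scheme <- bin_scheme()
  for (seed in 1:10) {
    set.seed(seed)
    counts <- rpois(840, sample(c(60, 100, 180), 1))
    s <- summarize_day(make_day(counts))
    sed <- counts < 100
    bins <- bin_sedentary_time(extract_bouts(sed), scheme)
    expect_equal(unlist(s[scheme$labels], use.names = FALSE),
                 unname(bins$time))
    expect_equal(s$sed_total, sum(sed))
    expect_equal(s$sed_total + s$wake_total, 840)
    expect_equal(sum(unlist(s[scheme$labels])), s$sed_total)
    expect_equal(sum(unlist(s[paste0("sed_time_", two_hour_slot_labels())])),
                 s$sed_total)
    expect_equal(sum(unlist(s[paste0("act_time_", two_hour_slot_labels())])),
                 s$wake_total)
    # bout-count bounds: count x lower <= time <= count x upper
    counts_per_bin <- unlist(s[paste0("n_", scheme$labels)], use.names = FALSE)
    times_per_bin <- unlist(s[scheme$labels], use.names = FALSE)
    expect_true(all(times_per_bin >= counts_per_bin * scheme$lower))
    finite <- is.finite(scheme$upper)
    expect_true(all(times_per_bin[finite] <=
                      (counts_per_bin * scheme$upper)[finite]))
  }
})

test_that("raising the threshold never decreases sed_total", {
  set.seed(21)
  counts <- rpois(840, 120)
  day <- make_day(counts)
  totals <- vapply(c(50, 100, 150, 300),
                   function(th) summarize_day(day, threshold = th)$sed_total,
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("feature averaging matches per-day means and pools count statistics", {
  d1 <- make_day(rep(c(50, 150), 420), as.Date("2024-01-01")) # Monday
  d2 <- make_day(rep(c(0, 300), c(500, 340)), as.Date("2024-01-06")) # Saturday
  s <- dplyr::bind_rows(summarize_day(d1), summarize_day(d2))

  # single-day subset: features equal that day's summary
  f_we <- average_features(s, list(d1, d2), "weekend", group = "HC")
  expect_equal(f_we$sed_total, 500)
  expect_equal(f_we$n_days, 1L)

  # two days with sed_total 420 and 500 average to 460
  f_all <- average_features(s, list(d1, d2), "all7", group = "HC")
  expect_equal(f_all$sed_total, 460)

  # pooled descriptive statistics over all epochs of the subset
  pooled <- c(d1$counts, d2$counts)
  expect_equal(f_all$mean_cpm, mean(pooled))
  expect_equal(f_all$sd_cpm, sd(pooled))
  expect_equal(f_all$mean_sed_cpm, mean(pooled[pooled < 100]))
  expect_equal(f_all$mean_act_cpm, mean(pooled[pooled >= 100]))

  expect_error(average_features(s[1, ], list(d1), "weekend", "HC"), "subset")
})

test_that("a Monday-Sunday week contributes exactly 5 weekday days", {
  co <- simulate_cohort(n_ai = 1, n_hc = 1, rng_seed = 2)
  res <- subject_features(co$series[[1]], run_config())
  f <- res$features
  expect_equal(f$n_days[f$day_subset == "weekday"], 5L)
  expect_equal(f$n_days[f$day_subset == "weekend"], 2L)
  expect_equal(f$n_days[f$day_subset == "all7"], 7L)
})

test_that("group table averages subject features arithmetically", {
  f <- tibble::tibble(
    subject_id = c("a", "b", "c"), group = c("AI", "AI", "HC"),
    day_subset = "all7", sed_total = c(500, 540, 400)
  )
  expect_equal(group_table(f, "AI")$sed_total, 520)
  expect_equal(group_table(f, "HC")$sed_total, 400)
  expect_error(group_table(f[f$group == "AI", ], "XX"), "no subjects")

  # generator presets with heavier long-bout mass raise the >60 group mean
  co <- simulate_cohort(n_ai = 5, n_hc = 5, n_days = 2, rng_seed = 8)
  feats <- features_from_cohort(co)
  all7 <- feats[feats$day_subset == "all7", ]
  expect_gt(group_table(all7, "AI")$sed_bouts_gt60,
            group_table(all7, "HC")$sed_bouts_gt60)
})
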