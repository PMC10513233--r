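test_that("preset validation enforces the state partition and dwell domains", {
  expect_error(group_preset("AI", 0, 5, 19, 333), "mean_sed_bout")
  expect_error(group_preset("AI", 10, 5, 120, 333))
  expect_error(group_preset("AI", 10, 5, 19, 90))
  expect_error(group_preset("AI", 10, 5, 19, 333, missing_frac = 0.5))
  expect_s3_class(group_preset("HC", 8, 6, 23, 355), "group_preset")
})

test_that("degenerate active dwell yields a single all-day sedentary bout", {
  preset <- group_preset("AI", 12, 0, 19, 333)
  sim <- simulate_day(preset, rng_seed = 1)
  expect_equal(nrow(sim$bouts), 1L)
  expect_equal(sim$bouts$duration, 840L)
  expect_equal(sim$bouts$state, "sedentary")
  expect_true(all(sim$day$counts < 100))
})

test_that("classification + extraction recovers the generated segmentation exactly", {
  presets <- default_presets()
  for (seed in 1:30) {
    preset <- presets[[1 + seed %% 2]]
    sim <- simulate_day(preset, rng_seed = seed)
    recovered <- extract_bouts(classify_sedentary(sim$day$counts))
    expect_identical(as.data.frame(recovered), as.data.frame(sim$bouts))
  }
})

test_that("long-run sedentary occupancy matches the renewal oracle", {
  preset <- group_preset("AI", 20, 10, 19, 333)
  set.seed(99)
  occ <- mean(vapply(1:500, function(i) {
    sim <- simulate_day(preset)
    sum(sim$day$counts < 100) / 840
  }, numeric(1)))
  # continuous-dwell target 20/(20+10) = 2/3; minute rounding shifts the
  # stationary fraction to E[ceil]/sums, both must be within 3 points
  expect_lt(abs(occ - 20 / 30), 0.03)
  expect_lt(abs(occ - oracle_occupancy(20, 10)), 0.03)
})

test_that("generated sedentary dwell times follow the preset exponential", {
  # interior bouts only (day-boundary bouts are truncated); the integer
  # durations are ceil(Exp), so subtracting U(0,1) recovers a sample whose
  # CDF is the linear interpolant of the exponential CDF at integers -
  # indistinguishable from Exp at this sample size
  preset <- default_presets()$AI
  set.seed(17)
  durs <- integer(0)
  while (length(durs) < 5000) {
    sim <- simulate_day(preset)
    b <- sim$bouts
    interior <- b$state == "sedentary" & b$start_index > 0 &
      b$start_index + b$duration < 840
    durs <- c(durs, b$duration[interior])
  }
  durs <- durs[1:5000]
  smooth <- durs - runif(5000)
  ref <- rexp(5000, rate = 1 / preset$mean_sed_bout)
  expect_gt(ks_two_sample(smooth, ref)$p, 0.01)
  expect_lt(abs(mean(durs) - (preset$mean_sed_bout + 0.5)), 0.5)
})

test_that("cohorts are reproducible, correctly sized, and subject-varied", {
  a <- simulate_cohort(n_ai = 3, n_hc = 3, n_days = 2, rng_seed = 123)
  b <- simulate_cohort(n_ai = 3, n_hc = 3, n_days = 2, rng_seed = 123)
  expect_identical(a$manifest, b$manifest)
  for (id in names(a$series)) {
    expect_identical(a$series[[id]]$counts, b$series[[id]]$counts)
  }
  expect_identical(a$truth, b$truth)

  # different subjects have different realizations
  expect_false(identical(a$series[[1]]$counts, a$series[[2]]$counts))

  co <- simulate_cohort(rng_seed = 9)
  expect_equal(nrow(co$manifest), 37L)
  expect_equal(sum(co$manifest$group == "AI"), 15L)
  expect_equal(sum(co$manifest$group == "HC"), 22L)
  expect_true(all(co$manifest$age >= 20 & co$manifest$age <= 40))
  # 7-day weeks starting Monday
  expect_equal(format(co$start_date, "%u"), "1")
  # ~1% missingness injected per series
  miss <- vapply(co$series, function(s) mean(is.na(s$counts)), numeric(1))
  expect_true(all(abs(miss - 0.01) < 0.002))
})

test_that("written cohorts round-trip through the canonical file layout", {
  co <- simulate_cohort(n_ai = 2, n_hc = 2, n_days = 1, rng_seed = 77)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m$subject_id, co$manifest$subject_id)
  es <- read_epoch_csv(file.path(dir, m$file[1]), subject_id = m$subject_id[1],
                       group = m$group[1])
  expect_identical(es$counts, co$series[[1]]$counts)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt[[1]][[1]]$duration, co$truth[[1]][[1]]$duration)
})
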