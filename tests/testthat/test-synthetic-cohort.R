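test_that("a saturated habit level forces adherence every day", {
  prof <- flat_profile(10)
  rec <- simulate_participant(prof, 50)
  expect_equal(nrow(rec), 50)
  expect_true(all(rec$play_duration > 0))
  expect_true(all(rec$session_count >= 1))
  expect_true(all(rec$tasks_completed >= 1))
})

test_that("simulation is a pure function of the profile seed", {
  prof <- draw_profile(study_config("S", n_participants = 3, seed = 9), 2)
  expect_identical(simulate_participant(prof, 60), simulate_participant(prof, 60))
  expect_error(simulate_participant(prof, 0), "positive")
})

test_that("with flat dynamics the adherence rate matches the logistic closed form", {
  # mu = 0, rho = sigma = drift = 0, no weekday effect: days are iid
  # Bernoulli(1/2); Monte-Carlo rate within 3 standard errors.
  rec <- simulate_participant(flat_profile(0, seed = 42), 10000)
  rate <- mean(rec$play_duration > 0)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("daily records satisfy the conservation invariants", {
  study <- simulate_study(study_config("S", n_participants = 6, seed = 3))
  rec <- study$records
  zero <- rec$play_duration == 0
  expect_identical(zero, rec$session_count == 0)
  expect_identical(zero, rec$tasks_completed == 0)
  expect_true(all(rec$max_level >= 1 & rec$max_level <= 58))
  for (pid in unique(rec$participant_id)) {
    lv <- rec$max_level[rec$participant_id == pid]
    expect_false(is.unsorted(lv))
  }
})

test_that("a study has n_participants x n_days rows and is seed-sensitive", {
  s1 <- simulate_study(study_config("S", n_participants = 5, n_days = 60, seed = 1))
  expect_equal(nrow(s1$records), 300)
  expect_equal(length(unique(s1$records$participant_id)), 5)
  s2 <- simulate_study(study_config("S", n_participants = 5, n_days = 60, seed = 2))
  expect_false(identical(s1$records, s2$records))
  # pure function of the config
  expect_identical(s1$records, simulate_study(study_config("S", n_participants = 5,
                                                           n_days = 60, seed = 1))$records)
})

test_that("raising the habit-mean prior raises the study adherence rate", {
  base <- study_config("lo", n_participants = 50, seed = 7)
  hi <- study_config("hi", n_participants = 50, seed = 7,
                     habit_mean_prior = c(base$habit_mean_prior[1] + 2, 0.8))
  rate <- function(s) mean(s$records$play_duration >= 10)
  expect_gt(rate(simulate_study(hi)), rate(simulate_study(base)))
})

test_that("the benchmark suite has the documented shape and validates shift", {
  suite <- make_benchmark_suite(1, shift_strength = 1)
  expect_named(suite, c("A", "B", "C"))
  expect_equal(sum(vapply(suite, function(s) nrow(s$records), numeric(1))), 4320)
  expect_error(make_benchmark_suite(1, shift_strength = -0.5), "nonnegative")
})

test_that("zero shift yields exchangeable studies, full shift separates them", {
  suite0 <- make_benchmark_suite(11, shift_strength = 0)
  rate_by_p <- function(s) {
    tapply(s$records$play_duration >= 10, s$records$participant_id, mean)
  }
  p0 <- stats::t.test(rate_by_p(suite0$A), rate_by_p(suite0$B))$p.value
  expect_gt(p0, 0.01)
  # under shift, study B's habit prior sits lower: rates differ across seeds
  diffs <- vapply(1:5, function(s) {
    st <- make_benchmark_suite(s, shift_strength = 1, n_participants = 12)
    mean(rate_by_p(st$A)) - mean(rate_by_p(st$B))
  }, numeric(1))
  expect_gt(mean(diffs), 0.05)
})

test_that("records survive a CSV round trip and validation catches corruption", {
  study <- simulate_study(study_config("S", n_participants = 3, seed = 2))
  f <- tempfile(fileext = ".csv")
  pf <- tempfile(fileext = ".csv")
  write_study_csv(study, f, profiles_file = pf)
  back <- read_records_csv(f)
  expect_equal(back$play_duration, study$records$play_duration, tolerance = 1e-6)
  expect_equal(nrow(utils::read.csv(pf)), 3)
  bad <- study$records
  bad$session_count[bad$play_duration > 0][1] <- 0L
  bf <- tempfile(fileext = ".csv")
  utils::write.csv(bad, bf, row.names = FALSE)
  expect_error(read_records_csv(bf), "jointly zero")
})
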