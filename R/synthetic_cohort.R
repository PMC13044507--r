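# Synthetic multi-study cohort generator.
#
# Daily engagement with a cognitive-training game is driven by a latent habit
# process: AR(1) on the logit scale with a day-of-week effect and a slow
# drift. On adherent-propensity days the four observed engagement features
# (play duration, session count, maximum level, tasks completed) are drawn
# from simple count/duration models; on lapse days all activity is zero and
# the maximum level carries forward.

#' Define the generative parameters of one synthetic study
#'
#' A study is a cohort of participants whose individual behavioral parameters
#' are drawn from study-level priors. Between-study domain shift is created by
#' displacing those priors (see [make_benchmark_suite()]).
#'
#' @param study_id Character label for the study.
#' @param n_participants Number of participants (positive integer).
#' @param n_days Days of follow-up per participant; must be at least 60 so a
#'   30-day train / 30-day test split always exists.
#' @param habit_mean_prior Length-2 numeric `(location, scale)` of the normal
#'   prior for each participant's baseline habit level (logit scale).
#' @param habit_persistence_prior Length-2 numeric `(low, high)` bounds, inside
#'   `[0, 1)`, of the uniform prior for the AR(1) persistence coefficient.
#' @param weekday_amplitude Magnitude of the day-of-week effect on adherence
#'   propensity (logit scale); 0 removes weekday structure.
#' @param drift_per_day Signed daily trend in adherence propensity (logit
#'   scale per day).
#' @param duration_lognorm Length-2 numeric `(meanlog, sdlog)` of the
#'   log-normal play-duration distribution (minutes) on adherent days.
#' @param session_rate Mean sessions per adherent day (>= 1).
#' @param task_rate_per_min Expected tasks completed per minute played (> 0).
#' @param level_gain_rate Expected level increments per adherent day (> 0).
#' @param noise_sd Innovation standard deviation of the latent habit process.
#' @param seed Integer seed; the whole study table is a pure function of the
#'   config, including this seed.
#'
#' @return An object of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config("A", n_participants = 5, seed = 1)
#' study <- simulate_study(cfg)
#' head(study$records)
study_config <- function(study_id,
                         n_participants = 24L,
                         n_days = 60L,
                         habit_mean_prior = c(0.5, 0.8),
                         habit_persistence_prior = c(0.85, 0.97),
                         weekday_amplitude = 1.2,
                         drift_per_day = -0.005,
                         duration_lognorm = c(log(30), 0.55),
                         session_rate = 2,
                         task_rate_per_min = 0.8,
                         level_gain_rate = 0.5,
                         noise_sd = 1.0,
                         seed = 1L) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  stop_if_not_scalar_number(n_participants, "n_participants", lower = 1)
  stop_if_not_scalar_number(n_days, "n_days", lower = 60)
  stopifnot(length(habit_mean_prior) == 2L, is.finite(habit_mean_prior))
  stopifnot(length(habit_persistence_prior) == 2L)
  if (habit_persistence_prior[1] < 0 || habit_persistence_prior[2] >= 1 ||
      habit_persistence_prior[1] > habit_persistence_prior[2]) {
    stop("`habit_persistence_prior` bounds must satisfy 0 <= low <= high < 1",
         call. = FALSE)
  }
  stop_if_not_scalar_number(habit_mean_prior[2], "habit_mean_prior[2]", lower = 0)
  stop_if_not_scalar_number(weekday_amplitude, "weekday_amplitude", lower = 0)
  stop_if_not_scalar_number(drift_per_day, "drift_per_day")
  stopifnot(length(duration_lognorm) == 2L, duration_lognorm[2] > 0)
  stop_if_not_scalar_number(session_rate, "session_rate", lower = 1)
  if (task_rate_per_min <= 0 || level_gain_rate <= 0) {
    stop("rate parameters must be strictly positive", call. = FALSE)
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)

  structure(
    list(
      study_id = study_id,
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days),
      habit_mean_prior = as.numeric(habit_mean_prior),
      habit_persistence_prior = as.numeric(habit_persistence_prior),
      weekday_amplitude = as.numeric(weekday_amplitude),
      drift_per_day = as.numeric(drift_per_day),
      duration_lognorm = as.numeric(duration_lognorm),
      session_rate = as.numeric(session_rate),
      task_rate_per_min = as.numeric(task_rate_per_min),
      level_gain_rate = as.numeric(level_gain_rate),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("Synthetic study config '%s': %d participants x %d days (seed %d)\n",
              x$study_id, x$n_participants, x$n_days, x$seed))
  cat(sprintf("  habit mean prior N(%.2f, %.2f), persistence U(%.2f, %.2f), noise sd %.2f\n",
              x$habit_mean_prior[1], x$habit_mean_prior[2],
              x$habit_persistence_prior[1], x$habit_persistence_prior[2], x$noise_sd))
  cat(sprintf("  weekday amplitude %.2f, drift %+0.4f/day, duration lognormal(%.2f, %.2f)\n",
              x$weekday_amplitude, x$drift_per_day,
              x$duration_lognorm[1], x$duration_lognorm[2]))
  invisible(x)
}

# Fixed within-week shape of the adherence propensity (Mon..Sun), centered at
# zero; scaled by the study's weekday_amplitude. Weekend engagement dips.
WEEKDAY_PATTERN <- c(0.25, 0.35, 0.30, 0.15, 0.00, -0.55, -0.50)

#' Construct a participant profile directly
#'
#' Assembles the realized behavioral parameters of one participant. Usually
#' profiles are drawn from a study's priors with [draw_profile()]; the direct
#' constructor is useful for calibration checks with hand-picked dynamics
#' (e.g. no persistence, no noise, so the adherence rate has a closed form).
#'
#' @param participant_id,study_id Labels.
#' @param habit_mean Baseline habit level (logit scale).
#' @param persistence AR(1) coefficient in `[0, 1)`.
#' @param weekday_effects Length-7 day-of-week effects (Mon..Sun, logit).
#' @param drift Daily trend (logit/day).
#' @param duration_meanlog,duration_sdlog Log-normal play-duration parameters.
#' @param session_rate,task_rate_per_min,level_gain_rate Activity rates.
#' @param noise_sd Habit innovation SD.
#' @param seed Integer seed for the participant's trajectory.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, study_id = "synthetic",
                                habit_mean = 0, persistence = 0,
                                weekday_effects = rep(0, 7), drift = 0,
                                duration_meanlog = log(30), duration_sdlog = 0.55,
                                session_rate = 2, task_rate_per_min = 0.8,
                                level_gain_rate = 0.5, noise_sd = 0, seed = 1L) {
  stopifnot(length(weekday_effects) == 7L, persistence >= 0, persistence < 1,
            duration_sdlog > 0, session_rate >= 1, task_rate_per_min > 0,
            level_gain_rate > 0, noise_sd >= 0)
  structure(
    list(participant_id = participant_id, study_id = study_id,
         habit_mean = habit_mean, persistence = persistence,
         weekday_effects = as.numeric(weekday_effects), drift = drift,
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         session_rate = session_rate, task_rate_per_min = task_rate_per_min,
         level_gain_rate = level_gain_rate, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "participant_profile"
  )
}

#' Draw one participant's behavioral parameters from a study's priors
#'
#' Profiles are deterministically reproducible from `(config$seed, index)`:
#' each participant's draws come from an independently derived sub-seed, so
#' profile `i` does not depend on how many other profiles were drawn.
#'
#' @param config A [study_config()].
#' @param index 1-based participant index within the study.
#' @return An object of class `participant_profile`.
#' @export
draw_profile <- function(config, index) {
  stopifnot(inherits(config, "study_config"))
  stop_if_not_scalar_number(index, "index", lower = 1)
  sub <- derive_seed(config$seed, index, stream = 1L)
  with_seed(sub, {
    mu <- rnorm(1, config$habit_mean_prior[1], config$habit_mean_prior[2])
    rho <- runif(1, config$habit_persistence_prior[1], config$habit_persistence_prior[2])
    w <- config$weekday_amplitude *
      (WEEKDAY_PATTERN + rnorm(7, 0, 0.15))
    w <- w - mean(w)
    meanlog <- config$duration_lognorm[1] + rnorm(1, 0, 0.15)
    participant_profile(
      participant_id = sprintf("%s_p%02d", config$study_id, as.integer(index)),
      study_id = config$study_id,
      habit_mean = mu,
      persistence = rho,
      weekday_effects = w,
      drift = config$drift_per_day,
      duration_meanlog = meanlog,
      duration_sdlog = config$duration_lognorm[2],
      session_rate = config$session_rate,
      task_rate_per_min = config$task_rate_per_min,
      level_gain_rate = config$level_gain_rate,
      noise_sd = config$noise_sd,
      seed = derive_seed(config$seed, index, stream = 2L)
    )
  })
}

#' Simulate one participant's daily engagement records
#'
#' The latent habit follows `h_t = rho * h_{t-1} + (1 - rho) * mu + eps_t`
#' with `eps_t ~ N(0, sigma^2)` and `h_0 = mu`. Daily adherence propensity is
#' `logistic(h_t + w[dayofweek(t)] + drift * t)`; day `t` is adherent with
#' that probability. On adherent days, play duration is log-normal (minutes),
#' session count is `1 + Poisson(session_rate - 1)`, tasks completed is at
#' least 1 with Poisson mean `task_rate_per_min * duration`, and the maximum
#' level advances by a Poisson increment (capped at 58). On lapse days all
#' activity fields are zero and the level carries forward. Days are 1-based
#' and consecutive; day 1 is a Monday.
#'
#' @param profile A [draw_profile()] result.
#' @param n_days Number of consecutive days to simulate (positive integer).
#' @return A data.frame with one row per day and columns `participant_id`,
#'   `study_id`, `day_index`, `play_duration`, `session_count`, `max_level`,
#'   `tasks_completed`.
#' @export
simulate_participant <- function(profile, n_days) {
  stopifnot(inherits(profile, "participant_profile"))
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    stop("`n_days` must be a positive integer", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  with_seed(profile$seed, {
    h <- profile$habit_mean
    level <- 1L
    play <- numeric(n_days)
    sessions <- integer(n_days)
    levels <- integer(n_days)
    tasks <- integer(n_days)
    for (t in seq_len(n_days)) {
      h <- profile$persistence * h +
        (1 - profile$persistence) * profile$habit_mean +
        rnorm(1, 0, profile$noise_sd)
      dow <- ((t - 1L) %% 7L) + 1L
      prob <- logistic(h + profile$weekday_effects[dow] + profile$drift * t)
      adherent <- runif(1) < prob
      if (adherent) {
        play[t] <- rlnorm(1, profile$duration_meanlog, profile$duration_sdlog)
        sessions[t] <- 1L + rpois(1, max(profile$session_rate - 1, 0))
        tasks[t] <- max(1L, rpois(1, profile$task_rate_per_min * play[t]))
        level <- min(58L, level + rpois(1, profile$level_gain_rate))
      }
      levels[t] <- level
    }
    data.frame(
      participant_id = profile$participant_id,
      study_id = profile$study_id,
      day_index = seq_len(n_days),
      play_duration = play,
      session_count = sessions,
      max_level = levels,
      tasks_completed = tasks,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full synthetic study
#'
#' Draws `n_participants` profiles from the study's priors and simulates each
#' for `n_days` days. Profiles are returned alongside the records so the
#' generative ground truth is available to tests and diagnostics.
#'
#' @param config A [study_config()].
#' @return An object of class `cohort_study`: a list with `records` (one row
#'   per participant-day), `profiles` (list of `participant_profile`), and
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  profiles <- lapply(seq_len(config$n_participants), function(i) draw_profile(config, i))
  records <- do.call(rbind, lapply(profiles, simulate_participant, n_days = config$n_days))
  rownames(records) <- NULL
  structure(list(records = records, profiles = profiles, config = config),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  rate <- mean(x$records$play_duration >= 10)
  cat(sprintf("Synthetic study '%s': %d participants x %d days (%d rows), adherence rate %.3f\n",
              x$config$study_id, x$config$n_participants, x$config$n_days,
              nrow(x$records), rate))
  invisible(x)
}

#' @rdname simulate_study
#' @param object,nsim,seed,... Standard [stats::simulate()] arguments; `nsim`
#'   independent replicate studies are generated, reseeding the config with
#'   `seed` when supplied.
#' @export
simulate.study_config <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  out <- lapply(seq_len(nsim), function(r) {
    cfg <- object
    cfg$seed <- derive_seed(base_seed, r, stream = 3L)
    simulate_study(cfg)
  })
  if (nsim == 1) out[[1]] else out
}

#' Build the three-study benchmark suite with controllable domain shift
#'
#' Emits three study configs ("A", "B", "C") sharing a base parameterization
#' but displaced from one another in habit-mean location, weekday amplitude
#' and duration log-mean in proportion to `shift_strength`, then simulates
#' all three. `shift_strength = 0` yields exchangeable studies (identical
#' generative law, different seeds).
#'
#' @param master_seed Integer seed controlling all three studies.
#' @param shift_strength Nonnegative scale of between-study displacement;
#'   1 is the default benchmark condition.
#' @param n_participants,n_days Cohort dimensions per study.
#' @return A named list of three `cohort_study` objects (`A`, `B`, `C`),
#'   classed `benchmark_suite`.
#' @export
make_benchmark_suite <- function(master_seed, shift_strength = 1,
                                 n_participants = 24L, n_days = 60L) {
  if (!is.numeric(shift_strength) || length(shift_strength) != 1L ||
      !is.finite(shift_strength) || shift_strength < 0) {
    stop("`shift_strength` must be a nonnegative number", call. = FALSE)
  }
  # Per-study displacement of (habit-mean location, weekday amplitude,
  # duration meanlog) at shift_strength = 1.
  shifts <- list(
    A = c(0, 0, 0),
    B = c(-0.45, 0.50, -0.25),
    C = c(0.35, -0.30, 0.20)
  )
  studies <- lapply(names(shifts), function(id) {
    d <- shifts[[id]] * shift_strength
    cfg <- study_config(
      study_id = id,
      n_participants = n_participants,
      n_days = n_days,
      habit_mean_prior = c(0.5 + d[1], 0.8),
      weekday_amplitude = max(0, 1.2 + d[2]),
      duration_lognorm = c(log(30) + d[3], 0.55),
      seed = derive_seed(master_seed, match(id, names(shifts)), stream = 4L)
    )
    simulate_study(cfg)
  })
  names(studies) <- names(shifts)
  structure(studies, class = "benchmark_suite")
}

#' Write a study's daily records as tidy CSV
#'
#' One row per participant-day with columns `participant_id`, `study_id`,
#' `day_index`, `play_duration`, `session_count`, `max_level`,
#' `tasks_completed`. Ground-truth profiles can be written alongside.
#'
#' @param study A `cohort_study`.
#' @param file Output CSV path for the records.
#' @param profiles_file Optional CSV path for the ground-truth profile table.
#' @return `file`, invisibly.
#' @export
write_study_csv <- function(study, file, profiles_file = NULL) {
  stopifnot(inherits(study, "cohort_study"))
  utils::write.csv(study$records, file, row.names = FALSE, quote = FALSE)
  if (!is.null(profiles_file)) {
    prof <- do.call(rbind, lapply(study$profiles, function(p) {
      data.frame(
        participant_id = p$participant_id, study_id = p$study_id,
        habit_mean = p$habit_mean, persistence = p$persistence,
        t(stats::setNames(p$weekday_effects, paste0("weekday_", 1:7))),
        drift = p$drift, duration_meanlog = p$duration_meanlog,
        duration_sdlog = p$duration_sdlog, session_rate = p$session_rate,
        task_rate_per_min = p$task_rate_per_min,
        level_gain_rate = p$level_gain_rate, noise_sd = p$noise_sd,
        seed = p$seed, stringsAsFactors = FALSE
      )
    }))
    utils::write.csv(prof, profiles_file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' Read daily engagement records from CSV
#'
#' Reads the tidy dialect written by [write_study_csv()] and validates the
#' record invariants (consecutive 1-based days, jointly-zero activity fields,
#' non-decreasing level within participant).
#'
#' @param file CSV path.
#' @return A data.frame of daily records.
#' @export
read_records_csv <- function(file) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("participant_id", "study_id", "day_index", "play_duration",
              "session_count", "max_level", "tasks_completed")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    stop("records CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_records(rec)
  rec
}

#' @noRd
validate_records <- function(rec) {
  zero_play <- rec$play_duration == 0
  if (any(zero_play != (rec$session_count == 0)) ||
      any(zero_play != (rec$tasks_completed == 0))) {
    stop("activity fields must be jointly zero on non-adherent days", call. = FALSE)
  }
  if (any(rec$max_level < 1 | rec$max_level > 58)) {
    stop("max_level must lie in [1, 58]", call. = FALSE)
  }
  for (pid in unique(rec$participant_id)) {
    sub <- rec[rec$participant_id == pid, ]
    sub <- sub[order(sub$day_index), ]
    if (!identical(as.integer(sub$day_index), seq_len(nrow(sub)))) {
      stop(sprintf("participant %s: day_index must be 1-based and consecutive", pid),
           call. = FALSE)
    }
    if (is.unsorted(sub$max_level)) {
      stop(sprintf("participant %s: max_level must be non-decreasing", pid),
           call. = FALSE)
    }
  }
  invisible(rec)
}
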