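# Shared fixtures: everything is generated in code at test time.

# A deterministic flat-propensity profile: rho = sigma = drift = 0, no
# weekday structure, so P(adherent day) = logistic(habit_mean) exactly.
flat_profile <- function(mu, seed = 1L, ...) {
  participant_profile(participant_id = sprintf("flat_mu%+.1f", mu),
                      habit_mean = mu, persistence = 0, noise_sd = 0,
                      weekday_effects = rep(0, 7), drift = 0, seed = seed, ...)
}

# A small net spec for fast training tests.
tiny_net_spec <- function(seed = 1L) {
  adherence_net_spec(conv_channels = c(6L, 8L), hidden_units = 12L, seed = seed)
}

# A short schedule for fast training tests.
tiny_schedule <- function(max_epochs = 25L) {
  optimizer_schedule(max_epochs = max_epochs, early_stop_patience = 5L)
}

# Records for one participant where every day is identical (constant input).
constant_records <- function(n_days = 60, play = 20) {
  data.frame(
    participant_id = "const", study_id = "S", day_index = seq_len(n_days),
    play_duration = play, session_count = 2L, max_level = 5L,
    tasks_completed = 10L, stringsAsFactors = FALSE
  )
}

# A linearly separable toy window problem: class 1 windows are all +1,
# class 0 windows all -1 (constant over days and channels).
separable_windows <- function(n_per_class = 8, N = 7, C = 4) {
  n <- 2 * n_per_class
  x <- array(rep(c(-1, 1), each = n_per_class * N * C), dim = c(n, N, C))
  for (i in seq_len(n)) x[i, , ] <- if (i <= n_per_class) -1 else 1
  structure(list(x = x, y = rep(c(0L, 1L), each = n_per_class),
                 target_day = seq_len(n), participant_id = rep("toy", n)),
            class = "window_set")
}

# A small prepared two-study scenario for pipeline tests.
small_prepared_pair <- function(seed = 5, n_participants = 4) {
  suite <- make_benchmark_suite(seed, shift_strength = 1,
                                n_participants = n_participants)
  list(source = prepare_study(suite$A), target = prepare_study(suite$B),
       suite = suite)
}
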