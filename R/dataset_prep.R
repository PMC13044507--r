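# Sliding-window dataset preparation: adherence labeling at the 10-minute
# threshold, per-participant standardization from training days only, and
# chronological train/validation/test splits.

#' Splitting and windowing parameters
#'
#' @param train_days Days in the training segment (default 30).
#' @param test_days Days in the test segment (default 30).
#' @param val_fraction Fraction of training windows held out for validation,
#'   taken chronologically from the end of the training segment (default 0.15).
#' @param window_size Number of past days whose features predict the next
#'   day's adherence (default 7).
#' @param threshold Minutes of play at or above which a day counts as
#'   adherent (default 10).
#' @param scaling Feature normalization. `"fixed"` (default) divides each
#'   channel by an a-priori constant anchored to the prescription and game
#'   design (45 min/day dose, ~3 sessions, 58 levels, ~30 tasks), which
#'   conditions optimization while preserving each participant's engagement
#'   level — the information pooled models need. `"participant"` z-scores
#'   each channel with that participant's training-day statistics (level
#'   information is removed; kept for sensitivity checks). `"none"` leaves
#'   raw values.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_days = 30L, test_days = 30L, val_fraction = 0.15,
                       window_size = 7L, threshold = 10,
                       scaling = c("fixed", "participant", "none")) {
  scaling <- match.arg(scaling)
  stop_if_not_scalar_number(train_days, "train_days", lower = 2)
  stop_if_not_scalar_number(test_days, "test_days", lower = 1)
  stop_if_not_scalar_number(val_fraction, "val_fraction")
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_number(window_size, "window_size", lower = 1)
  stop_if_not_scalar_number(threshold, "threshold", lower = 0)
  if (train_days < window_size + 1) {
    stop("`train_days` must be at least `window_size` + 1 so a training window exists",
         call. = FALSE)
  }
  structure(
    list(train_days = as.integer(train_days), test_days = as.integer(test_days),
         val_fraction = val_fraction, window_size = as.integer(window_size),
         threshold = threshold, scaling = scaling),
    class = "split_spec"
  )
}

# A-priori per-channel divisors for scaling = "fixed": the prescribed daily
# dose (45 min), a typical session count, the known level range (1..58) and
# a typical task count. Constants, so no statistic is estimated anywhere.
FIXED_CHANNEL_SCALE <- c(play_duration = 45, session_count = 3,
                         max_level = 58, tasks_completed = 30)

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Split spec: %d train / %d test days, window %d, threshold %.1f min, val fraction %.2f, scaling '%s'\n",
              x$train_days, x$test_days, x$window_size, x$threshold,
              x$val_fraction, x$scaling))
  invisible(x)
}

# Channel order is fixed across the whole pipeline.
FEATURE_CHANNELS <- c("play_duration", "session_count", "max_level", "tasks_completed")

#' Label a day as adherent or lapsed
#'
#' A day is adherent (label 1) when play duration is at least `threshold`
#' minutes; the boundary value itself is adherent.
#'
#' @param play_duration Minutes played (nonnegative; vectorized).
#' @param threshold Adherence threshold in minutes (default 10).
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' label_adherence(c(0, 9.99, 10, 45))
label_adherence <- function(play_duration, threshold = 10) {
  if (any(!is.finite(play_duration)) || any(play_duration < 0)) {
    stop("`play_duration` must be finite and nonnegative", call. = FALSE)
  }
  as.integer(play_duration >= threshold)
}

#' Build labeled sliding windows with a chronological split
#'
#' For one participant's day-ordered records, every target day `t` yields an
#' example whose features are the `window_size` preceding days (4 channels:
#' play duration, session count, maximum level, tasks completed) and whose
#' label is day `t`'s adherence. Training windows target days
#' `window_size + 1 ... train_days`; the chronologically last
#' `ceiling(val_fraction * n_train)` of them form the validation set. Test
#' windows target days `train_days + 1 ... train_days + test_days`; their
#' feature history may reach back into the training segment, as at
#' deployment. Channels are normalized according to `spec$scaling`: fixed
#' a-priori divisors by default, or per-participant z-scoring with mean and
#' SD of the training days only, under which a zero-variance channel maps to
#' all zeros and is recorded in `$zero_variance_channels`.
#'
#' @param records Data.frame of one participant's daily records (the dialect
#'   of [simulate_participant()] / [read_records_csv()]).
#' @param spec A [split_spec()].
#' @return A list of class `prepared_participant` with elements `train`,
#'   `val`, `test` (each a `window_set`: feature array `x` of dim
#'   `n x window_size x 4`, labels `y`, `target_day`, `participant_id`),
#'   `scaling` (per-channel center/scale) and `zero_variance_channels`.
#' @export
make_windows <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  pid <- unique(records$participant_id)
  if (length(pid) != 1L) {
    stop("`records` must contain exactly one participant", call. = FALSE)
  }
  need <- spec$train_days + spec$test_days
  if (nrow(records) < need) {
    stop(sprintf("participant %s has %d days; %d are required for the %d/%d split",
                 pid, nrow(records), need, spec$train_days, spec$test_days),
         call. = FALSE)
  }
  records <- records[order(records$day_index), , drop = FALSE][seq_len(need), , drop = FALSE]
  feat <- as.matrix(records[, FEATURE_CHANNELS])
  labels <- label_adherence(records$play_duration, spec$threshold)

  train_idx <- seq_len(spec$train_days)
  zero_var <- character(0)
  if (spec$scaling == "participant") {
    center <- colMeans(feat[train_idx, , drop = FALSE])
    scale_ <- apply(feat[train_idx, , drop = FALSE], 2, stats::sd)
    zero_var <- FEATURE_CHANNELS[scale_ == 0]
    scale_[scale_ == 0] <- 1
  } else if (spec$scaling == "fixed") {
    center <- stats::setNames(numeric(length(FEATURE_CHANNELS)), FEATURE_CHANNELS)
    scale_ <- FIXED_CHANNEL_SCALE
  } else {
    center <- stats::setNames(numeric(length(FEATURE_CHANNELS)), FEATURE_CHANNELS)
    scale_ <- stats::setNames(rep(1, length(FEATURE_CHANNELS)), FEATURE_CHANNELS)
  }
  z <- sweep(sweep(feat, 2, center), 2, scale_, "/")

  build <- function(target_days) {
    n <- length(target_days)
    x <- array(0, dim = c(n, spec$window_size, length(FEATURE_CHANNELS)))
    for (i in seq_len(n)) {
      t <- target_days[i]
      x[i, , ] <- z[(t - spec$window_size):(t - 1L), , drop = FALSE]
    }
    structure(list(x = x, y = labels[target_days],
                   target_day = as.integer(target_days),
                   participant_id = rep(pid, n)),
              class = "window_set")
  }

  train_targets <- seq(spec$window_size + 1L, spec$train_days)
  n_val <- ceiling(spec$val_fraction * length(train_targets))
  val_targets <- utils::tail(train_targets, n_val)
  fit_targets <- utils::head(train_targets, length(train_targets) - n_val)
  test_targets <- seq(spec$train_days + 1L, spec$train_days + spec$test_days)

  structure(
    list(train = build(fit_targets), val = build(val_targets),
         test = build(test_targets),
         all_train = build(train_targets),
         scaling = list(center = center, scale = scale_),
         zero_variance_channels = zero_var,
         spec = spec),
    class = "prepared_participant"
  )
}

#' Number of windows in a window set
#' @param x A `window_set`.
#' @param ... Unused.
#' @export
length.window_set <- function(x) as.integer(unname(dim(x$x)[1]))

#' Concatenate window sets (pooling across participants)
#' @param ... `window_set` objects with identical window dimensions.
#' @return A single pooled `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, logical(1), "window_set")))
  dims <- vapply(sets, function(s) dim(s$x)[2:3], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("window sets have incompatible dimensions", call. = FALSE)
  }
  n <- sum(vapply(sets, length, integer(1)))
  x <- array(0, dim = c(n, dims[1, 1], dims[2, 1]))
  at <- 0L
  for (s in sets) {
    k <- length(s)
    if (k > 0) x[at + seq_len(k), , ] <- s$x
    at <- at + k
  }
  structure(list(
    x = x,
    y = unlist(lapply(sets, `[[`, "y"), use.names = FALSE),
    target_day = unlist(lapply(sets, `[[`, "target_day"), use.names = FALSE),
    participant_id = unlist(lapply(sets, `[[`, "participant_id"), use.names = FALSE)
  ), class = "window_set")
}

#' Prepare every participant of a study
#'
#' @param study A `cohort_study` or a records data.frame covering several
#'   participants.
#' @param spec A [split_spec()].
#' @return Named list of `prepared_participant`, one per participant.
#' @export
prepare_study <- function(study, spec = split_spec()) {
  records <- if (inherits(study, "cohort_study")) study$records else study
  ids <- unique(records$participant_id)
  out <- lapply(ids, function(pid) {
    make_windows(records[records$participant_id == pid, , drop = FALSE], spec)
  })
  names(out) <- ids
  out
}

#' Pool training and validation windows across prepared participants
#'
#' @param prepared Named list from [prepare_study()].
#' @param exclude Participant ids to drop before pooling (e.g. the held-out
#'   target participant during fine-tuning).
#' @return List with pooled `train` and `val` window sets.
#' @export
pool_windows <- function(prepared, exclude = character(0)) {
  keep <- setdiff(names(prepared), exclude)
  if (!length(keep)) stop("no participants left after exclusion", call. = FALSE)
  list(
    train = bind_window_sets(lapply(prepared[keep], `[[`, "train")),
    val = bind_window_sets(lapply(prepared[keep], `[[`, "val"))
  )
}
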