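# Evaluation: per-participant confusion metrics, unweighted across-participant
# aggregation ("mean (SD)" per metric), and the paired one-tailed t and
# Wilcoxon signed-rank comparisons between experimental arms.

#' Confusion-matrix metrics for one participant
#'
#' Positive class is adherent (1). When precision or recall has a zero
#' denominator the metric scores 0 and the participant is flagged degenerate
#' rather than excluded, so across-participant means stay unbiased.
#'
#' @param predictions,labels Equal-length binary (0/1) vectors.
#' @return List with `accuracy`, `precision`, `recall`, `f1`,
#'   `degenerate_flag`, `n`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length", call. = FALSE)
  }
  if (length(labels) < 1L) stop("need at least one prediction", call. = FALSE)
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1))) {
    stop("predictions and labels must be binary 0/1", call. = FALSE)
  }
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if ((tp + fp) == 0) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1, degenerate_flag = degenerate,
       n = length(labels))
}

#' Aggregate per-participant metrics into a cohort report
#'
#' Cohort scores are the unweighted arithmetic mean and the sample SD (n - 1
#' denominator) of per-participant values; participants are not weighted by
#' their test-window counts. A single participant yields SD 0 with a warning.
#'
#' @param per_participant Data.frame with columns `participant_id`,
#'   `accuracy`, `precision`, `recall`, `f1`, `n_test_windows`,
#'   `degenerate_flag`.
#' @param arm_label Label of the experimental arm (e.g. `"no_source"`,
#'   `"sfda"`).
#' @return An object of class `eval_report`.
#' @export
aggregate_report <- function(per_participant, arm_label = "arm") {
  if (!is.data.frame(per_participant) || nrow(per_participant) < 1L) {
    stop("`per_participant` must be a non-empty data.frame", call. = FALSE)
  }
  metrics <- c("accuracy", "precision", "recall", "f1")
  stopifnot(all(metrics %in% names(per_participant)))
  if (nrow(per_participant) == 1L) {
    warning("single participant: SD reported as 0")
  }
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_participant[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) {
      if (nrow(per_participant) == 1L) 0 else stats::sd(per_participant[[m]])
    }, numeric(1)),
    row.names = NULL
  )
  structure(list(per_participant = per_participant, aggregate = agg,
                 arm_label = arm_label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report: arm '%s', %d participants\n",
              x$arm_label, nrow(x$per_participant)))
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-9s %.3f (SD %.3f)\n", a$metric[i], a$mean[i], a$sd[i]))
  }
  n_deg <- sum(x$per_participant$degenerate_flag)
  if (n_deg > 0) cat(sprintf("  (%d participant(s) flagged degenerate)\n", n_deg))
  invisible(x)
}

pair_by_participant <- function(a, b, participants_a, participants_b) {
  if (is.null(participants_a) || is.null(participants_b)) {
    if (length(a) != length(b)) stop("unpaired inputs of unequal length", call. = FALSE)
    return(list(a = a, b = b))
  }
  common <- intersect(participants_a, participants_b)
  list(a = a[match(common, participants_a)], b = b[match(common, participants_b)])
}

#' Paired one-tailed t test (arm A greater than arm B)
#'
#' Closed form on per-participant differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, one-tailed p from the t distribution
#' with `n - 1` degrees of freedom, alternative `mean(d) > 0`. All-zero
#' differences return p = 0.5 with a degenerate-variance warning; zero
#' variance around a nonzero mean returns p = 0 or 1.
#'
#' @param a,b Per-participant scores of the two arms (e.g. SFDA and
#'   no-source accuracies).
#' @param participants_a,participants_b Optional ids; pairing is by id (the
#'   intersection) when given, by position otherwise.
#' @return List with `t_statistic`, `p_value`, `n_pairs`, `mean_difference`.
#' @export
paired_one_tailed_t <- function(a, b, participants_a = NULL, participants_b = NULL) {
  pr <- pair_by_participant(a, b, participants_a, participants_b)
  d <- pr$a - pr$b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    warning("degenerate variance: all paired differences are equal")
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    t_stat <- if (mean(d) == 0) NaN else sign(mean(d)) * Inf
    return(list(t_statistic = t_stat, p_value = p, n_pairs = n,
                mean_difference = mean(d)))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_statistic = t_stat,
       p_value = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
       n_pairs = n, mean_difference = mean(d))
}

#' Paired Wilcoxon signed-rank test (arm A greater than arm B)
#'
#' Zero differences are dropped before ranking (standard signed-rank
#' convention). The reported statistic is the negative-rank sum; small values
#' support the one-sided alternative `a > b`. The null distribution is exact
#' for n <= 25 without ties in |d|, and a normal approximation with
#' continuity and tie corrections otherwise.
#'
#' @inheritParams paired_one_tailed_t
#' @return List with `statistic` (negative-rank sum), `p_value`, `n_pairs`
#'   (after zero-drop), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(a, b, participants_a = NULL, participants_b = NULL) {
  pr <- pair_by_participant(a, b, participants_a, participants_b)
  d <- pr$a - pr$b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all paired differences are zero: signed-rank test undefined", call. = FALSE)
  }
  r <- rank(abs(d))
  v_neg <- sum(r[d < 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25L && !has_ties) {
    p <- stats::psignrank(v_neg, n)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    p <- stats::pnorm((v_neg - mu + 0.5) / sqrt(sigma2))
    exact <- FALSE
  }
  list(statistic = v_neg, p_value = p, n_pairs = n, exact = exact)
}

#' Run one source/target experiment over the full protocol
#'
#' For every participant of the target study: (1) the no-source baseline is
#' trained on that participant's own retained training windows; (2) the
#' source model (trained once on the pooled source study) is fine-tuned on
#' the pooled target study excluding the participant, then adapted to the
#' participant source-free by local structure clustering. Both arms — plus
#' the fine-tuned-unadapted model, kept for stability diagnostics — are
#' evaluated on the participant's identical test windows, metrics are
#' aggregated unweighted across participants, and the SFDA and no-source
#' accuracies are compared with the paired one-tailed t and Wilcoxon
#' signed-rank tests.
#'
#' @param suite A `benchmark_suite` (or any named list of `cohort_study`).
#' @param source,target Study names; must differ.
#' @param split A [split_spec()].
#' @param net_spec An [adherence_net_spec()].
#' @param schedule An [optimizer_schedule()].
#' @param adapt An [lsc_config()].
#' @param seed Integer master seed.
#' @return An object of class `sfda_experiment`: reports per arm, paired
#'   comparisons on accuracy, and the per-participant score table.
#' @export
run_experiment <- function(suite, source, target,
                           split = split_spec(),
                           net_spec = adherence_net_spec(),
                           schedule = optimizer_schedule(),
                           adapt = lsc_config(),
                           seed = 1L) {
  if (identical(source, target)) stop("source and target studies must differ", call. = FALSE)
  stopifnot(source %in% names(suite), target %in% names(suite))
  prepared_source <- prepare_study(suite[[source]], split)
  prepared_target <- prepare_study(suite[[target]], split)

  source_net <- train_source_model(prepared_source, net_spec, schedule,
                                   seed = derive_seed(seed, 1L, stream = 30L))
  ids <- names(prepared_target)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    prep <- prepared_target[[pid]]
    test <- prep$test

    baseline <- train_no_source_baseline(prep, net_spec, schedule,
                                         seed = derive_seed(seed, i, stream = 31L))
    finetuned <- finetune_on_target_study(source_net, prepared_target, pid,
                                          schedule,
                                          seed = derive_seed(seed, i, stream = 32L))
    cfg <- adapt
    cfg$seed <- derive_seed(seed, i, stream = 33L)
    adapted <- adapt_to_participant(finetuned, prep, cfg)

    one_arm <- function(net) {
      m <- confusion_metrics(predict(net, test, type = "class"), test$y)
      data.frame(participant_id = pid, accuracy = m$accuracy,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 n_test_windows = m$n, degenerate_flag = m$degenerate_flag,
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- list(no_source = one_arm(baseline),
                      finetuned = one_arm(finetuned),
                      sfda = one_arm(adapted))
  }
  arm_table <- function(arm) do.call(rbind, lapply(rows, `[[`, arm))
  tabs <- list(no_source = arm_table("no_source"),
               finetuned = arm_table("finetuned"),
               sfda = arm_table("sfda"))
  reports <- lapply(names(tabs), function(a) aggregate_report(tabs[[a]], a))
  names(reports) <- names(tabs)
  comparison <- list(
    t = paired_one_tailed_t(tabs$sfda$accuracy, tabs$no_source$accuracy,
                            tabs$sfda$participant_id, tabs$no_source$participant_id),
    wilcoxon = wilcoxon_signed_rank(tabs$sfda$accuracy, tabs$no_source$accuracy,
                                    tabs$sfda$participant_id, tabs$no_source$participant_id)
  )
  structure(list(source = source, target = target, reports = reports,
                 comparison = comparison, seed = seed),
            class = "sfda_experiment")
}

#' @export
print.sfda_experiment <- function(x, ...) {
  cat(sprintf("Source %s -> target %s (%d target participants)\n",
              x$source, x$target, nrow(x$reports$sfda$per_participant)))
  for (arm in names(x$reports)) {
    a <- x$reports[[arm]]$aggregate
    cat(sprintf("  %-10s", arm))
    cat(paste(sprintf("%s %.3f (%.3f)", a$metric, a$mean, a$sd), collapse = "  "), "\n")
  }
  cat(sprintf("  SFDA vs no-source accuracy: mean gain %+.3f, t = %.3f (p = %.4g), Wilcoxon W- = %.1f (p = %.4g)\n",
              x$comparison$t$mean_difference, x$comparison$t$t_statistic,
              x$comparison$t$p_value, x$comparison$wilcoxon$statistic,
              x$comparison$wilcoxon$p_value))
  invisible(x)
}

#' @export
summary.sfda_experiment <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Paired accuracy plot for one experiment
#'
#' Draws each target participant's test accuracy under the no-source baseline
#' and under SFDA, joined by a segment; rising segments are participants the
#' adaptation helped.
#'
#' @param x An `sfda_experiment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sfda_experiment <- function(x, ...) {
  ns <- x$reports$no_source$per_participant$accuracy
  sf <- x$reports$sfda$per_participant$accuracy
  n <- length(ns)
  graphics::plot(NA, xlim = c(0.8, 2.2), ylim = range(c(ns, sf, 0, 1)),
                 xaxt = "n", xlab = "", ylab = "test accuracy",
                 main = sprintf("Source %s -> target %s", x$source, x$target), ...)
  graphics::axis(1, at = c(1, 2), labels = c("no source", "SFDA"))
  graphics::segments(1, ns, 2, sf, col = ifelse(sf >= ns, "grey40", "indianred"))
  graphics::points(rep(1, n), ns, pch = 19)
  graphics::points(rep(2, n), sf, pch = 19)
  invisible(x)
}

#' One-shot synthetic benchmark reproduction
#'
#' Generates the default three-study benchmark and runs the full experiment
#' for each requested (source, target) role assignment.
#'
#' @param seed Integer master seed (controls the cohort and all training).
#' @param shift_strength Between-study domain shift (default 1).
#' @param roles List of `c(source, target)` study-name pairs.
#' @param n_participants,n_days Cohort dimensions per study.
#' @param ... Passed on to [run_experiment()] (e.g. `adapt`, `schedule`).
#' @return Named list of `sfda_experiment` objects (`"A->B"` etc.).
#' @export
reproduce_benchmark <- function(seed, shift_strength = 1,
                                roles = list(c("A", "B"), c("B", "C")),
                                n_participants = 24L, n_days = 60L, ...) {
  suite <- make_benchmark_suite(seed, shift_strength,
                                n_participants = n_participants, n_days = n_days)
  out <- lapply(roles, function(r) {
    run_experiment(suite, r[1], r[2], seed = derive_seed(seed, match(r[2], names(suite)),
                                                         stream = 40L), ...)
  })
  names(out) <- vapply(roles, function(r) paste0(r[1], "->", r[2]), character(1))
  out
}
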