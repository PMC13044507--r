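# Exhaustive enumeration oracle for the one-sided signed-rank p value:
# P(negative-rank sum <= observed) over all 2^n sign assignments.
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  stats <- apply(signs, 1, function(neg) sum(r[neg]))
  mean(stats <= obs)
}

test_that("confusion metrics match a hand-computed confusion matrix", {
  labels <- c(rep(1, 5), rep(0, 5))           # TP+FN = 5, FP+TN = 5
  preds <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)    # TP=3 FN=2 FP=1 TN=4
  m <- confusion_metrics(preds, labels)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_false(m$degenerate_flag)
})

test_that("perfect and degenerate predictions hit the documented conventions", {
  p <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(p[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  d <- confusion_metrics(c(0, 0, 0), c(0, 1, 0))
  expect_equal(d$precision, 0)
  expect_true(d$degenerate_flag)
  expect_error(confusion_metrics(c(1, 0), c(1)), "equal length")
  expect_error(confusion_metrics(c(2, 0), c(1, 0)), "binary")
})

test_that("aggregation is the unweighted mean with sample SD, order-invariant", {
  tab <- data.frame(participant_id = c("a", "b"),
                    accuracy = c(0.6, 0.8), precision = c(0.5, 0.7),
                    recall = c(0.4, 0.6), f1 = c(0.44, 0.65),
                    n_test_windows = c(30L, 10L), degenerate_flag = FALSE)
  rep1 <- aggregate_report(tab, "arm")
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "accuracy"], 0.7)
  expect_equal(rep1$aggregate$sd[rep1$aggregate$metric == "accuracy"],
               sd(c(0.6, 0.8)))  # 0.1414..., n - 1 denominator
  rep2 <- aggregate_report(tab[2:1, ], "arm")
  expect_equal(rep1$aggregate, rep2$aggregate)
  expect_warning(aggregate_report(tab[1, , drop = FALSE]), "single participant")
})

test_that("the paired one-tailed t test matches its closed form and stats::t.test", {
  d <- c(0.2, 0.0, 0.1, 0.3, -0.1)
  a <- d + 0.5; b <- rep(0.5, 5)
  res <- paired_one_tailed_t(a, b)
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  ref <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(res$t_statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
  expect_warning(z <- paired_one_tailed_t(rep(0.1, 4) + 1, rep(1, 4)), "degenerate")
  expect_equal(z$p_value, 0)
  expect_warning(z0 <- paired_one_tailed_t(rep(1, 4), rep(1, 4)), "degenerate")
  expect_equal(z0$p_value, 0.5)
  expect_error(paired_one_tailed_t(1, 2), "at least 2 pairs")
})

test_that("pairing is by participant id when ids are supplied", {
  res <- paired_one_tailed_t(c(0.9, 0.8, 0.4), c(0.3, 0.7, 0.6),
                             participants_a = c("p1", "p2", "p9"),
                             participants_b = c("p2", "p1", "p9"))
  # p1: 0.9 - 0.7, p2: 0.8 - 0.3, p9: 0.4 - 0.6
  expect_equal(res$n_pairs, 3)
  expect_equal(res$mean_difference, mean(c(0.2, 0.5, -0.2)))
})

test_that("the signed-rank test matches exhaustive enumeration on small samples", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5)),
               list(statistic = 0, p_value = 1 / 32, n_pairs = 5L, exact = TRUE))
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    res <- wilcoxon_signed_rank(d + 10, rep(10, length(d)))
    expect_equal(res$p_value, enumerate_signrank_p(d), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "undefined")
})

test_that("both tests match the reference implementations on random samples", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    a <- rnorm(n, 0.05, 0.2)
    b <- rnorm(n, 0, 0.2)
    t_ref <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
    t_mine <- paired_one_tailed_t(a, b)
    expect_equal(t_mine$t_statistic, unname(t_ref$statistic), tolerance = 1e-8)
    expect_equal(t_mine$p_value, t_ref$p.value, tolerance = 1e-8)
    w_mine <- wilcoxon_signed_rank(a, b)
    w_ref <- suppressWarnings(stats::wilcox.test(
      a, b, paired = TRUE, alternative = "greater",
      exact = w_mine$exact, correct = TRUE))
    # reference reports the positive-rank sum; ours the negative-rank sum
    expect_equal(w_mine$statistic, n * (n + 1) / 2 - unname(w_ref$statistic),
                 tolerance = 1e-8)
    expect_equal(w_mine$p_value, w_ref$p.value, tolerance = 1e-8)
  }
})

test_that("type-I error of the paired t is calibrated under the null", {
  set.seed(21)
  pvals <- replicate(400, paired_one_tailed_t(rnorm(10), rnorm(10))$p_value)
  rate <- mean(pvals <= 0.1)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / 400))
})

test_that("the experiment driver shares test windows across arms and is role-sensitive", {
  suite <- make_benchmark_suite(3, shift_strength = 1, n_participants = 3)
  sch <- optimizer_schedule(max_epochs = 8, early_stop_patience = 3)
  cfg <- lsc_config(adapt_epochs = 3)
  ab <- run_experiment(suite, "A", "B", schedule = sch, adapt = cfg,
                       net_spec = tiny_net_spec(), seed = 5)
  expect_s3_class(ab, "sfda_experiment")
  tabs <- lapply(ab$reports, `[[`, "per_participant")
  expect_identical(tabs$sfda$participant_id, tabs$no_source$participant_id)
  expect_identical(tabs$sfda$n_test_windows, tabs$no_source$n_test_windows)
  expect_equal(ab$comparison$t$n_pairs, 3)
  ba <- run_experiment(suite, "B", "A", schedule = sch, adapt = cfg,
                       net_spec = tiny_net_spec(), seed = 5)
  expect_false(identical(ab$reports$sfda$aggregate, ba$reports$sfda$aggregate))
  expect_error(run_experiment(suite, "A", "A"), "must differ")
})
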