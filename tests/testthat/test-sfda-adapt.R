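unit_row <- function(theta) c(cos(theta), sin(theta))

manual_banks <- function(feats) {
  structure(list(feature_bank = feats,
                 score_bank = matrix(0.5, nrow(feats), 2)),
            class = "memory_banks")
}

test_that("memory banks have aligned rows, unit norms, and are deterministic", {
  pair <- small_prepared_pair()
  net <- build_adherence_net(tiny_net_spec())
  prep <- pair$target[[1]]
  banks <- build_banks(net, prep$all_train, k_neighbors = 3)
  expect_equal(dim(banks$feature_bank), c(23, 12))
  expect_equal(dim(banks$score_bank), c(23, 2))
  nrm <- sqrt(rowSums(banks$feature_bank^2))
  expect_true(all(abs(nrm - 1) < 1e-6 | nrm == 0))
  expect_equal(rowSums(banks$score_bank), rep(1, 23), tolerance = 1e-9)
  expect_identical(banks, build_banks(net, prep$all_train, k_neighbors = 3))
  few <- prep$all_train
  few$x <- few$x[1:3, , , drop = FALSE]
  expect_error(build_banks(net, few, k_neighbors = 3), "at least 4")
})

test_that("neighbor search picks the closest rows by cosine similarity", {
  b <- manual_banks(rbind(unit_row(0), unit_row(10 * pi / 180), unit_row(pi / 2)))
  expect_identical(find_neighbors(b, 1, 1), 2L)
  expect_identical(find_neighbors(b, 1, 2), c(2L, 3L))
  # duplicates: self excluded, the duplicate row returned first
  b2 <- manual_banks(rbind(unit_row(0), unit_row(0), unit_row(1)))
  expect_identical(find_neighbors(b2, 1, 2), c(2L, 3L))
  expect_error(find_neighbors(b, 1, 3), "smaller than the bank size")
})

test_that("neighbor search agrees exactly with O(n^2) brute force", {
  set.seed(9)
  f <- matrix(rnorm(60 * 5), 60, 5)
  f <- f / sqrt(rowSums(f^2))
  b <- manual_banks(f)
  for (i in c(1, 17, 60)) {
    sims <- as.numeric(f %*% f[i, ])
    sims[i] <- -Inf
    brute <- order(-sims, seq_len(60))
    for (k in c(1, 4, 59)) {
      expect_identical(find_neighbors(b, i, k), brute[seq_len(k)])
    }
  }
})

test_that("the LSC loss rewards neighbor agreement and penalizes collapse", {
  # two windows, mutual neighbors, identical confident predictions
  p <- rbind(c(1, 0), c(1, 0))
  q <- array(0, c(2, 1, 2)); q[, 1, ] <- p
  expect_equal(lsc_loss(p, q, lambda = 0), -1)
  # orthogonal predictions: agreement term vanishes
  p2 <- rbind(c(1, 0), c(0, 1))
  q2 <- array(0, c(2, 1, 2)); q2[1, 1, ] <- p2[2, ]; q2[2, 1, ] <- p2[1, ]
  expect_equal(lsc_loss(p2, q2, lambda = 0), 0)
  # uniform batch marginal minimizes the diversity term at -lambda * log(2)
  expect_equal(lsc_loss(p2, q2, lambda = 1.5), -1.5 * log(2))
  expect_error(lsc_loss(rbind(c(2, 0)), array(0.5, c(1, 1, 2))), "probability")
})

test_that("adaptation with zero epochs or too few windows returns the checkpoint", {
  pair <- small_prepared_pair()
  net <- build_adherence_net(tiny_net_spec())
  prep <- pair$target[[1]]
  same <- adapt_to_participant(net, prep, lsc_config(adapt_epochs = 0))
  expect_identical(same$params, net$params)
  few <- prep$all_train
  few$x <- few$x[1:3, , , drop = FALSE]; few$y <- few$y[1:3]
  expect_warning(out <- adapt_to_participant(net, few, lsc_config(k_neighbors = 3)),
                 "unadapted")
  expect_identical(out$params, net$params)
})

test_that("adaptation never reads target labels (poisoned-sentinel audit)", {
  pair <- small_prepared_pair()
  net <- build_adherence_net(tiny_net_spec())
  clean <- pair$target[[1]]$all_train
  poisoned <- clean
  poisoned$y <- rep(999L, length(poisoned))   # invalid labels must not matter
  cfg <- lsc_config(adapt_epochs = 5, seed = 2)
  a <- adapt_to_participant(net, clean, cfg)
  b <- adapt_to_participant(net, poisoned, cfg)
  expect_identical(a$params, b$params)
})

test_that("the adaptation interface admits no source-study data", {
  # source-freedom is structural: the only inputs are a checkpoint, the
  # target participant's windows, and the config.
  expect_named(formals(adapt_to_participant), c("net", "windows", "config"))
})

test_that("a frozen classifier head stays frozen during adaptation", {
  pair <- small_prepared_pair()
  net <- build_adherence_net(tiny_net_spec())
  out <- adapt_to_participant(net, pair$target[[1]], lsc_config(adapt_epochs = 5))
  expect_identical(out$params$W4, net$params$W4)
  expect_identical(out$params$b4, net$params$b4)
  expect_false(identical(out$params$W1, net$params$W1))
  full <- adapt_to_participant(net, pair$target[[1]],
                               lsc_config(adapt_epochs = 5, freeze_classifier = FALSE))
  expect_false(identical(full$params$W4, net$params$W4))
})

test_that("reciprocal weighting down-weights non-reciprocal neighbors", {
  pair <- small_prepared_pair()
  net <- build_adherence_net(tiny_net_spec())
  cfg_l <- lsc_config(adapt_epochs = 5, seed = 3, variant = "lsc")
  cfg_r <- lsc_config(adapt_epochs = 5, seed = 3, variant = "reciprocal")
  a <- adapt_to_participant(net, pair$target[[1]], cfg_l)
  b <- adapt_to_participant(net, pair$target[[1]], cfg_r)
  expect_false(identical(a$params, b$params))
})

test_that("LSC adaptation raises label purity on the shifted two-cluster toy", {
  r <- lsc_toy_experiment(seed = 1)
  expect_gt(r$purity_after, r$purity_before)
})
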