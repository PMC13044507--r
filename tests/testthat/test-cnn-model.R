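# Independent oracle: O(n*m) brute-force sliding dot product.
brute_conv <- function(f, g) {
  n <- length(f); m <- length(g)
  vapply(seq_len(n - m + 1), function(i) sum(f[i:(i + m - 1)] * g), numeric(1))
}

test_that("conv1d_valid matches hand examples and rejects long kernels", {
  expect_equal(conv1d_valid(c(5, -2, 7), 1), c(5, -2, 7))
  expect_equal(conv1d_valid(c(1, 2, 3, 4), c(1, 0)), c(1, 2, 3))
  expect_equal(conv1d_valid(c(1, 2, 3), c(1, 1)), c(3, 5))
  expect_error(conv1d_valid(c(1, 2), c(1, 2, 3)), "exceeds")
})

test_that("conv1d_valid agrees with the brute-force oracle on random pairs", {
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    m <- sample(seq_len(n), 1)
    f <- rnorm(n); g <- rnorm(m)
    expect_equal(conv1d_valid(f, g), brute_conv(f, g), tolerance = 1e-12)
  }
})

test_that("the spec validates window survival through the conv/pool stack", {
  expect_error(adherence_net_spec(kernel_sizes = c(8L, 2L)), "conv block 1")
  expect_error(adherence_net_spec(pool_sizes = c(1L, 8L)), "pool block 2")
  s <- adherence_net_spec()
  expect_equal(unname(s$lengths), c(5L, 5L, 4L, 2L))
})

test_that("initialization is a pure function of the spec seed", {
  n1 <- build_adherence_net(adherence_net_spec(seed = 11))
  n2 <- build_adherence_net(adherence_net_spec(seed = 11))
  n3 <- build_adherence_net(adherence_net_spec(seed = 12))
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, n3$params))
})

test_that("predictions are normalized, deterministic, and tie-break to lapse", {
  net <- build_adherence_net(tiny_net_spec())
  set.seed(2)
  x <- array(rnorm(6 * 7 * 4), dim = c(6, 7, 4))
  p <- predict(net, x)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_identical(p, predict(net, x))
  # zeroed output layer: symmetric scores, probability 1/2, predicted class 0
  net$params$W4[] <- 0; net$params$b4[] <- 0
  p0 <- predict(net, x)
  expect_equal(as.vector(p0), rep(0.5, 12))
  expect_identical(predict(net, x, type = "class"), rep(0L, 6))
})

test_that("batch permutation permutes predictions identically", {
  net <- build_adherence_net(tiny_net_spec(seed = 3))
  set.seed(3)
  x <- array(rnorm(8 * 7 * 4), dim = c(8, 7, 4))
  perm <- sample(8)
  expect_equal(predict(net, x)[perm, ], predict(net, x[perm, , , drop = FALSE]))
})

test_that("extractor plus classifier equals the monolithic forward pass", {
  net <- build_adherence_net(adherence_net_spec(seed = 5))
  set.seed(5)
  x <- array(rnorm(4 * 7 * 4), dim = c(4, 7, 4))
  expect_identical(classify_features(net, extract_features(net, x)),
                   predict(net, x, type = "score"))
})

test_that("input shape mismatches are rejected", {
  net <- build_adherence_net(adherence_net_spec())
  expect_error(predict(net, array(0, c(2, 6, 4))), "7 x 4")
})

test_that("backpropagation matches numerical gradients", {
  net <- build_adherence_net(tiny_net_spec(seed = 7))
  set.seed(7)
  x <- array(rnorm(5 * 7 * 4), dim = c(5, 7, 4))
  y <- c(0L, 1L, 1L, 0L, 1L)
  fwd <- lapsenet:::net_forward(net, x, keep_cache = TRUE)
  lg <- lapsenet:::ce_loss_grad(fwd$scores, y, c(1.2, 0.9))
  gr <- lapsenet:::net_backward(net, fwd$cache, lg$grad)
  lossfun <- function(params) {
    n2 <- net; n2$params <- params
    lapsenet:::ce_loss_grad(lapsenet:::net_forward(n2, x)$scores, y, c(1.2, 0.9))$loss
  }
  eps <- 1e-6
  for (nm in names(net$params)) {
    idx <- seq_len(min(5, length(net$params[[nm]])))
    for (i in idx) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip with bit-identical predictions", {
  net <- build_adherence_net(adherence_net_spec(seed = 21))
  f <- tempfile(fileext = ".json")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  set.seed(21)
  x <- array(rnorm(3 * 7 * 4), dim = c(3, 7, 4))
  expect_identical(predict(back, x), predict(net, x))
  expect_error(suppressWarnings(load_checkpoint(tempfile())),
               "cannot open|recognized")
})
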