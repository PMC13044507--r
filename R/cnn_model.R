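# The 1D convolutional adherence network.
#
# Architecture: two convolutional blocks (valid 1D convolution + ReLU +
# non-overlapping max pooling), then flatten, a linear layer with ReLU whose
# output is the feature vector, and a 2-class output layer. The
# extractor/classifier decomposition is explicit: source-free adaptation
# updates the extractor against a frozen classifier, so both halves must be
# independently invocable.
#
# The forward/backward pass is implemented directly with matrix algebra
# (im2col unfolding); networks here are tiny (7-step windows, 4 channels,
# tens of filters), so vectorized base R is entirely adequate.

#' Valid-mode 1D convolution (sliding dot product)
#'
#' Slides the kernel from the start of the series to its end and returns the
#' dot product at each fully-overlapping position:
#' `out[i] = sum_j f[i + j - 1] * g[j]` for `i = 1 ... n - m + 1`. This is
#' the cross-correlation convention used by deep-learning frameworks (no
#' kernel flip); with learned kernels the distinction is immaterial.
#'
#' @param f Numeric input vector of length `n`.
#' @param g Numeric kernel of length `m <= n`.
#' @return Numeric vector of length `n - m + 1`.
#' @export
#' @examples
#' conv1d_valid(c(1, 2, 3), c(1, 1)) # 3 5
conv1d_valid <- function(f, g) {
  n <- length(f)
  m <- length(g)
  if (m > n) {
    stop(sprintf("kernel length %d exceeds input length %d", m, n), call. = FALSE)
  }
  out_len <- n - m + 1L
  out <- numeric(out_len)
  for (j in seq_len(m)) {
    out <- out + f[j:(j + out_len - 1L)] * g[j]
  }
  out
}

#' Architecture specification for the adherence network
#'
#' The window length must survive both convolution/pooling stages with at
#' least one output position: with valid convolution and floor-division
#' pooling, `((N - k1 + 1) %/% p1 - k2 + 1) %/% p2 >= 1`.
#'
#' @param window_size Input window length N (days).
#' @param in_channels Input channels (the 4 engagement features).
#' @param conv_channels Length-2 integer vector: filters in each conv block.
#' @param kernel_sizes Length-2 integer vector: kernel lengths.
#' @param pool_sizes Length-2 integer vector: non-overlapping max-pool widths.
#' @param hidden_units Width of the linear layer; its ReLU output is the
#'   feature vector used by the adaptation memory banks.
#' @param n_classes Output classes (2: lapse = 0, adherent = 1).
#' @param seed Integer; parameter initialization is a pure function of it.
#' @return An object of class `adherence_net_spec`.
#' @export
adherence_net_spec <- function(window_size = 7L, in_channels = 4L,
                               conv_channels = c(16L, 32L),
                               kernel_sizes = c(3L, 2L),
                               pool_sizes = c(1L, 2L),
                               hidden_units = 32L, n_classes = 2L,
                               seed = 1L) {
  stopifnot(length(conv_channels) == 2L, length(kernel_sizes) == 2L,
            length(pool_sizes) == 2L, all(conv_channels >= 1),
            all(kernel_sizes >= 1), all(pool_sizes >= 1),
            hidden_units >= 1, n_classes == 2L, window_size >= 1,
            in_channels >= 1)
  l1 <- window_size - kernel_sizes[1] + 1L
  if (l1 < 1) {
    stop(sprintf("conv block 1: window %d - kernel %d + 1 = %d < 1",
                 window_size, kernel_sizes[1], l1), call. = FALSE)
  }
  l1p <- l1 %/% pool_sizes[1]
  if (l1p < 1) {
    stop(sprintf("pool block 1: %d %%/%% %d = %d < 1", l1, pool_sizes[1], l1p),
         call. = FALSE)
  }
  l2 <- l1p - kernel_sizes[2] + 1L
  if (l2 < 1) {
    stop(sprintf("conv block 2: %d - kernel %d + 1 = %d < 1",
                 l1p, kernel_sizes[2], l2), call. = FALSE)
  }
  l2p <- l2 %/% pool_sizes[2]
  if (l2p < 1) {
    stop(sprintf("pool block 2: %d %%/%% %d = %d < 1", l2, pool_sizes[2], l2p),
         call. = FALSE)
  }
  structure(
    list(window_size = as.integer(window_size), in_channels = as.integer(in_channels),
         conv_channels = as.integer(conv_channels), kernel_sizes = as.integer(kernel_sizes),
         pool_sizes = as.integer(pool_sizes), hidden_units = as.integer(hidden_units),
         n_classes = as.integer(n_classes), seed = as.integer(seed),
         lengths = c(l1 = l1, l1p = l1p, l2 = l2, l2p = l2p)),
    class = "adherence_net_spec"
  )
}

#' Build an adherence network with seeded initialization
#'
#' Weights use He initialization (`N(0, 2 / fan_in)`), biases start at zero;
#' the parameter draw is a pure function of `spec$seed`.
#'
#' @param spec An [adherence_net_spec()].
#' @return An object of class `adherence_net`.
#' @export
build_adherence_net <- function(spec = adherence_net_spec()) {
  stopifnot(inherits(spec, "adherence_net_spec"))
  k1 <- spec$kernel_sizes[1]; k2 <- spec$kernel_sizes[2]
  c0 <- spec$in_channels; c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  flat <- spec$lengths[["l2p"]] * c2
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  params <- with_seed(spec$seed, list(
    W1 = he(k1 * c0, c1), b1 = numeric(c1),
    W2 = he(k2 * c1, c2), b2 = numeric(c2),
    W3 = he(flat, spec$hidden_units), b3 = numeric(spec$hidden_units),
    W4 = he(spec$hidden_units, spec$n_classes), b4 = numeric(spec$n_classes)
  ))
  structure(list(spec = spec, params = params), class = "adherence_net")
}

#' @export
print.adherence_net <- function(x, ...) {
  s <- x$spec
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "Adherence network: %d-day x %d-channel window -> conv(%d,k%d)/pool%d -> conv(%d,k%d)/pool%d -> linear(%d) -> %d classes (%d parameters)\n",
    s$window_size, s$in_channels, s$conv_channels[1], s$kernel_sizes[1],
    s$pool_sizes[1], s$conv_channels[2], s$kernel_sizes[2], s$pool_sizes[2],
    s$hidden_units, s$n_classes, n_par))
  invisible(x)
}

#' @export
coef.adherence_net <- function(object, ...) object$params

# --- internal forward / backward machinery -------------------------------

# Unfold (B, L_in, C) into the im2col matrix (B*L_out, k*C); column index
# (c-1)*k + j holds input position (t + j - 1) of channel c.
unfold3 <- function(x, k) {
  d <- dim(x)
  B <- d[1]; L_in <- d[2]; C <- d[3]
  L <- L_in - k + 1L
  Z <- array(0, dim = c(B, L, k * C))
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      Z[, , (c - 1L) * k + j] <- x[, j:(j + L - 1L), c, drop = FALSE]
    }
  }
  dim(Z) <- c(B * L, k * C)
  list(mat = Z, B = B, L = L)
}

# Inverse of unfold3 for gradients: scatter-add (B*L, k*C) back to (B, L_in, C).
fold3 <- function(dmat, B, L, k, C, L_in) {
  dZ <- dmat
  dim(dZ) <- c(B, L, k * C)
  dx <- array(0, dim = c(B, L_in, C))
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      idx <- j:(j + L - 1L)
      dx[, idx, c] <- dx[, idx, c] + dZ[, , (c - 1L) * k + j]
    }
  }
  dx
}

# Non-overlapping max pool over dim 2, floor division; returns pooled array
# and the winning offset (1..p) per pooled cell for backprop.
maxpool3 <- function(x, p) {
  d <- dim(x)
  B <- d[1]; L <- d[2]; C <- d[3]
  Lp <- L %/% p
  if (p == 1L) {
    return(list(out = x[, seq_len(Lp), , drop = FALSE],
                arg = array(1L, dim = c(B, Lp, C)), p = p, L = L))
  }
  out <- array(0, dim = c(B, Lp, C))
  arg <- array(1L, dim = c(B, Lp, C))
  for (q in seq_len(Lp)) {
    best <- x[, (q - 1L) * p + 1L, , drop = FALSE]
    dim(best) <- c(B, C)
    win <- matrix(1L, B, C)
    for (j in 2:p) {
      cand <- x[, (q - 1L) * p + j, , drop = FALSE]
      dim(cand) <- c(B, C)
      upd <- cand > best
      best[upd] <- cand[upd]
      win[upd] <- j
    }
    out[, q, ] <- best
    arg[, q, ] <- win
  }
  list(out = out, arg = arg, p = p, L = L)
}

maxpool3_backward <- function(dout, pool) {
  d <- dim(dout)
  B <- d[1]; Lp <- d[2]; C <- d[3]
  dx <- array(0, dim = c(B, pool$L, C))
  for (q in seq_len(Lp)) {
    dq <- dout[, q, , drop = FALSE]; dim(dq) <- c(B, C)
    aq <- pool$arg[, q, , drop = FALSE]; dim(aq) <- c(B, C)
    for (j in seq_len(pool$p)) {
      mask <- aq == j
      if (any(mask)) {
        tmp <- matrix(0, B, C)
        tmp[mask] <- dq[mask]
        pos <- (q - 1L) * pool$p + j
        dx[, pos, ] <- dx[, pos, ] + tmp
      }
    }
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Full forward pass. Returns scores and, when keep_cache, every intermediate
# needed by net_backward.
net_forward <- function(net, x, keep_cache = FALSE) {
  s <- net$spec; p <- net$params
  if (length(dim(x)) != 3L || dim(x)[2] != s$window_size || dim(x)[3] != s$in_channels) {
    stop(sprintf("input must be a (batch x %d x %d) array", s$window_size, s$in_channels),
         call. = FALSE)
  }
  B <- dim(x)[1]
  u1 <- unfold3(x, s$kernel_sizes[1])
  z1 <- sweep(u1$mat %*% p$W1, 2, p$b1, "+")
  a1 <- relu(z1)
  a1arr <- array(a1, dim = c(B, u1$L, s$conv_channels[1]))
  pool1 <- maxpool3(a1arr, s$pool_sizes[1])

  u2 <- unfold3(pool1$out, s$kernel_sizes[2])
  z2 <- sweep(u2$mat %*% p$W2, 2, p$b2, "+")
  a2 <- relu(z2)
  a2arr <- array(a2, dim = c(B, u2$L, s$conv_channels[2]))
  pool2 <- maxpool3(a2arr, s$pool_sizes[2])

  flat <- pool2$out
  dim(flat) <- c(B, s$lengths[["l2p"]] * s$conv_channels[2])
  z3 <- sweep(flat %*% p$W3, 2, p$b3, "+")
  feat <- relu(z3)
  scores <- sweep(feat %*% p$W4, 2, p$b4, "+")

  out <- list(scores = scores, features = feat)
  if (keep_cache) {
    out$cache <- list(x = x, B = B, u1 = u1, z1 = z1, pool1 = pool1,
                      u2 = u2, z2 = z2, pool2 = pool2, flat = flat, z3 = z3,
                      feat = feat)
  }
  out
}

# Backpropagate d(loss)/d(scores) to parameter gradients.
net_backward <- function(net, cache, dscores) {
  s <- net$spec; p <- net$params
  B <- cache$B
  gW4 <- crossprod(cache$feat, dscores)
  gb4 <- colSums(dscores)
  dfeat <- dscores %*% t(p$W4)
  dz3 <- dfeat * (cache$z3 > 0)
  gW3 <- crossprod(cache$flat, dz3)
  gb3 <- colSums(dz3)
  dflat <- dz3 %*% t(p$W3)
  dpool2 <- dflat
  dim(dpool2) <- c(B, s$lengths[["l2p"]], s$conv_channels[2])
  da2arr <- maxpool3_backward(dpool2, cache$pool2)
  da2 <- da2arr
  dim(da2) <- c(B * cache$u2$L, s$conv_channels[2])
  dz2 <- da2 * (cache$z2 > 0)
  gW2 <- crossprod(cache$u2$mat, dz2)
  gb2 <- colSums(dz2)
  du2 <- dz2 %*% t(p$W2)
  dpool1 <- fold3(du2, B, cache$u2$L, s$kernel_sizes[2], s$conv_channels[1],
                  dim(cache$pool1$out)[2])
  da1arr <- maxpool3_backward(dpool1, cache$pool1)
  da1 <- da1arr
  dim(da1) <- c(B * cache$u1$L, s$conv_channels[1])
  dz1 <- da1 * (cache$z1 > 0)
  gW1 <- crossprod(cache$u1$mat, dz1)
  gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

softmax_rows <- function(scores) {
  z <- scores - apply(scores, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Run the feature extractor
#'
#' Maps windows to the ReLU output of the linear layer — the feature vector
#' whose neighborhood structure drives source-free adaptation.
#'
#' @param net An `adherence_net`.
#' @param x A `window_set` or a `(batch x N x 4)` array.
#' @return A `(batch x hidden_units)` feature matrix.
#' @export
extract_features <- function(net, x) {
  net_forward(net, as_window_array(x))$features
}

#' Run the classifier head on extracted features
#'
#' @param net An `adherence_net`.
#' @param features A `(batch x hidden_units)` matrix from [extract_features()].
#' @return A `(batch x 2)` score matrix.
#' @export
classify_features <- function(net, features) {
  stopifnot(ncol(features) == net$spec$hidden_units)
  sweep(features %*% net$params$W4, 2, net$params$b4, "+")
}

as_window_array <- function(x) {
  if (inherits(x, "window_set")) x$x else x
}

#' Predict adherence from feature windows
#'
#' @param object An `adherence_net`.
#' @param newdata A `window_set` or `(batch x N x 4)` array.
#' @param type `"prob"` for class probabilities (columns: lapse, adherent),
#'   `"class"` for hard 0/1 labels, `"score"` for raw output scores. Ties in
#'   the probabilities break toward the lapse class (0), the actionable alarm.
#' @param ... Unused.
#' @return Matrix of probabilities/scores, or an integer label vector.
#' @export
predict.adherence_net <- function(object, newdata, type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  scores <- net_forward(object, as_window_array(newdata))$scores
  if (type == "score") return(scores)
  prob <- softmax_rows(scores)
  colnames(prob) <- c("lapse", "adherent")
  if (type == "prob") return(prob)
  as.integer(prob[, 2] > prob[, 1])
}
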