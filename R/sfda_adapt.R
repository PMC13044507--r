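# Source-free domain adaptation by local structure clustering (LSC).
#
# Only a trained checkpoint crosses the study boundary. For one target
# participant, the fine-tuned model is adapted on that participant's
# training-segment windows treated as UNLABELED: memory banks cache
# L2-normalized extractor features and soft predictions for all target
# windows; each step pushes every window's prediction toward those of its K
# nearest bank neighbors (cosine similarity) while a diversity term on the
# batch marginal prevents collapse to a single class. The classifier head
# stays frozen by default so the class geometry inherited from the source
# survives; only the extractor moves.

#' Configuration of local-structure-clustering adaptation
#'
#' @param k_neighbors Neighbors per window (default 3; banks hold only ~23
#'   rows under the default split, so K is kept small).
#' @param diversity_weight Weight of the marginal-entropy diversity term
#'   (default 1); 0 disables it and invites class collapse.
#' @param adapt_epochs Adaptation epochs (default 30).
#' @param adapt_lr Adam learning rate during adaptation (default 1e-4).
#' @param variant `"lsc"` for plain neighbor agreement, `"reciprocal"` to
#'   down-weight non-reciprocal neighbors (weight 0.1 instead of 1).
#' @param freeze_classifier Keep the classifier head fixed and update only
#'   the extractor (default TRUE).
#' @param seed Integer seed for minibatch order.
#' @return An object of class `lsc_config`.
#' @export
lsc_config <- function(k_neighbors = 3L, diversity_weight = 1,
                       adapt_epochs = 30L, adapt_lr = 1e-4,
                       variant = c("lsc", "reciprocal"),
                       freeze_classifier = TRUE, seed = 1L) {
  variant <- match.arg(variant)
  stop_if_not_scalar_number(k_neighbors, "k_neighbors", lower = 1)
  stop_if_not_scalar_number(diversity_weight, "diversity_weight", lower = 0)
  stop_if_not_scalar_number(adapt_epochs, "adapt_epochs", lower = 0)
  stop_if_not_scalar_number(adapt_lr, "adapt_lr", lower = 0)
  structure(
    list(k_neighbors = as.integer(k_neighbors), diversity_weight = diversity_weight,
         adapt_epochs = as.integer(adapt_epochs), adapt_lr = adapt_lr,
         variant = variant, freeze_classifier = isTRUE(freeze_classifier),
         seed = as.integer(seed)),
    class = "lsc_config"
  )
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m * m))
  nrm[nrm < 1e-12] <- 1
  m / nrm
}

#' Build feature and score memory banks for a target participant
#'
#' Runs the current model over all target windows and caches L2-normalized
#' extractor features and softmax scores, row-aligned.
#'
#' @param net An `adherence_net`.
#' @param windows A `window_set` (labels, if present, are ignored).
#' @param k_neighbors When given, at least `k_neighbors + 1` windows are
#'   required.
#' @return An object of class `memory_banks` with `feature_bank` and
#'   `score_bank`.
#' @export
build_banks <- function(net, windows, k_neighbors = NULL) {
  x <- as_window_array(windows)
  n <- dim(x)[1]
  if (!is.null(k_neighbors) && n < k_neighbors + 1L) {
    stop(sprintf("need at least %d target windows for K = %d neighbors, got %d",
                 k_neighbors + 1L, k_neighbors, n), call. = FALSE)
  }
  fwd <- net_forward(net, x)
  structure(
    list(feature_bank = l2_normalize_rows(fwd$features),
         score_bank = softmax_rows(fwd$scores)),
    class = "memory_banks"
  )
}

#' Nearest bank neighbors of one window
#'
#' Returns the indices of the `k` bank rows (excluding `i` itself) with
#' highest cosine similarity to feature row `i`; ties break toward the lower
#' index.
#'
#' @param banks A `memory_banks`.
#' @param i Query row index.
#' @param k Number of neighbors; must be below the bank size.
#' @return Integer vector of `k` row indices, most similar first.
#' @export
find_neighbors <- function(banks, i, k) {
  n <- nrow(banks$feature_bank)
  if (i < 1 || i > n) stop("invalid bank index", call. = FALSE)
  if (k >= n) {
    stop(sprintf("k = %d must be smaller than the bank size %d", k, n), call. = FALSE)
  }
  sims <- as.numeric(banks$feature_bank %*% banks$feature_bank[i, ])
  sims[i] <- -Inf
  order(-sims, seq_len(n))[seq_len(k)]
}

# K-nearest-neighbor index matrix (n x k) for every bank row at once.
all_neighbors <- function(feature_bank, k) {
  n <- nrow(feature_bank)
  sims <- feature_bank %*% t(feature_bank)
  diag(sims) <- -Inf
  t(vapply(seq_len(n), function(i) order(-sims[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

#' The local-structure-clustering loss
#'
#' `loss = -(1/B) sum_i sum_k w_ik (p_i . q_k) + lambda * sum_c m_c log m_c`
#' where `p_i` is window i's soft prediction, `q_k` the cached soft
#' predictions of its bank neighbors, `w_ik` optional affinity weights, and
#' `m` the batch marginal `mean(p_i)`. The first term rewards agreement with
#' neighbors (clusters move jointly toward a common class); the second — the
#' negative entropy of the marginal — penalizes collapse to a single class
#' and is minimized by the uniform marginal.
#'
#' @param batch_scores `(B x 2)` matrix of soft predictions (rows sum to 1).
#' @param neighbor_scores `(B x K x 2)` array of the cached neighbor
#'   predictions.
#' @param lambda Diversity weight.
#' @param weights Optional `(B x K)` affinity weights (default all 1).
#' @return Scalar loss.
#' @export
lsc_loss <- function(batch_scores, neighbor_scores, lambda = 1, weights = NULL) {
  B <- nrow(batch_scores)
  if (any(abs(rowSums(batch_scores) - 1) > 1e-6) || any(batch_scores < -1e-9)) {
    stop("batch_scores rows must be probability vectors", call. = FALSE)
  }
  dn <- dim(neighbor_scores)
  if (length(dn) != 3L || dn[1] != B || dn[3] != ncol(batch_scores)) {
    stop("neighbor_scores must be a (B x K x C) array", call. = FALSE)
  }
  K <- dn[2]
  if (is.null(weights)) weights <- matrix(1, B, K)
  agree <- 0
  for (k in seq_len(K)) {
    q <- neighbor_scores[, k, , drop = TRUE]
    if (is.null(dim(q))) q <- matrix(q, nrow = B)
    if (any(abs(rowSums(q) - 1) > 1e-6)) {
      stop("neighbor score rows must be probability vectors", call. = FALSE)
    }
    agree <- agree + sum(weights[, k] * rowSums(batch_scores * q))
  }
  m <- colMeans(batch_scores)
  div <- sum(ifelse(m > 0, m * log(m), 0))
  -agree / B + lambda * div
}

#' Adapt a fine-tuned checkpoint to one target participant, source-free
#'
#' Initializes from the checkpoint and minimizes the LSC loss over the
#' participant's training-segment windows for `adapt_epochs` epochs
#' (full-batch; banks hold only ~23 rows), refreshing the memory-bank rows of
#' each batch with the updated model after every step. Labels are never read.
#' With fewer than `k_neighbors + 1` windows the checkpoint is returned
#' unadapted with a warning.
#'
#' @param net Fine-tuned checkpoint (`adherence_net`).
#' @param windows The target participant's unlabeled window pool: a
#'   `window_set` or a `prepared_participant` (whose `all_train` —
#'   training-segment windows only — is used; test windows are never
#'   touched).
#' @param config An [lsc_config()].
#' @return The adapted `adherence_net`, with the per-epoch loss trace in
#'   `attr(, "adapt_log")`.
#' @export
adapt_to_participant <- function(net, windows, config = lsc_config()) {
  stopifnot(inherits(net, "adherence_net"), inherits(config, "lsc_config"))
  if (inherits(windows, "prepared_participant")) windows <- windows$all_train
  x <- as_window_array(windows)
  n <- dim(x)[1]
  K <- config$k_neighbors
  if (n < K + 1L) {
    warning(sprintf("only %d target windows for K = %d; returning checkpoint unadapted",
                    n, K))
    attr(net, "adapt_log") <- numeric(0)
    return(net)
  }
  if (config$adapt_epochs == 0L) {
    attr(net, "adapt_log") <- numeric(0)
    return(net)
  }
  update <- if (config$freeze_classifier) {
    c("W1", "b1", "W2", "b2", "W3", "b3")
  } else {
    names(net$params)
  }
  banks <- build_banks(net, x, k_neighbors = K)
  params <- net$params
  state <- adam_init(params)
  trace <- numeric(config$adapt_epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$adapt_epochs)) {
      net$params <- params
      fwd <- net_forward(net, x, keep_cache = TRUE)
      p <- softmax_rows(fwd$scores)
      nbr <- all_neighbors(banks$feature_bank, K)
      w <- matrix(1, n, K)
      if (config$variant == "reciprocal") {
        for (i in seq_len(n)) {
          for (j in seq_len(K)) {
            k_id <- nbr[i, j]
            if (!(i %in% nbr[k_id, ])) w[i, j] <- 0.1
          }
        }
      }
      q <- array(0, dim = c(n, K, 2))
      for (j in seq_len(K)) q[, j, ] <- banks$score_bank[nbr[, j], , drop = FALSE]
      loss <- lsc_loss(p, q, lambda = config$diversity_weight, weights = w)
      if (!is.finite(loss)) {
        stop(sprintf("adaptation diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      trace[epoch] <- loss

      # d(loss)/d(p_i): neighbor term uses cached bank scores as constants;
      # diversity term differentiates through the batch marginal.
      g <- matrix(0, n, 2)
      for (j in seq_len(K)) {
        qj <- q[, j, , drop = TRUE]
        if (is.null(dim(qj))) qj <- matrix(qj, nrow = n)
        g <- g - w[, j] * qj / n
      }
      m <- colMeans(p)
      g <- g + config$diversity_weight *
        matrix(ifelse(m > 0, log(m) + 1, 0), n, 2, byrow = TRUE) / n
      # through the softmax
      dscores <- p * (g - rowSums(g * p))
      grads <- net_backward(net, fwd$cache, dscores)
      upd <- adam_step(params, grads, state, config$adapt_lr, update = update)
      params <- upd$params
      state <- upd$state
      # refresh bank rows with the updated model (full batch: all rows)
      net$params <- params
      fwd2 <- net_forward(net, x)
      banks$feature_bank <- l2_normalize_rows(fwd2$features)
      banks$score_bank <- softmax_rows(fwd2$scores)
    }
  })
  net$params <- params
  attr(net, "adapt_log") <- trace
  net
}

#' Two-cluster toy demonstration of the LSC mechanism
#'
#' A linear softmax model (2D linear extractor + linear head) is trained on
#' two Gaussian source clusters, then the whole target distribution is shifted
#' so part of one cluster crosses the decision boundary. LSC adaptation of the
#' extractor (head frozen) should pull each cluster jointly back to a common
#' class, raising label purity; with `lambda = 0` and `k = n - 1` it instead
#' collapses predictions to one class (the documented failure mode motivating
#' the diversity term).
#'
#' @param seed Integer seed.
#' @param shift Length-2 target displacement applied to both clusters.
#' @param n_per_class Points per class.
#' @param lambda Diversity weight.
#' @param k Neighbors (default 3).
#' @param adapt_epochs Adaptation steps (full-batch gradient descent).
#' @param lr Adaptation learning rate.
#' @return List with `purity_before`, `purity_after` (accuracy of predictions
#'   against generative labels) and `majority_share_after` (largest predicted
#'   class share, the collapse diagnostic).
#' @export
lsc_toy_experiment <- function(seed, shift = c(1.8, 0.9), n_per_class = 60,
                               lambda = 1, k = 3L, adapt_epochs = 80, lr = 0.05) {
  with_seed(seed, {
    n <- 2L * n_per_class
    y <- rep(c(0L, 1L), each = n_per_class)
    centers <- rbind(c(-2, 0), c(2, 0))
    xs <- centers[y + 1L, ] + matrix(rnorm(2 * n, 0, 0.6), n, 2)
    # source training of extractor (W, c) and head (V, d) by full-batch CE
    W <- diag(2) * 0.5; cc <- c(0, 0)
    V <- matrix(rnorm(4, 0, 0.5), 2, 2); d <- c(0, 0)
    onehot <- cbind(1 - y, y)
    for (it in 1:300) {
      f <- xs %*% W + matrix(cc, n, 2, byrow = TRUE)
      p <- softmax_rows(f %*% V + matrix(d, n, 2, byrow = TRUE))
      ds <- (p - onehot) / n
      dV <- crossprod(f, ds); dd <- colSums(ds)
      df <- ds %*% t(V)
      dW <- crossprod(xs, df); dc <- colSums(df)
      V <- V - 0.5 * dV; d <- d - 0.5 * dd
      W <- W - 0.5 * dW; cc <- cc - 0.5 * dc
    }
    # shifted target sample
    xt <- centers[y + 1L, ] + matrix(rnorm(2 * n, 0, 0.6), n, 2) +
      matrix(shift, n, 2, byrow = TRUE)
    predict_toy <- function(W, cc) {
      f <- xt %*% W + matrix(cc, n, 2, byrow = TRUE)
      softmax_rows(f %*% V + matrix(d, n, 2, byrow = TRUE))
    }
    p0 <- predict_toy(W, cc)
    purity_before <- mean(as.integer(p0[, 2] > p0[, 1]) == y)
    # LSC adaptation of the extractor, head frozen
    for (it in seq_len(adapt_epochs)) {
      f <- xt %*% W + matrix(cc, n, 2, byrow = TRUE)
      fb <- l2_normalize_rows(f)
      p <- softmax_rows(f %*% V + matrix(d, n, 2, byrow = TRUE))
      nbr <- all_neighbors(fb, k)
      g <- matrix(0, n, 2)
      for (j in seq_len(k)) g <- g - p[nbr[, j], , drop = FALSE] / n
      m <- colMeans(p)
      g <- g + lambda * matrix(ifelse(m > 0, log(m) + 1, 0), n, 2, byrow = TRUE) / n
      ds <- p * (g - rowSums(g * p))
      df <- ds %*% t(V)
      W <- W - lr * crossprod(xt, df)
      cc <- cc - lr * colSums(df)
    }
    p1 <- predict_toy(W, cc)
    pred_after <- as.integer(p1[, 2] > p1[, 1])
    list(purity_before = purity_before,
         purity_after = mean(pred_after == y),
         majority_share_after = max(mean(pred_after == 0), mean(pred_after == 1)))
  })
}
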