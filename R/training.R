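# Supervised training: Adam with a step-decay learning-rate schedule,
# early stopping on validation loss, and the three-tier protocol — source
# training on a whole study, fine-tuning on the target study excluding the
# held-out participant, and the per-participant no-source baseline.

#' Optimizer schedule
#'
#' Adam with an initial learning rate of 1e-3, halved every 20 epochs, up to
#' 130 epochs with early stopping once validation loss has not improved for
#' `early_stop_patience` consecutive epochs.
#'
#' @param initial_lr Initial learning rate.
#' @param decay_factor Multiplicative decay applied every `decay_every` epochs.
#' @param decay_every Epoch interval of the decay.
#' @param max_epochs Upper bound on epochs (0 allowed: a no-op run).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param batch_size Minibatch size; runs full-batch when the training set is
#'   smaller (as for single-participant sets).
#' @return An object of class `optimizer_schedule`.
#' @export
optimizer_schedule <- function(initial_lr = 1e-3, decay_factor = 0.5,
                               decay_every = 20L, max_epochs = 130L,
                               early_stop_patience = 10L, batch_size = 32L) {
  stop_if_not_scalar_number(initial_lr, "initial_lr", lower = 0)
  stop_if_not_scalar_number(decay_factor, "decay_factor", lower = 0, upper = 1)
  stop_if_not_scalar_number(decay_every, "decay_every", lower = 1)
  stop_if_not_scalar_number(max_epochs, "max_epochs", lower = 0)
  stop_if_not_scalar_number(early_stop_patience, "early_stop_patience", lower = 1)
  stop_if_not_scalar_number(batch_size, "batch_size", lower = 1)
  structure(
    list(initial_lr = initial_lr, decay_factor = decay_factor,
         decay_every = as.integer(decay_every), max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size)),
    class = "optimizer_schedule"
  )
}

#' Learning rate at a given (0-based) epoch
#'
#' Closed form: `initial_lr * decay_factor ^ (epoch %/% decay_every)`; e.g.
#' 2.5e-4 at epoch 40 under the defaults.
#'
#' @param schedule An [optimizer_schedule()].
#' @param epoch 0-based epoch index (vectorized).
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(schedule, epoch) {
  schedule$initial_lr * schedule$decay_factor ^ (epoch %/% schedule$decay_every)
}

# Inverse-frequency class weights when labels are imbalanced beyond 80/20;
# otherwise unit weights. Applied identically in every supervised arm.
class_weights <- function(y, balance = TRUE) {
  w <- c(1, 1)
  if (!balance) return(w)
  n <- length(y)
  n1 <- sum(y == 1L)
  if (n1 == 0L || n1 == n) return(w)
  if (min(n1, n - n1) / n < 0.2) {
    w <- n / (2 * c(n - n1, n1))
  }
  w
}

# Weighted cross-entropy over a score matrix; returns loss and d(loss)/d(scores).
ce_loss_grad <- function(scores, y, w = c(1, 1)) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  wy <- w[y + 1L]
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -sum(wy * log(pmax(p[idx], 1e-12))) / sum(wy)
  onehot <- matrix(0, n, ncol(scores))
  onehot[idx] <- 1
  grad <- (p - onehot) * (wy / sum(wy))
  list(loss = loss, grad = grad)
}

ce_loss <- function(scores, y) {
  p <- softmax_rows(scores)
  idx <- cbind(seq_along(y), y + 1L)
  -mean(log(pmax(p[idx], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      update = names(params)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  for (nm in update) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train an adherence network with early stopping
#'
#' Minimizes (optionally class-weighted) cross-entropy with Adam under the
#' step-decay schedule; monitors unweighted validation loss each epoch and
#' returns the parameters of the best-validation epoch. Stops early when the
#' validation loss has not improved for `schedule$early_stop_patience`
#' epochs.
#'
#' @param net Starting `adherence_net` (fresh or a loaded checkpoint).
#' @param train,val `window_set`s with labels; both must be non-empty.
#' @param schedule An [optimizer_schedule()].
#' @param seed Integer seed for minibatch shuffling.
#' @param class_balance Apply inverse-frequency class weights when training
#'   labels are imbalanced beyond 80/20 (default TRUE).
#' @return The trained `adherence_net`, with the per-epoch log (epoch, lr,
#'   train and validation loss) in `attr(, "log")` and the best epoch in
#'   `attr(, "best_epoch")`.
#' @export
train_supervised <- function(net, train, val, schedule = optimizer_schedule(),
                             seed = 1L, class_balance = TRUE) {
  stopifnot(inherits(net, "adherence_net"), inherits(schedule, "optimizer_schedule"))
  if (length(train) == 0L || length(val) == 0L) {
    stop("training and validation sets must both be non-empty", call. = FALSE)
  }
  if (schedule$max_epochs == 0L) {
    attr(net, "log") <- data.frame(epoch = integer(), lr = numeric(),
                                   train_loss = numeric(), val_loss = numeric())
    attr(net, "best_epoch") <- 0L
    return(net)
  }
  w <- class_weights(train$y, class_balance)
  n <- length(train)
  params <- net$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  log <- vector("list", schedule$max_epochs)
  with_seed(seed, {
    for (epoch in seq_len(schedule$max_epochs)) {
      lr <- lr_at_epoch(schedule, epoch - 1L)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = schedule$batch_size)
      epoch_loss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + schedule$batch_size - 1L, n)]
        xb <- train$x[idx, , , drop = FALSE]
        yb <- train$y[idx]
        net$params <- params
        fwd <- net_forward(net, xb, keep_cache = TRUE)
        lg <- ce_loss_grad(fwd$scores, yb, w)
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        grads <- net_backward(net, fwd$cache, lg$grad)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + lg$loss * length(idx)
      }
      net$params <- params
      val_loss <- ce_loss(net_forward(net, val$x)$scores, val$y)
      if (!is.finite(val_loss)) {
        stop(sprintf("validation loss became non-finite at epoch %d", epoch),
             call. = FALSE)
      }
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                 train_loss = epoch_loss / n, val_loss = val_loss)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= schedule$early_stop_patience) break
      }
    }
  })
  net$params <- best$params
  attr(net, "log") <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  attr(net, "best_epoch") <- best$epoch
  net
}

#' Train the shared source model on a whole study
#'
#' Pools every source participant's training (and validation) windows into a
#' single supervised run. The returned network is the checkpoint that crosses
#' the study boundary; no source records ever do.
#'
#' @param prepared_source Named list from [prepare_study()] for the source
#'   study.
#' @param spec An [adherence_net_spec()]; its initialization seed is derived
#'   from `seed`.
#' @param schedule An [optimizer_schedule()].
#' @param seed Integer master seed for initialization and shuffling.
#' @return A trained `adherence_net` (the source checkpoint).
#' @export
train_source_model <- function(prepared_source, spec = adherence_net_spec(),
                               schedule = optimizer_schedule(), seed = 1L) {
  if (length(prepared_source) < 2L) {
    warning("source study has a single participant; proceeding anyway")
  }
  pooled <- pool_windows(prepared_source)
  spec$seed <- derive_seed(seed, 1L, stream = 10L)
  net <- build_adherence_net(spec)
  train_supervised(net, pooled$train, pooled$val, schedule,
                   seed = derive_seed(seed, 2L, stream = 10L))
}

#' Fine-tune a source checkpoint on the target study, excluding one participant
#'
#' Continues supervised training of the source model on the pooled labeled
#' training windows of every target-study participant except `participant`.
#' Leave-one-participant-out is enforced by construction and asserted.
#'
#' @param net Source checkpoint (`adherence_net`).
#' @param prepared_target Named list from [prepare_study()] for the target
#'   study.
#' @param participant Id of the held-out target participant.
#' @param schedule An [optimizer_schedule()].
#' @param seed Integer seed for shuffling.
#' @return The fine-tuned `adherence_net`.
#' @export
finetune_on_target_study <- function(net, prepared_target, participant,
                                     schedule = optimizer_schedule(), seed = 1L) {
  if (!participant %in% names(prepared_target)) {
    stop(sprintf("participant %s is not in the target study", participant),
         call. = FALSE)
  }
  if (length(prepared_target) < 2L) {
    stop("target study must have at least 2 participants for leave-one-out fine-tuning",
         call. = FALSE)
  }
  pooled <- pool_windows(prepared_target, exclude = participant)
  stopifnot(!participant %in% pooled$train$participant_id,
            !participant %in% pooled$val$participant_id)
  train_supervised(net, pooled$train, pooled$val, schedule, seed = seed)
}

#' Train the per-participant no-source baseline
#'
#' A fresh network trained only on the participant's own retained training
#' windows (about 19 under the default 30-day split) — no checkpoint, no data
#' from any other participant or study.
#'
#' @param prepared A `prepared_participant` from [make_windows()].
#' @param spec An [adherence_net_spec()]; initialization seed derived from
#'   `seed`.
#' @param schedule An [optimizer_schedule()].
#' @param seed Integer seed.
#' @return A trained `adherence_net`.
#' @export
train_no_source_baseline <- function(prepared, spec = adherence_net_spec(),
                                     schedule = optimizer_schedule(), seed = 1L) {
  stopifnot(inherits(prepared, "prepared_participant"))
  spec$seed <- derive_seed(seed, 1L, stream = 11L)
  net <- build_adherence_net(spec)
  train_supervised(net, prepared$train, prepared$val, schedule,
                   seed = derive_seed(seed, 2L, stream = 11L))
}
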