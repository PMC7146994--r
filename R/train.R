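# Training loop: minibatch cross-entropy on next-character prediction with
# Adam, per-epoch checkpointing and the examiner callback hook.

# recurse two parameter trees by name, applying f at numeric leaves
tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) {
    key <- if (!is.null(names(a))) names(a)[nm] else nm
    bb <- if (!is.null(names(a)) && nzchar(key)) b[[key]] else b[[nm]]
    out[[nm]] <- tree_map2(a[[nm]], bb, f)
  }
  out
}

tree_map <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  lapply(a, tree_map, f = f)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- tree_map2(params, tree_map2(state$m, state$v, function(m, v) {
    (m / c1) / (sqrt(v / c2) + eps)
  }), function(p, u) p - lr * u)
  list(params = params, state = state)
}

#' Train a generator network
#'
#' Minibatch categorical cross-entropy on next-character prediction.
#' After every epoch the weights are checkpointed and, when given, the
#' `examiner` callback is invoked; training halts when the callback
#' signals stop or `max_epochs` is reached. The examiner only observes
#' (it generates and grades a sample); it never feeds back into the
#' optimizer state or weights.
#'
#' @param model a `gen_model` from [build_network()].
#' @param corpus a `gen_corpus` from [encode_windows()].
#' @param max_epochs upper bound on training epochs.
#' @param examiner `NULL`, or `function(model, epoch)` returning
#'   `list(stop = logical, record = <anything>)`.
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 2e-3).
#' @param lr_decay multiplicative per-epoch learning-rate decay in (0, 1]
#'   (default 1 = constant rate). A decay stabilizes the late-training
#'   validity trajectory the examiner monitors.
#' @param lr_hold epochs trained at the full learning rate before the
#'   decay starts (default 0). A hold-then-decay schedule lets the model
#'   transit the below-margin regime at full speed and then settle.
#' @param seed integer; seeds shuffling and dropout, making the loss
#'   trajectory reproducible run-to-run.
#' @param shuffle shuffle window order each epoch (seeded).
#' @param keep_checkpoints retain a deep copy of the weights for every
#'   epoch (needed for earliest-stable-model selection).
#' @param verbose print one line per epoch to stderr.
#' @return list with `model` (weights at the last trained epoch),
#'   `checkpoints` (per epoch: `epoch`, `loss`, `params` when kept,
#'   `examined` record), `epochs_run`, `stopped_early`.
#' @export
train_network <- function(model, corpus, max_epochs, examiner = NULL,
                          batch_size = 128L, learning_rate = 2e-3,
                          lr_decay = 1.0, lr_hold = 0L, seed = 1L,
                          shuffle = TRUE,
                          keep_checkpoints = TRUE, verbose = FALSE) {
  stopifnot(lr_decay > 0, lr_decay <= 1, lr_hold >= 0)
  stopifnot(inherits(model, "gen_model"), inherits(corpus, "gen_corpus"),
            nrow(corpus$contexts) > 0, max_epochs >= 1)
  stopifnot(vocab_size(corpus$vocabulary) == model$V,
            corpus$window_length == model$W)
  set.seed(seed)
  N <- nrow(corpus$contexts); V <- model$V
  state <- adam_init(model$params)
  checkpoints <- list()
  stopped_early <- FALSE
  for (epoch in seq_len(max_epochs)) {
    lr_epoch <- learning_rate * lr_decay^max(0L, epoch - 1L - lr_hold)
    ord <- if (shuffle) sample.int(N) else seq_len(N)
    total_loss <- 0; n_seen <- 0
    for (start in seq.int(1L, N, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, N)]
      B <- length(rows)
      X <- contexts_idx(corpus$contexts[rows, , drop = FALSE])
      Y <- one_hot(corpus$labels[rows], V)
      fw <- model_forward(model, X, train = TRUE)
      eps <- 1e-12
      loss <- -sum(Y * log(fw$probs + eps)) / B
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      total_loss <- total_loss + loss * B; n_seen <- n_seen + B
      grads <- model_backward(model, X, fw, (fw$probs - Y) / B)
      upd <- adam_step(model$params, grads, state, lr = lr_epoch)
      model$params <- upd$params; state <- upd$state
    }
    ck <- list(epoch = epoch, loss = total_loss / n_seen)
    if (keep_checkpoints) ck$params <- model$params
    if (!is.null(examiner)) {
      # protect training RNG stream from whatever the examiner samples
      rng <- .Random.seed
      ex <- examiner(model, epoch)
      .Random.seed <<- rng
      ck$examined <- ex$record
      checkpoints[[epoch]] <- ck
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f validity %.1f%%", epoch, ck$loss,
                        if (!is.null(ex$record$validity)) ex$record$validity else NA))
      }
      if (isTRUE(ex$stop)) { stopped_early <- TRUE; break }
    } else {
      checkpoints[[epoch]] <- ck
      if (verbose) message(sprintf("epoch %d: loss %.4f", epoch, ck$loss))
    }
  }
  list(model = model, checkpoints = checkpoints,
       epochs_run = length(checkpoints), stopped_early = stopped_early)
}

#' Restore a checkpointed model
#'
#' @param model the `gen_model` whose architecture the checkpoint belongs to.
#' @param checkpoint one element of the `checkpoints` list returned by
#'   [train_network()] (must carry `params`).
#' @return a `gen_model` with the checkpoint's weights.
#' @export
restore_checkpoint <- function(model, checkpoint) {
  stopifnot(!is.null(checkpoint$params))
  model$params <- checkpoint$params
  model
}
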