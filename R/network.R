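# Native implementation of the generator networks.
#
# No deep-learning framework is assumed: LSTM/GRU cells, bidirectional
# wrappers, branch merging and the dense softmax head are implemented
# directly on BLAS-backed matrix operations, with hand-derived
# backpropagation-through-time. Batches are lists over time of B x d
# matrices, so every heavy operation is a GEMM.

sigm <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1, max))
  z / rowSums(z)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---------------------------------------------------------------- specs --

#' Describe one generator architecture
#'
#' The four families share a recurrent "embedding" layer reading the
#' one-hot character window and one or more recurrent "encoding" layers
#' producing a fixed-width representation for the dense next-character
#' head:
#' * `A` -- unidirectional embedding + encoding (k = 1);
#' * `B` -- bidirectional embedding + encoding (k = 1);
#' * `C` -- one bidirectional embedding layer feeding `branch_count`
#'   parallel bidirectional encoding layers, merged;
#' * `D` -- `branch_count` parallel full (embedding + encoding) stacks,
#'   merged.
#'
#' Bidirectional layers concatenate the two directions, doubling the
#' stated unit size in output width. `concatenate` merging yields
#' `k x` the branch width; `average` and `learnable_average` keep the
#' single-branch width and require equal branch widths.
#'
#' @param family one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param unit `"LSTM"` or `"GRU"` (never mixed within a network).
#' @param embedding_size,encoding_size recurrent unit counts per direction.
#' @param branch_count parallel branches k (families C/D; must be 1 for
#'   A/B).
#' @param merge_mode `"concatenate"`, `"average"` or `"learnable_average"`.
#' @param dropout_rate dropout applied to the merged representation during
#'   training (default 0.3).
#' @param bidirectional_embedding,bidirectional_encoding override the
#'   family defaults (A: both FALSE; B/C/D: both TRUE), e.g. to build the
#'   LSTM-embedding/biLSTM-encoding hybrids.
#' @return object of class `gen_architecture`.
#' @export
architecture_spec <- function(family = c("C", "A", "B", "D"),
                              unit = c("LSTM", "GRU"),
                              embedding_size = 64L,
                              encoding_size = 64L,
                              branch_count = if (family %in% c("C", "D")) 4L else 1L,
                              merge_mode = c("concatenate", "average",
                                             "learnable_average"),
                              dropout_rate = 0.3,
                              bidirectional_embedding = family != "A",
                              bidirectional_encoding = family != "A") {
  family <- match.arg(family)
  unit <- match.arg(unit)
  merge_mode <- match.arg(merge_mode)
  branch_count <- as.integer(branch_count)
  if (family %in% c("A", "B") && branch_count != 1L) {
    stop("families A and B have a single branch")
  }
  stopifnot(branch_count >= 1, dropout_rate >= 0, dropout_rate < 1,
            embedding_size >= 1, encoding_size >= 1)
  structure(list(
    family = family, unit = unit,
    embedding_size = as.integer(embedding_size),
    encoding_size = as.integer(encoding_size),
    branch_count = branch_count,
    merge_mode = merge_mode,
    dropout_rate = dropout_rate,
    bidirectional_embedding = isTRUE(bidirectional_embedding),
    bidirectional_encoding = isTRUE(bidirectional_encoding)
  ), class = "gen_architecture")
}

#' @export
print.gen_architecture <- function(x, ...) {
  cat(sprintf("<gen_architecture %s: %s%s %d / %s%s %d x%d, merge=%s, dropout=%.2f>\n",
              x$family,
              if (x$bidirectional_embedding) "bi" else "", x$unit,
              x$embedding_size,
              if (x$bidirectional_encoding) "bi" else "", x$unit,
              x$encoding_size, x$branch_count, x$merge_mode, x$dropout_rate))
  invisible(x)
}

# ------------------------------------------------------- recurrent cells --

n_gates <- function(unit) if (unit == "LSTM") 4L else 3L

init_cell <- function(unit, d, h) {
  g <- n_gates(unit)
  b <- numeric(g * h)
  if (unit == "LSTM") b[(h + 1):(2 * h)] <- 1  # forget-gate bias at 1
  list(Wx = glorot(d, g * h), Wh = glorot(h, g * h), b = b)
}

# Sequences flow between layers as "stacks": a (Tn*B) x d matrix whose
# t-th row block holds the batch at timestep t, plus the (Tn, B) shape.
# One GEMM projects a whole sequence through the input weights; only the
# recurrent term stays in the timestep loop.

seq_stack <- function(stack, Tn, B) list(stack = stack, Tn = Tn, B = B)

blk <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# row permutation reversing the time blocks (an involution)
rev_index <- function(Tn, B) {
  as.vector(outer(1:B, (Tn:1 - 1L) * B, `+`))
}

# cells process the input in forward or reversed time order; caches and
# output stacks are kept in *processing* order
lstm_cell_forward <- function(p, xs, reverse = FALSE) {
  Tn <- xs$Tn; B <- xs$B; h <- nrow(p$Wh)
  i1 <- 1:h; i2 <- h + i1; i3 <- 2 * h + i1; i4 <- 3 * h + i1
  XW <- xs$stack %*% p$Wx
  bmat <- matrix(p$b, B, 4 * h, byrow = TRUE)
  H <- matrix(0, B, h); C <- H
  Hstack <- matrix(0, Tn * B, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    src <- if (reverse) Tn + 1L - t else t
    Z <- XW[blk(src, B), , drop = FALSE] + (H %*% p$Wh + bmat)
    i <- sigm(Z[, i1, drop = FALSE]); f <- sigm(Z[, i2, drop = FALSE])
    g <- tanh(Z[, i3, drop = FALSE]); o <- sigm(Z[, i4, drop = FALSE])
    Cn <- f * C + i * g
    tc <- tanh(Cn)
    Hn <- o * tc
    cache[[t]] <- list(hprev = H, cprev = C,
                       i = i, f = f, g = g, o = o, tc = tc)
    H <- Hn; C <- Cn
    Hstack[blk(t, B), ] <- Hn
  }
  list(Hstack = Hstack, final = H, cache = cache, xs = xs,
       reverse = reverse)
}

lstm_cell_backward <- function(p, fwres, dHstack, dHfinal = NULL) {
  cache <- fwres$cache; xs <- fwres$xs
  Tn <- xs$Tn; B <- xs$B; h <- nrow(p$Wh)
  dWh <- matrix(0, h, 4 * h)
  dZstack <- matrix(0, Tn * B, 4 * h)
  dHnext <- NULL; dCnext <- NULL
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    dH <- if (is.null(dHnext)) matrix(0, B, h) else dHnext
    if (!is.null(dHstack)) dH <- dH + dHstack[blk(t, B), , drop = FALSE]
    if (t == Tn && !is.null(dHfinal)) dH <- dH + dHfinal
    dC <- dH * k$o * (1 - k$tc^2)
    if (!is.null(dCnext)) dC <- dC + dCnext
    do <- dH * k$tc * k$o * (1 - k$o)
    di <- dC * k$g * k$i * (1 - k$i)
    df <- dC * k$cprev * k$f * (1 - k$f)
    dg <- dC * k$i * (1 - k$g^2)
    dZ <- cbind(di, df, dg, do)
    dZstack[blk(t, B), ] <- dZ
    dWh <- dWh + crossprod(k$hprev, dZ)
    dHnext <- tcrossprod(dZ, p$Wh)
    dCnext <- dC * k$f
  }
  # dZstack is in processing order; map back to input time order
  if (fwres$reverse) dZstack <- dZstack[rev_index(Tn, B), , drop = FALSE]
  list(grads = list(Wx = crossprod(xs$stack, dZstack), Wh = dWh,
                    b = colSums(dZstack)),
       dXstack = tcrossprod(dZstack, p$Wx))
}

gru_cell_forward <- function(p, xs, reverse = FALSE) {
  Tn <- xs$Tn; B <- xs$B; h <- nrow(p$Wh)
  i1 <- 1:h; i2 <- h + i1; i3 <- 2 * h + i1
  XW <- xs$stack %*% p$Wx
  bmat <- matrix(p$b, B, 3 * h, byrow = TRUE)
  H <- matrix(0, B, h)
  Hstack <- matrix(0, Tn * B, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    src <- if (reverse) Tn + 1L - t else t
    Zx <- XW[blk(src, B), , drop = FALSE] + bmat
    Zh <- H %*% p$Wh[, c(i1, i2), drop = FALSE]
    z <- sigm(Zx[, i1, drop = FALSE] + Zh[, i1, drop = FALSE])
    r <- sigm(Zx[, i2, drop = FALSE] + Zh[, i2, drop = FALSE])
    rh <- r * H
    hb <- tanh(Zx[, i3, drop = FALSE] + rh %*% p$Wh[, i3, drop = FALSE])
    Hn <- z * H + (1 - z) * hb
    cache[[t]] <- list(hprev = H, z = z, r = r, rh = rh, hb = hb)
    H <- Hn
    Hstack[blk(t, B), ] <- Hn
  }
  list(Hstack = Hstack, final = H, cache = cache, xs = xs,
       reverse = reverse)
}

gru_cell_backward <- function(p, fwres, dHstack, dHfinal = NULL) {
  cache <- fwres$cache; xs <- fwres$xs
  Tn <- xs$Tn; B <- xs$B; h <- nrow(p$Wh)
  i1 <- 1:h; i2 <- h + i1; i3 <- 2 * h + i1
  dWh <- matrix(0, h, 3 * h)
  dZstack <- matrix(0, Tn * B, 3 * h)
  dHnext <- NULL
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    dH <- if (is.null(dHnext)) matrix(0, B, h) else dHnext
    if (!is.null(dHstack)) dH <- dH + dHstack[blk(t, B), , drop = FALSE]
    if (t == Tn && !is.null(dHfinal)) dH <- dH + dHfinal
    dz <- dH * (k$hprev - k$hb) * k$z * (1 - k$z)
    dhb_pre <- dH * (1 - k$z) * (1 - k$hb^2)
    drh <- tcrossprod(dhb_pre, p$Wh[, i3, drop = FALSE])
    dr <- drh * k$hprev * k$r * (1 - k$r)
    dZx <- cbind(dz, dr, dhb_pre)
    dZstack[blk(t, B), ] <- dZx
    dWh[, c(i1, i2)] <- dWh[, c(i1, i2), drop = FALSE] +
      crossprod(k$hprev, cbind(dz, dr))
    dWh[, i3] <- dWh[, i3, drop = FALSE] + crossprod(k$rh, dhb_pre)
    dHnext <- dH * k$z +
      tcrossprod(cbind(dz, dr), p$Wh[, c(i1, i2), drop = FALSE]) +
      drh * k$r
  }
  if (fwres$reverse) dZstack <- dZstack[rev_index(Tn, B), , drop = FALSE]
  list(grads = list(Wx = crossprod(xs$stack, dZstack), Wh = dWh,
                    b = colSums(dZstack)),
       dXstack = tcrossprod(dZstack, p$Wx))
}

use_cpp_cells <- function() isTRUE(getOption("gensmiles.use_cpp", TRUE))

# The compiled kernels are the production path; the pure-R cell functions
# above are retained as the reference implementation and cross-checked in
# the test suite. keep_cache = FALSE skips cache retention on inference-
# only passes (generation).
cell_forward <- function(unit, p, xs, reverse = FALSE, keep_cache = TRUE) {
  if (!is.null(xs$ctx)) {
    # one-hot context indices: gather path (LSTM + compiled only; callers
    # densify for the other combinations)
    res <- lstm_forward_idx_cpp(p$Wx, p$Wh, p$b, xs$ctx, reverse, keep_cache)
    return(list(Hstack = res$Hstack, final = res$final, cpp_idx = res$cache,
                xs = xs, reverse = reverse))
  }
  if (!use_cpp_cells()) {
    return(if (unit == "LSTM") lstm_cell_forward(p, xs, reverse)
           else gru_cell_forward(p, xs, reverse))
  }
  res <- if (unit == "LSTM") {
    lstm_forward_cpp(p$Wx, p$Wh, p$b, xs$stack, xs$Tn, xs$B, reverse,
                     keep_cache)
  } else {
    gru_forward_cpp(p$Wx, p$Wh, p$b, xs$stack, xs$Tn, xs$B, reverse,
                    keep_cache)
  }
  list(Hstack = res$Hstack, final = res$final, cpp = res$cache, xs = xs,
       reverse = reverse)
}

cell_backward <- function(unit, p, fwres, dHstack, dHfinal = NULL) {
  if (!is.null(fwres$cpp_idx)) {
    none <- matrix(0, 0, 0)
    res <- lstm_backward_idx_cpp(fwres$cpp_idx, p$Wx, p$Wh,
                                 if (is.null(dHstack)) none else dHstack,
                                 if (is.null(dHfinal)) none else dHfinal)
    return(list(grads = list(Wx = res$dWx, Wh = res$dWh,
                             b = as.vector(res$db)),
                dXstack = NULL))
  }
  if (is.null(fwres$cpp)) {
    return(if (unit == "LSTM") lstm_cell_backward(p, fwres, dHstack, dHfinal)
           else gru_cell_backward(p, fwres, dHstack, dHfinal))
  }
  none <- matrix(0, 0, 0)
  dHs <- if (is.null(dHstack)) none else dHstack
  dHf <- if (is.null(dHfinal)) none else dHfinal
  res <- if (unit == "LSTM") {
    lstm_backward_cpp(fwres$cpp, p$Wx, p$Wh, dHs, dHf)
  } else {
    gru_backward_cpp(fwres$cpp, p$Wx, p$Wh, dHs, dHf)
  }
  list(grads = list(Wx = res$dWx, Wh = res$dWh, b = as.vector(res$db)),
       dXstack = res$dXstack)
}

# ------------------------------------------------- (bi)directional layer --

init_layer <- function(unit, d, h, bidirectional) {
  if (bidirectional) {
    list(fwd = init_cell(unit, d, h), bwd = init_cell(unit, d, h))
  } else {
    list(fwd = init_cell(unit, d, h))
  }
}

layer_out_width <- function(p) {
  nrow(p$fwd$Wh) * (1L + as.integer(!is.null(p$bwd)))
}

# xs: seq_stack. return_sequences yields a seq_stack in original time
# order (bidirectional: forward and backward features side by side);
# otherwise the final hidden state(s) as a B x width matrix.
layer_forward <- function(unit, p, xs, return_sequences, keep_cache = TRUE) {
  Tn <- xs$Tn; B <- xs$B
  f <- cell_forward(unit, p$fwd, xs, reverse = FALSE, keep_cache = keep_cache)
  if (is.null(p$bwd)) {
    out <- if (return_sequences) seq_stack(f$Hstack, Tn, B) else f$final
    return(list(out = out, cache = list(f = f)))
  }
  b <- cell_forward(unit, p$bwd, xs, reverse = TRUE, keep_cache = keep_cache)
  if (return_sequences) {
    out <- seq_stack(cbind(f$Hstack, b$Hstack[rev_index(Tn, B), , drop = FALSE]),
                     Tn, B)
  } else {
    out <- cbind(f$final, b$final)
  }
  list(out = out, cache = list(f = f, b = b))
}

# dOut: seq_stack-shaped gradient matrix (original time order) or a final
# state gradient. Returns grads and the input-stack gradient.
layer_backward <- function(unit, p, cache, dOut, return_sequences) {
  h <- nrow(p$fwd$Wh)
  if (is.null(p$bwd)) {
    if (return_sequences) {
      res <- cell_backward(unit, p$fwd, cache$f, dOut$stack)
    } else {
      res <- cell_backward(unit, p$fwd, cache$f, NULL, dHfinal = dOut)
    }
    return(list(grads = list(fwd = res$grads), dXstack = res$dXstack))
  }
  if (return_sequences) {
    Tn <- cache$f$xs$Tn; B <- cache$f$xs$B
    ridx <- rev_index(Tn, B)
    rf <- cell_backward(unit, p$fwd, cache$f, dOut$stack[, 1:h, drop = FALSE])
    rb <- cell_backward(unit, p$bwd, cache$b,
                        dOut$stack[ridx, h + 1:h, drop = FALSE])
  } else {
    rf <- cell_backward(unit, p$fwd, cache$f, NULL,
                        dHfinal = dOut[, 1:h, drop = FALSE])
    rb <- cell_backward(unit, p$bwd, cache$b, NULL,
                        dHfinal = dOut[, h + 1:h, drop = FALSE])
  }
  dXstack <- if (is.null(rf$dXstack) || is.null(rb$dXstack)) NULL
             else rf$dXstack + rb$dXstack
  list(grads = list(fwd = rf$grads, bwd = rb$grads), dXstack = dXstack)
}

# ------------------------------------------------------------ merge ops --

#' Learnable weighted average of parallel branch representations
#'
#' Combines k equal-width representations as `sum_i w_i B_i` where the
#' weights are a softmax over k trainable logits, hence non-negative and
#' summing to one. At equal logits (the initialization) this is a plain
#' average; as one logit dominates, the merge converges to that branch
#' alone.
#'
#' @param branches list of k numeric matrices of identical dimensions.
#' @param logits numeric vector of k trainable logits (default all zero).
#' @return list with `merged` (matrix) and `weights` (softmax of logits).
#' @export
learnable_average_merge <- function(branches, logits = rep(0, length(branches))) {
  k <- length(branches)
  stopifnot(k >= 1, length(logits) == k)
  dims <- vapply(branches, dim, integer(2))
  if (k > 1 && any(dims != dims[, 1])) {
    stop("learnable average requires equal branch widths")
  }
  if (k == 1) warning("learnable average over a single branch is the identity")
  w <- exp(logits - max(logits)); w <- w / sum(w)
  merged <- Reduce(`+`, Map(function(b, wi) wi * b, branches, w))
  list(merged = merged, weights = w)
}

merge_forward <- function(mode, branches, logits = NULL) {
  k <- length(branches)
  if (k == 1) return(list(merged = branches[[1]], weights = 1))
  switch(mode,
    concatenate = list(merged = do.call(cbind, branches), weights = NULL),
    average = list(merged = Reduce(`+`, branches) / k, weights = rep(1 / k, k)),
    learnable_average = learnable_average_merge(branches, logits))
}

merge_backward <- function(mode, branches, weights, dM) {
  k <- length(branches)
  if (k == 1) return(list(dBranches = list(dM), dLogits = NULL))
  if (mode == "concatenate") {
    w <- ncol(branches[[1]])
    dB <- lapply(seq_len(k), function(i) dM[, (i - 1) * w + 1:w, drop = FALSE])
    return(list(dBranches = dB, dLogits = NULL))
  }
  if (mode == "average") {
    return(list(dBranches = rep(list(dM / k), k), dLogits = NULL))
  }
  # learnable average: dB_i = w_i dM; dlogit via softmax jacobian
  dB <- lapply(seq_len(k), function(i) weights[i] * dM)
  s <- vapply(seq_len(k), function(i) sum(dM * branches[[i]]), 0)
  dLogits <- weights * (s - sum(weights * s))
  list(dBranches = dB, dLogits = dLogits)
}

# ------------------------------------------------------------ the model --

#' Build a generator network
#'
#' Instantiates the parameters of the architecture described by `spec` for
#' a vocabulary of `vocab_size` symbols and context windows of
#' `window_length` characters. The network maps a one-hot `W x V` context
#' to a length-V softmax over the next character.
#'
#' @param spec a [architecture_spec()].
#' @param vocab_size number of symbols V (>= 2).
#' @param window_length context length W (>= 1).
#' @param seed integer seed for weight initialization.
#' @return object of class `gen_model`.
#' @export
build_network <- function(spec, vocab_size, window_length, seed = 1L) {
  stopifnot(inherits(spec, "gen_architecture"), vocab_size >= 2,
            window_length >= 1)
  V <- as.integer(vocab_size)
  set.seed(seed)
  unit <- spec$unit
  e_w <- spec$embedding_size * (1L + spec$bidirectional_embedding)
  c_w <- spec$encoding_size * (1L + spec$bidirectional_encoding)
  k <- spec$branch_count
  if (k > 1 && spec$merge_mode != "concatenate" && spec$family == "D") {
    # widths are equal by construction here, but keep the contract explicit
  }
  params <- list()
  if (spec$family == "D") {
    params$branches <- lapply(seq_len(k), function(i) {
      list(emb = init_layer(unit, V, spec$embedding_size,
                            spec$bidirectional_embedding),
           enc = init_layer(unit, e_w, spec$encoding_size,
                            spec$bidirectional_encoding))
    })
  } else {
    params$emb <- init_layer(unit, V, spec$embedding_size,
                             spec$bidirectional_embedding)
    params$encoders <- lapply(seq_len(k), function(i) {
      init_layer(unit, e_w, spec$encoding_size, spec$bidirectional_encoding)
    })
  }
  m_w <- if (spec$merge_mode == "concatenate") k * c_w else c_w
  if (spec$merge_mode == "learnable_average" && k > 1) {
    params$merge_logits <- numeric(k)
  }
  params$dense <- list(W = glorot(m_w, V), b = numeric(V))
  structure(list(spec = spec, V = V, W = as.integer(window_length),
                 params = params),
            class = "gen_model")
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<gen_model> V =", x$V, ", window =", x$W, ",",
      format(count_params(x), big.mark = ","), "parameters\n")
  print(x$spec)
  invisible(x)
}

#' Total trainable parameter count of a network
#' @param model a `gen_model`.
#' @return integer number of scalar parameters.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model$params)
  n
}

# Forward pass. X: a seq_stack of one-hot rows (see contexts_to_stack).
# Returns probs (B x V) and, when keep_cache, everything backward needs.
model_forward <- function(model, X, train = FALSE, keep_cache = train) {
  spec <- model$spec; p <- model$params
  unit <- spec$unit; k <- spec$branch_count
  if (!is.null(X$ctx) && (unit != "LSTM" || !use_cpp_cells())) {
    X <- contexts_to_stack(X$ctx, model$V)
  }
  if (spec$family == "D") {
    emb_caches <- vector("list", k); enc_caches <- vector("list", k)
    branch_outs <- vector("list", k)
    for (i in seq_len(k)) {
      e <- layer_forward(unit, p$branches[[i]]$emb, X, TRUE, keep_cache)
      g <- layer_forward(unit, p$branches[[i]]$enc, e$out, FALSE, keep_cache)
      emb_caches[[i]] <- e$cache; enc_caches[[i]] <- g$cache
      branch_outs[[i]] <- g$out
    }
  } else {
    e <- layer_forward(unit, p$emb, X, TRUE, keep_cache)
    enc_caches <- vector("list", k)
    branch_outs <- vector("list", k)
    for (i in seq_len(k)) {
      g <- layer_forward(unit, p$encoders[[i]], e$out, FALSE, keep_cache)
      enc_caches[[i]] <- g$cache
      branch_outs[[i]] <- g$out
    }
    emb_caches <- e$cache
  }
  mg <- merge_forward(spec$merge_mode, branch_outs, p$merge_logits)
  M <- mg$merged
  mask <- NULL
  if (train && spec$dropout_rate > 0) {
    mask <- (matrix(stats::runif(length(M)), nrow(M), ncol(M)) >=
               spec$dropout_rate) / (1 - spec$dropout_rate)
    M <- M * mask
  }
  logits <- M %*% p$dense$W + matrix(p$dense$b, nrow(M), model$V, byrow = TRUE)
  probs <- softmax_rows(logits)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(branch_outs = branch_outs, merged_weights = mg$weights,
                    M = M, mask = mask, emb_caches = emb_caches,
                    enc_caches = enc_caches))
}

# dLogits = (probs - Y) / B. Returns a gradient tree shaped like params.
model_backward <- function(model, X, fw, dLogits) {
  spec <- model$spec; p <- model$params
  unit <- spec$unit; k <- spec$branch_count
  ca <- fw$cache
  grads <- list()
  grads$dense <- list(W = crossprod(ca$M, dLogits), b = colSums(dLogits))
  dM <- tcrossprod(dLogits, p$dense$W)
  if (!is.null(ca$mask)) dM <- dM * ca$mask
  mb <- merge_backward(spec$merge_mode, ca$branch_outs, ca$merged_weights, dM)
  if (!is.null(mb$dLogits)) grads$merge_logits <- mb$dLogits
  if (spec$family == "D") {
    grads$branches <- vector("list", k)
    for (i in seq_len(k)) {
      gb <- layer_backward(unit, p$branches[[i]]$enc, ca$enc_caches[[i]],
                           mb$dBranches[[i]], FALSE)
      eb <- layer_backward(unit, p$branches[[i]]$emb, ca$emb_caches[[i]],
                           seq_stack(gb$dXstack, X$Tn, X$B), TRUE)
      grads$branches[[i]] <- list(emb = eb$grads, enc = gb$grads)
    }
  } else {
    dEmbStack <- NULL
    grads$encoders <- vector("list", k)
    for (i in seq_len(k)) {
      gb <- layer_backward(unit, p$encoders[[i]], ca$enc_caches[[i]],
                           mb$dBranches[[i]], FALSE)
      grads$encoders[[i]] <- gb$grads
      dEmbStack <- if (is.null(dEmbStack)) gb$dXstack else dEmbStack + gb$dXstack
    }
    eb <- layer_backward(unit, p$emb, ca$emb_caches,
                         seq_stack(dEmbStack, X$Tn, X$B), TRUE)
    grads$emb <- eb$grads
  }
  grads
}
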