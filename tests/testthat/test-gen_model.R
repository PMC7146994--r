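# Network construction, widths, merges, gradients and sampling.

test_that("architecture constraints are enforced", {
  expect_error(architecture_spec("A", branch_count = 2), "single branch")
  s <- architecture_spec("B", "LSTM", 256, 256)
  expect_true(s$bidirectional_embedding && s$bidirectional_encoding)
  expect_false(architecture_spec("A")$bidirectional_embedding)
  expect_equal(architecture_spec("C")$branch_count, 4L)
})

test_that("parameter counts match the closed-form oracle", {
  V <- 23L
  cases <- list(
    architecture_spec("A", "LSTM", 256, 256),
    architecture_spec("A", "GRU", 256, 256),
    architecture_spec("B", "LSTM", 256, 256),
    architecture_spec("B", "GRU", 64, 64),
    architecture_spec("C", "LSTM", 64, 64, branch_count = 4),
    architecture_spec("C", "LSTM", 64, 64, branch_count = 4,
                      merge_mode = "average"),
    architecture_spec("C", "LSTM", 64, 64, branch_count = 4,
                      merge_mode = "learnable_average"),
    architecture_spec("D", "LSTM", 64, 64, branch_count = 4),
    architecture_spec("C", "LSTM", 128, 64, branch_count = 4))
  for (spec in cases) {
    model <- build_network(spec, V, 10, seed = 1)
    expect_equal(count_params(model), params_architecture(spec, V),
                 info = format(spec))
  }
})

test_that("merged representation widths follow the family arithmetic", {
  V <- 12L
  m <- build_network(architecture_spec("C", "LSTM", 64, 64, branch_count = 4),
                     V, 6, seed = 1)
  expect_equal(nrow(m$params$dense$W), 4 * 128)
  m2 <- build_network(architecture_spec("C", "LSTM", 64, 64, branch_count = 4,
                                        merge_mode = "average"), V, 6, seed = 1)
  expect_equal(nrow(m2$params$dense$W), 128)
  mB <- build_network(architecture_spec("B", "LSTM", 256, 256), V, 6, seed = 1)
  expect_equal(nrow(mB$params$dense$W), 512)
})

test_that("softmax output is a probability vector", {
  set.seed(4)
  m <- build_network(architecture_spec("C", "GRU", 8, 8, branch_count = 2),
                     7L, 5L, seed = 2)
  ctx <- matrix(sample(0:6, 5 * 9, TRUE), 9, 5)
  probs <- gensmiles:::model_forward(m, gensmiles:::contexts_to_stack(ctx, 7L))$probs
  expect_equal(rowSums(probs), rep(1, 9), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("learnable average merge is a convex combination", {
  b <- list(matrix(1:6, 2), matrix(7:12, 2), matrix(0, 2, 3))
  eq <- learnable_average_merge(b, c(0, 0, 0))
  expect_equal(eq$weights, rep(1 / 3, 3))
  expect_equal(eq$merged, (b[[1]] + b[[2]] + b[[3]]) / 3)
  dom <- learnable_average_merge(b, c(60, 0, 0))
  expect_equal(dom$merged, b[[1]], tolerance = 1e-20)
  expect_equal(sum(dom$weights), 1)
  expect_warning(learnable_average_merge(b[1]), "identity")
  expect_error(learnable_average_merge(list(matrix(0, 2, 3), matrix(0, 2, 4))),
               "equal branch widths")
})

test_that("C with k=1 is forward-equivalent to B on identical weights", {
  V <- 9L; W <- 6L
  sB <- architecture_spec("B", "LSTM", 12, 12, dropout_rate = 0)
  sC <- architecture_spec("C", "LSTM", 12, 12, branch_count = 1,
                          dropout_rate = 0)
  mB <- build_network(sB, V, W, seed = 3)
  mC <- build_network(sC, V, W, seed = 99)
  mC$params$emb <- mB$params$emb
  mC$params$encoders[[1]] <- mB$params$encoders[[1]]
  mC$params$dense <- mB$params$dense
  ctx <- matrix(sample(0:(V - 1), W * 8, TRUE), 8, W)
  X <- gensmiles:::contexts_to_stack(ctx, V)
  expect_equal(gensmiles:::model_forward(mC, X)$probs,
               gensmiles:::model_forward(mB, X)$probs, tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  # one representative per family; every leaf's first entries are checked
  specs <- list(
    architecture_spec("B", "LSTM", 5, 5, dropout_rate = 0),
    architecture_spec("C", "GRU", 5, 5, branch_count = 2,
                      merge_mode = "learnable_average", dropout_rate = 0),
    architecture_spec("D", "LSTM", 4, 4, branch_count = 2, dropout_rate = 0))
  V <- 6L; W <- 4L; B <- 3L
  for (spec in specs) {
    model <- build_network(spec, V, W, seed = 5)
    set.seed(6)
    ctx <- matrix(sample(0:(V - 1), B * W, TRUE), B, W)
    X <- gensmiles:::contexts_to_stack(ctx, V)
    Y <- gensmiles:::one_hot(sample(0:(V - 1), B, TRUE), V)
    loss_of <- function(m) {
      -sum(Y * log(gensmiles:::model_forward(m, X)$probs + 1e-12)) / B
    }
    fw <- gensmiles:::model_forward(model, X, keep_cache = TRUE)
    grads <- gensmiles:::model_backward(model, X, fw, (fw$probs - Y) / B)
    walk <- function(path, g) {
      if (is.numeric(g)) {
        for (j in seq_len(min(3, length(g)))) {
          eps <- 1e-5
          bump <- function(d) {
            m2 <- model
            sel <- paste0("m2$params",
                          paste0("[[", vapply(path, function(x) {
                            if (is.character(x)) paste0('"', x, '"') else as.character(x)
                          }, ""), "]]", collapse = ""))
            val <- eval(parse(text = sel))
            val[j] <- val[j] + d
            eval(parse(text = paste0(sel, " <- val")))
            m2
          }
          num <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
          expect_equal(g[j], num, tolerance = 1e-4)
        }
      } else {
        for (nm in seq_along(g)) {
          key <- if (!is.null(names(g)) && nzchar(names(g)[nm])) names(g)[nm] else nm
          walk(c(path, list(key)), g[[key]])
        }
      }
    }
    walk(list(), grads)
  }
})

test_that("training is deterministic and the examiner cannot touch weights", {
  texts <- substitute_tokens(fixture_corpus()[1:40])
  vocab <- build_vocabulary(texts)
  corpus <- encode_windows(texts, vocab, window_length = 8, step = 4)
  spec <- architecture_spec("A", "GRU", 6, 6)
  run <- function() {
    m <- build_network(spec, vocab_size(vocab), 8, seed = 2)
    train_network(m, corpus, max_epochs = 2, seed = 9, batch_size = 64)
  }
  f1 <- run(); f2 <- run()
  expect_equal(vapply(f1$checkpoints, `[[`, 0, "loss"),
               vapply(f2$checkpoints, `[[`, 0, "loss"))
  expect_equal(f1$model$params, f2$model$params)

  # an examiner that merely samples must not alter training trajectory
  m <- build_network(spec, vocab_size(vocab), 8, seed = 2)
  probe <- function(model, epoch) {
    before <- model$params
    s <- sample_strings(model, vocab, 10, seed = epoch, window_length = 8,
                        max_length = 30)
    expect_identical(model$params, before)
    list(stop = FALSE, record = list(validity = NA))
  }
  f3 <- train_network(m, corpus, max_epochs = 2, examiner = probe, seed = 9,
                      batch_size = 64)
  expect_equal(vapply(f3$checkpoints, `[[`, 0, "loss"),
               vapply(f1$checkpoints, `[[`, 0, "loss"))
})

test_that("an examiner stopping at epoch 1 yields exactly one checkpoint", {
  texts <- substitute_tokens(fixture_corpus()[1:20])
  vocab <- build_vocabulary(texts)
  corpus <- encode_windows(texts, vocab, window_length = 6, step = 5)
  m <- build_network(architecture_spec("A", "GRU", 4, 4),
                     vocab_size(vocab), 6, seed = 1)
  fit <- train_network(m, corpus, max_epochs = 10,
                       examiner = function(model, epoch) {
                         list(stop = TRUE, record = list(validity = 0))
                       }, seed = 1)
  expect_equal(fit$epochs_run, 1L)
  expect_true(fit$stopped_early)
})

test_that("generate_smiles honors stubs, seeds and edge cases", {
  texts <- substitute_tokens(c("CCO", "CCN"))
  vocab <- build_vocabulary(texts)
  V <- vocab_size(vocab)
  # argmax stub deterministically spelling C, C, O, terminator
  spell <- c("C", "C", "O", vocab$terminator)
  stub <- function(contexts, vc) {
    probs <- matrix(1e-9, nrow(contexts), V)
    for (r in seq_len(nrow(contexts))) {
      # characters emitted since the last terminator in the window
      seen <- ncol(contexts) - max(which(contexts[r, ] == vc$terminator_index))
      target <- spell[min(seen + 1L, length(spell))]
      probs[r, vc$char_to_index[[target]] + 1L] <- 1
    }
    probs / rowSums(probs)
  }
  b <- generate_smiles(stub, vocab, 5, mode = "argmax", window_length = 6,
                       seed = 1)
  expect_equal(b$strings, rep("CCO", 5))
  expect_false(any(b$truncated))

  expect_equal(length(generate_smiles(stub, vocab, 0, window_length = 6)$strings), 0L)
  expect_error(generate_smiles(stub, vocab, 1, temperature = 0,
                               window_length = 6), "positive")

  b1 <- generate_smiles(stub, vocab, 20, seed = 42, window_length = 6)
  b2 <- generate_smiles(stub, vocab, 20, seed = 42, window_length = 6)
  expect_identical(b1$strings, b2$strings)

  # truncation flagging: a stub that never emits the terminator
  never <- function(contexts, vc) {
    probs <- matrix(0, nrow(contexts), V)
    probs[, vc$char_to_index[["C"]] + 1L] <- 1
    probs
  }
  bt <- generate_smiles(never, vocab, 3, max_length = 7, window_length = 6,
                        seed = 1)
  expect_true(all(bt$truncated))
  expect_equal(bt$strings, rep("CCCCCCC", 3))
})

test_that("multinomial sampling tracks a uniform stub within 3 sigma", {
  vocab <- build_vocabulary("CNO")  # V = 4 incl terminator
  V <- vocab_size(vocab)
  uniform <- function(contexts, vc) matrix(1 / V, nrow(contexts), V)
  b <- generate_smiles(uniform, vocab, 400, window_length = 4, seed = 8,
                       max_length = 50)
  chars <- unlist(strsplit(paste(b$strings, collapse = ""), ""))
  n <- length(chars)
  counts <- table(factor(chars, levels = c("C", "N", "O")))
  # each emitted non-terminator character is uniform over the 3 symbols
  p <- 1 / 3
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < 3 * sigma))
})
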