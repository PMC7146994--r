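# Sampling SMILES strings from a trained network (or any stub that maps a
# context window to next-character probabilities -- used by tests).

# probs: B x V row-stochastic matrix -> 0-based sampled indices
sample_rows <- function(probs, temperature, argmax) {
  if (argmax) return(max.col(probs, ties.method = "first") - 1L)
  if (temperature != 1) {
    probs <- probs^(1 / temperature)
    probs <- probs / rowSums(probs)
  }
  cum <- t(apply(probs, 1, cumsum))
  u <- stats::runif(nrow(probs))
  # guard the 0-based index against u landing beyond a cumsum that fell
  # epsilon short of 1
  pmin(as.integer(rowSums(cum < u)), ncol(probs) - 1L)
}

next_char_probs <- function(model, contexts, vocab) {
  if (is.function(model)) return(model(contexts, vocab))
  model_forward(model, contexts_idx(contexts), train = FALSE,
                keep_cache = FALSE)$probs
}

#' Generate SMILES strings from a model
#'
#' Sampling runs in parallel "lanes". Every lane starts from a context of
#' W terminators; the next character is drawn from the softmax
#' (multinomial at the given temperature, or argmax when
#' `mode = "argmax"`) and a terminator ends the current string.
#'
#' By default the context *slides across string boundaries*, exactly the
#' structure of the training corpus, where each molecule is conditioned
#' on the (valid) molecule that precedes it. To keep that conditioning
#' in-distribution, a lane only *counts* strings while "warm": after
#' emitting a string that is terminator-ended and ring/parenthesis
#' balanced. Cold lanes (at start, or after an ill-formed string, whose
#' trailing context would otherwise contaminate every following sample in
#' the lane) discard strings until one is well formed, up to `burn_in`
#' attempts per cold phase, after which the lane counts strings anyway
#' (so hopeless early-epoch models still measure, near 0% validity).
#' Without this warm/cold discipline, failures within a lane are strongly
#' correlated and the examiner's validity estimate carries far more than
#' binomial noise. `continue_context = FALSE` gives the literal
#' reset-to-terminators behavior: every string starts cold and all count.
#'
#' Strings reaching `max_length` without a terminator are flagged
#' truncated and still count as generated candidates when warm. Every
#' output is desubstituted (`L`/`R`/`A` back to `Cl`/`Br`/`[nH]`) before
#' return.
#'
#' @param model a `gen_model`, or (for testing) a function
#'   `(contexts, vocab) -> B x V probability matrix` over 0-based context
#'   index matrices.
#' @param vocab the `gen_vocabulary` used to train the model.
#' @param n number of strings to generate (>= 0).
#' @param temperature positive sampling temperature (default 1.0).
#' @param max_length per-string character budget (default 120).
#' @param seed integer seed; fixed seed gives an identical batch.
#' @param mode `"sample"` (default) or `"argmax"` (deterministic; tests).
#' @param window_length context length, required for function stubs
#'   (defaults to `model$W`).
#' @param lanes number of parallel generation lanes.
#' @param burn_in discarded warm-up attempts per cold phase (default 5;
#'   ignored when `continue_context = FALSE`).
#' @param continue_context slide the context across string boundaries
#'   (default `TRUE`).
#' @return object of class `gen_batch`: `strings` (desubstituted SMILES),
#'   `truncated` (logical), plus the sampling settings.
#' @export
generate_smiles <- function(model, vocab, n, temperature = 1.0,
                            max_length = 120L, seed = 1L,
                            mode = c("sample", "argmax"),
                            window_length = NULL,
                            lanes = min(n, 50L), burn_in = 5L,
                            continue_context = TRUE) {
  mode <- match.arg(mode)
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(n >= 0)
  W <- if (!is.null(window_length)) as.integer(window_length) else model$W
  term <- vocab$terminator_index
  if (n == 0) {
    return(structure(list(strings = character(0), truncated = logical(0),
                          temperature = temperature,
                          max_length = as.integer(max_length),
                          seed = as.integer(seed), mode = mode),
                     class = "gen_batch"))
  }
  set.seed(seed)
  L <- max(1L, min(as.integer(lanes), n))
  quota <- rep(n %/% L, L)
  if (n %% L > 0) quota[seq_len(n %% L)] <- quota[seq_len(n %% L)] + 1L

  contexts <- matrix(term, L, W)
  buf <- matrix(NA_integer_, L, max_length)
  len <- integer(L)
  done <- vector("list", L)        # per lane: finished counted strings
  trunc_flags <- vector("list", L)
  warm <- rep(!continue_context || burn_in == 0L, L)
  burns <- integer(L)
  active <- quota > 0L

  finish_string <- function(i, truncated) {
    s <- if (len[i] > 0) indices_to_chars(buf[i, seq_len(len[i])], vocab) else ""
    well_formed <- !truncated && len[i] > 0 && ring_branch_balanced(s)
    if (!continue_context) {
      # literal mode: count everything, always restart cold
      done[[i]] <<- c(done[[i]], s)
      trunc_flags[[i]] <<- c(trunc_flags[[i]], truncated)
      if (length(done[[i]]) >= quota[i]) active[i] <<- FALSE
      contexts[i, ] <<- term
    } else if (warm[i]) {
      done[[i]] <<- c(done[[i]], s)
      trunc_flags[[i]] <<- c(trunc_flags[[i]], truncated)
      if (length(done[[i]]) >= quota[i]) active[i] <<- FALSE
      if (!well_formed) {
        warm[i] <<- FALSE
        burns[i] <<- 0L
        contexts[i, ] <<- term
      } else if (truncated) {
        contexts[i, ] <<- c(contexts[i, -1L], term)
      }
    } else {
      burns[i] <<- burns[i] + 1L
      if (well_formed) {
        warm[i] <<- TRUE           # context continues from the good string
      } else if (burns[i] >= burn_in) {
        warm[i] <<- TRUE           # give up warming; count from cold starts
        contexts[i, ] <<- term
      } else {
        contexts[i, ] <<- term
      }
    }
    len[i] <<- 0L
  }

  while (any(active)) {
    rows <- which(active)
    probs <- next_char_probs(model, contexts[rows, , drop = FALSE], vocab)
    idx <- sample_rows(probs, temperature, mode == "argmax")
    if (continue_context) {
      contexts[rows, ] <- cbind(contexts[rows, -1L, drop = FALSE], idx)
    }
    for (j in seq_along(rows)) {
      i <- rows[j]
      if (idx[j] == term) {
        finish_string(i, FALSE)
      } else {
        len[i] <- len[i] + 1L
        buf[i, len[i]] <- idx[j]
        if (!continue_context) {
          contexts[i, ] <- c(contexts[i, -1L], idx[j])
        }
        if (len[i] >= max_length) {
          finish_string(i, TRUE)
        }
      }
    }
  }
  strings <- unlist(done, use.names = FALSE)
  truncated <- unlist(trunc_flags, use.names = FALSE)
  stopifnot(length(strings) == n)
  structure(list(strings = desubstitute_tokens(strings),
                 truncated = truncated,
                 temperature = temperature,
                 max_length = as.integer(max_length),
                 seed = as.integer(seed), mode = mode),
            class = "gen_batch")
}

#' @export
print.gen_batch <- function(x, ...) {
  cat("<gen_batch>", length(x$strings), "strings,",
      sum(x$truncated), "truncated, temperature", x$temperature, "\n")
  invisible(x)
}

#' Draw a sample of strings from a generator handle
#'
#' Generic used by the examiner so that real models and scripted mock
#' generators are interchangeable.
#'
#' @param generator a `gen_model`, probability-function stub, or
#'   `gen_mock_generator`.
#' @param vocab vocabulary (ignored by mocks).
#' @param n sample size.
#' @param seed integer seed.
#' @param ... passed on to the underlying sampler.
#' @return character vector of n candidate SMILES.
#' @export
sample_strings <- function(generator, vocab, n, seed, ...) {
  UseMethod("sample_strings")
}

#' @export
sample_strings.default <- function(generator, vocab, n, seed, ...) {
  generate_smiles(generator, vocab, n, seed = seed, ...)$strings
}
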