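# Vocabulary construction and next-character window encoding.
#
# The corpus is a terminator-joined stream of substituted SMILES; training
# examples pair a fixed-length character window with the character that
# follows it (many-to-one next-character prediction). One-hot expansion is
# deferred to batch assembly at training time.

#' Build a character vocabulary from substituted corpus texts
#'
#' Inventory of observed characters, sorted for determinism, plus a
#' terminator symbol (default newline, which can never occur inside a
#' SMILES token and survives plain-text round trips). Indices are
#' contiguous `0..V-1`.
#'
#' @param corpus_texts character vector of substituted SMILES.
#' @param terminator single character marking end-of-string.
#' @return object of class `gen_vocabulary`: list with `chars`
#'   (index `i` holds character `i-1`), `char_to_index` (named integer,
#'   0-based), `terminator`, `terminator_index`, `substitutions`.
#' @export
build_vocabulary <- function(corpus_texts, terminator = "\n") {
  if (length(corpus_texts) == 0 || !any(nzchar(corpus_texts))) {
    stop("cannot build a vocabulary from an empty corpus")
  }
  stopifnot(nchar(terminator) == 1)
  if (any(grepl(terminator, corpus_texts, fixed = TRUE))) {
    stop("terminator character occurs inside the corpus")
  }
  chars <- sort(unique(strsplit(paste(corpus_texts, collapse = ""), "")[[1]]))
  chars <- c(chars, terminator)
  idx <- stats::setNames(seq_along(chars) - 1L, chars)
  structure(list(
    chars = chars,
    char_to_index = idx,
    terminator = terminator,
    terminator_index = unname(idx[terminator]),
    substitutions = SUBSTITUTIONS
  ), class = "gen_vocabulary")
}

#' @export
print.gen_vocabulary <- function(x, ...) {
  shown <- vapply(x$chars, function(ch) {
    if (ch == "\n") "\\n" else ch
  }, "")
  cat("<gen_vocabulary> V =", length(x$chars), ":",
      paste(shown, collapse = " "), "\n")
  invisible(x)
}

#' Number of symbols in a vocabulary
#' @param vocab a `gen_vocabulary`.
#' @return integer V.
#' @export
vocab_size <- function(vocab) length(vocab$chars)

# characters -> 0-based index vector; errors on out-of-vocabulary symbols
chars_to_indices <- function(text, vocab) {
  ch <- strsplit(text, "")[[1]]
  idx <- vocab$char_to_index[ch]
  if (anyNA(idx)) {
    stop("character(s) outside vocabulary: ",
         paste(unique(ch[is.na(idx)]), collapse = " "))
  }
  unname(idx)
}

indices_to_chars <- function(idx, vocab) {
  paste(vocab$chars[idx + 1L], collapse = "")
}

#' Encode a corpus into next-character training windows
#'
#' The texts are joined by the terminator, prefixed by `window_length`
#' terminators (so generation can start from an all-terminator context) and
#' followed by one trailing terminator. Sliding windows of length W at the
#' given step each predict the immediately following character.
#'
#' @param corpus_texts character vector of substituted SMILES.
#' @param vocab `gen_vocabulary` covering every character of the corpus.
#' @param window_length window length W (default 40).
#' @param step stride between consecutive window starts (default 1).
#' @return object of class `gen_corpus`: `contexts` (integer matrix
#'   N x W of 0-based indices), `labels` (integer N, 0-based),
#'   `window_length`, `step`, `vocabulary`.
#' @export
encode_windows <- function(corpus_texts, vocab, window_length = 40L,
                           step = 1L) {
  stopifnot(window_length >= 1, step >= 1)
  W <- as.integer(window_length)
  joined <- paste0(
    strrep(vocab$terminator, W),
    paste(corpus_texts, collapse = vocab$terminator),
    vocab$terminator)
  idx <- chars_to_indices(joined, vocab)
  L <- length(idx)
  # L - W is the corpus length without the terminator prefix
  if (W > L - W) stop("window_length exceeds the total corpus length")
  starts <- seq.int(1L, L - W, by = step)
  pos <- outer(starts, 0:(W - 1L), "+")
  contexts <- matrix(idx[pos], nrow = length(starts), ncol = W)
  labels <- idx[starts + W]
  structure(list(
    contexts = contexts,
    labels = labels,
    window_length = W,
    step = as.integer(step),
    vocabulary = vocab
  ), class = "gen_corpus")
}

#' @export
print.gen_corpus <- function(x, ...) {
  cat("<gen_corpus>", nrow(x$contexts), "windows of length",
      x$window_length, "(step", x$step, "), V =",
      vocab_size(x$vocabulary), "\n")
  invisible(x)
}

# one-hot a 0-based index vector into a B x V matrix
one_hot <- function(idx, V) {
  m <- matrix(0, length(idx), V)
  m[cbind(seq_along(idx), idx + 1L)] <- 1
  m
}

# context index matrix (B x W) -> seq_stack of one-hot rows: the t-th row
# block of the (W*B) x V matrix is the batch at timestep t, which matches
# column-major order of the context matrix
# context index matrix as a lazily-one-hot sequence: the compiled LSTM
# embedding kernel gathers weight rows directly from the indices
contexts_idx <- function(contexts) {
  storage.mode(contexts) <- "integer"
  list(ctx = contexts, Tn = ncol(contexts), B = nrow(contexts))
}

contexts_to_stack <- function(contexts, V) {
  B <- nrow(contexts); W <- ncol(contexts)
  m <- matrix(0, B * W, V)
  m[cbind(seq_len(B * W), as.vector(contexts) + 1L)] <- 1
  seq_stack(m, W, B)
}
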