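# Shared fixtures, built once per test run (RDKit calls are batched and
# subprocess-based, so tests reuse these instead of regenerating).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# 300 valid-by-construction molecules plus their RDKit analysis
fixture_corpus <- function() {
  cached("corpus", function() {
    generate_fixture_corpus(fixture_spec(n_molecules = 300L, seed = 101L))
  })
}

fixture_analysis <- function() {
  cached("analysis", function() rdkit_analyze(fixture_corpus()))
}

# substituted texts + vocabulary for encoding/model tests
fixture_vocab <- function() {
  cached("vocab", function() {
    sub <- substitute_tokens(fixture_corpus())
    list(texts = sub, vocab = build_vocabulary(sub))
  })
}

# brute-force window enumerator: the independent oracle for encode_windows
enumerate_windows_bruteforce <- function(texts, vocab, W, step) {
  joined <- paste0(strrep(vocab$terminator, W),
                   paste(texts, collapse = vocab$terminator),
                   vocab$terminator)
  chars <- strsplit(joined, "")[[1]]
  ctx <- list(); lab <- integer(0)
  i <- 1L
  while (i + W <= length(chars)) {
    ctx[[length(ctx) + 1L]] <- unname(vocab$char_to_index[chars[i:(i + W - 1L)]])
    lab <- c(lab, unname(vocab$char_to_index[chars[i + W]]))
    i <- i + step
  }
  list(contexts = do.call(rbind, ctx), labels = lab)
}

# brute-force replay of the examination counter rules: the independent
# oracle for run_examination
replay_examination_bruteforce <- function(validities, lower, patience) {
  streak <- 0L
  for (e in seq_along(validities)) {
    if (validities[e] < lower) streak <- 0L else streak <- streak + 1L
    if (streak == patience) {
      return(list(stopped = e, selected = e - patience + 1L, converged = TRUE))
    }
  }
  n <- length(validities)
  sel <- if (streak > 0L) n - streak + 1L else which.max(validities)
  list(stopped = n, selected = sel, converged = FALSE)
}

# closed-form parameter counts: the algebraic oracle for count_params
params_recurrent <- function(unit, d, h) {
  gates <- if (unit == "LSTM") 4L else 3L
  gates * ((d + h + 1L) * h)
}

params_layer <- function(unit, d, h, bidirectional) {
  (1L + bidirectional) * params_recurrent(unit, d, h)
}

params_architecture <- function(spec, V) {
  e_w <- spec$embedding_size * (1L + spec$bidirectional_embedding)
  c_w <- spec$encoding_size * (1L + spec$bidirectional_encoding)
  k <- spec$branch_count
  emb <- params_layer(spec$unit, V, spec$embedding_size,
                      spec$bidirectional_embedding)
  enc <- params_layer(spec$unit, e_w, spec$encoding_size,
                      spec$bidirectional_encoding)
  merged <- if (spec$merge_mode == "concatenate") k * c_w else c_w
  n <- if (spec$family == "D") k * (emb + enc) else emb + k * enc
  n <- n + merged * V + V
  if (spec$merge_mode == "learnable_average" && k > 1) n <- n + k
  n
}
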