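# Evaluation suite: validity verdicts, summary rates, the 12-property
# panel with shared-bin histograms, continuous Tanimoto and Jensen-Shannon
# distribution matching, and the chunked novelty / efficiency analysis.

# ---- ring/branch token balance (failure classification only) -----------

# Scans a raw SMILES: ring-bond digits (outside square brackets, including
# %nn two-digit closures) must each occur an even number of times, and
# parentheses must balance without going negative. Used to *classify*
# failures; the validity verdict itself always comes from the toolkit.
ring_branch_balanced <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  in_bracket <- FALSE
  percent_pending <- 0L
  ring_counts <- integer(0)
  bump <- function(key) {
    cur <- if (!is.null(ring_counts[key]) && !is.na(ring_counts[key]))
      ring_counts[key] else 0L
    ring_counts[key] <<- cur + 1L
  }
  pct_key <- ""
  for (ch in chars) {
    if (in_bracket) {
      if (ch == "]") in_bracket <- FALSE
      next
    }
    if (ch == "[") { in_bracket <- TRUE; next }
    if (percent_pending > 0L) {
      if (!grepl("[0-9]", ch)) return(FALSE)
      pct_key <- paste0(pct_key, ch)
      percent_pending <- percent_pending - 1L
      if (percent_pending == 0L) bump(paste0("%", pct_key))
      next
    }
    if (ch == "%") { percent_pending <- 2L; pct_key <- ""; next }
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (grepl("[0-9]", ch)) bump(ch)
  }
  if (in_bracket || depth != 0L || percent_pending > 0L) return(FALSE)
  all(ring_counts %% 2L == 0L)
}

#' Validity verdicts for generated SMILES candidates
#'
#' A candidate is valid iff the toolkit parses it *and* converts it to an
#' InChIKey; the key doubles as the molecule identity used for
#' uniqueness, novelty and training recall. Failures are classified:
#' `ring_branch_mismatch` for easy-detectable unbalanced ring-closure
#' digits or parentheses (these stay in the denominator -- classification
#' never rescues or removes a string), `parse_error` otherwise, and
#' `identity_failure` for the rare parseable molecule without an InChIKey.
#'
#' @param candidates character vector of desubstituted SMILES candidates.
#' @return data.frame with `smiles`, `is_valid`, `identity_key` (`NA` when
#'   invalid), `failure_class` in
#'   `none|ring_branch_mismatch|parse_error|identity_failure`.
#' @export
check_validity <- function(candidates) {
  n <- length(candidates)
  if (n == 0) {
    return(data.frame(smiles = character(), is_valid = logical(),
                      identity_key = character(),
                      failure_class = character(), stringsAsFactors = FALSE))
  }
  res <- rdkit_analyze(candidates)
  balanced <- vapply(candidates, ring_branch_balanced, TRUE, USE.NAMES = FALSE)
  is_valid <- res$ok & nzchar(res$inchikey)
  failure <- rep("none", n)
  failure[!res$ok & !balanced] <- "ring_branch_mismatch"
  failure[!res$ok & balanced] <- "parse_error"
  failure[res$ok & !nzchar(res$inchikey)] <- "identity_failure"
  data.frame(smiles = candidates,
             is_valid = is_valid,
             identity_key = ifelse(is_valid, res$inchikey, NA_character_),
             failure_class = failure,
             stringsAsFactors = FALSE)
}

#' Validity, uniqueness and training-recall percentages
#'
#' `validity%` = valid / generated; `uniqueness%` = unique identity keys /
#' valid; `training%` = unique keys also present in the training set /
#' unique keys (membership evaluated on the deduplicated molecule set).
#'
#' @param verdicts data.frame from [check_validity()].
#' @param training_keys character vector of training-set InChIKeys.
#' @return named numeric vector `c(validity =, uniqueness =, training =)`,
#'   percent scale.
#' @export
summary_rates <- function(verdicts, training_keys = character()) {
  n <- nrow(verdicts)
  if (n == 0) stop("empty generation batch")
  n_valid <- sum(verdicts$is_valid)
  keys <- unique(verdicts$identity_key[verdicts$is_valid])
  n_unique <- length(keys)
  c(validity = 100 * n_valid / n,
    uniqueness = if (n_valid > 0) 100 * n_unique / n_valid else NA_real_,
    training = if (n_unique > 0)
      100 * sum(keys %in% training_keys) / n_unique else NA_real_)
}

#' Compute the 12-property panel for a set of molecules
#'
#' Thin wrapper over [rdkit_properties()] returning only the panel columns
#' for valid molecules (SMILES length is measured on the canonical,
#' unsubstituted SMILES).
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame of 12 numeric columns (see [property_panel()]), one
#'   row per molecule.
#' @export
compute_properties <- function(smiles) {
  df <- rdkit_properties(smiles)
  if (any(!df$ok)) {
    stop("compute_properties called on invalid SMILES: ",
         paste(utils::head(smiles[!df$ok], 3), collapse = ", "))
  }
  df[, property_panel()]
}

# ---- histograms --------------------------------------------------------

# default bin width per property: unit bins for integer-valued properties,
# fixed widths for continuous ones
default_bin_width <- function(property_name) {
  switch(property_name,
    smiles_length = 1, hac = 1, rot_bonds = 1,
    mw = 10, logp = 0.25, tpsa = 5,
    frac_cyclic = 0.05, frac_conjugated = 0.05, frac_aromatic = 0.05,
    frac_c = 0.05, frac_n = 0.05, frac_o = 0.05,
    stop("unknown property: ", property_name))
}

#' Bin one molecular property into a named histogram
#'
#' @param values numeric vector of property values.
#' @param property_name one of [property_panel()] (sets the default bin
#'   width).
#' @param bin_edges explicit ordered break points; computed from the data
#'   range and default width when `NULL`.
#' @param normalized divide counts by their sum.
#' @return object of class `property_histogram`: `property_name`,
#'   `bin_edges`, `counts`, `normalized`.
#' @export
property_histogram <- function(values, property_name, bin_edges = NULL,
                               normalized = FALSE) {
  stopifnot(length(values) > 0)
  if (is.null(bin_edges)) {
    w <- default_bin_width(property_name)
    lo <- floor(min(values) / w) * w
    hi <- ceiling(max(values) / w) * w
    if (hi <= lo) hi <- lo + w
    bin_edges <- seq(lo, hi, by = w)
    if (max(values) >= bin_edges[length(bin_edges)]) {
      bin_edges <- c(bin_edges, bin_edges[length(bin_edges)] + w)
    }
  }
  counts <- as.numeric(table(cut(values, breaks = bin_edges, right = FALSE,
                                 include.lowest = FALSE)))
  if (normalized) {
    s <- sum(counts)
    if (s == 0) stop("cannot normalize an all-zero histogram")
    counts <- counts / s
  }
  structure(list(property_name = property_name, bin_edges = bin_edges,
                 counts = counts, normalized = normalized),
            class = "property_histogram")
}

#' Histograms of the same property over two sets on shared bin edges
#'
#' Both inputs are binned over the union of their ranges so the resulting
#' histograms are directly comparable by [tanimoto_match()] / [jsd()].
#'
#' @param values_a,values_b numeric vectors.
#' @param property_name panel property name.
#' @param normalized normalize both histograms.
#' @return list of two `property_histogram`s (`a`, `b`).
#' @export
shared_histograms <- function(values_a, values_b, property_name,
                              normalized = FALSE) {
  w <- default_bin_width(property_name)
  lo <- floor(min(values_a, values_b) / w) * w
  hi <- ceiling(max(values_a, values_b) / w) * w + w
  edges <- seq(lo, hi, by = w)
  list(a = property_histogram(values_a, property_name, edges, normalized),
       b = property_histogram(values_b, property_name, edges, normalized))
}

check_comparable <- function(A, B) {
  stopifnot(inherits(A, "property_histogram"),
            inherits(B, "property_histogram"))
  if (length(A$bin_edges) != length(B$bin_edges) ||
      any(A$bin_edges != B$bin_edges)) {
    stop("histograms must share identical bin edges")
  }
}

#' Continuous Tanimoto match between two histograms
#'
#' `T(A, B) = sum(A B) / (sum(A^2) + sum(B^2) - sum(A B)) x 100` over
#' shared bins. Scale-invariant under joint rescaling; computed on raw or
#' normalized counts alike.
#'
#' @param A,B `property_histogram`s on identical bin edges.
#' @return percentage in `[0, 100]` (negative values impossible for
#'   non-negative counts).
#' @export
tanimoto_match <- function(A, B) {
  check_comparable(A, B)
  a <- A$counts; b <- B$counts
  if (all(a == 0) && all(b == 0)) stop("both histograms are all-zero")
  ab <- sum(a * b)
  100 * ab / (sum(a^2) + sum(b^2) - ab)
}

shannon_entropy <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Jensen-Shannon divergence between two normalized histograms
#'
#' `JSD = H(w_a A + w_b B) - (w_a H(A) + w_b H(B))` with Shannon entropy H
#' over bins and `0 log 0 = 0`. Defaults to equal weights and log base 2,
#' bounding the divergence by 1 bit (attained for disjoint supports).
#' Inputs must already be normalized -- unnormalized histograms are an
#' error, never silently rescaled.
#'
#' @param A,B normalized `property_histogram`s on identical bin edges.
#' @param weights two mixture weights summing to 1.
#' @param base logarithm base (2 = bits, default).
#' @return non-negative divergence.
#' @export
jsd <- function(A, B, weights = c(0.5, 0.5), base = 2) {
  check_comparable(A, B)
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-9)
  for (H in list(A, B)) {
    if (abs(sum(H$counts) - 1) > 1e-6) {
      stop("jsd requires normalized histograms (counts summing to 1)")
    }
  }
  mix <- weights[1] * A$counts + weights[2] * B$counts
  shannon_entropy(mix, base) -
    (weights[1] * shannon_entropy(A$counts, base) +
     weights[2] * shannon_entropy(B$counts, base))
}

#' Distribution match report between a training and a generated set
#'
#' For each of the 12 panel properties, bins both sets on shared edges and
#' reports the continuous Tanimoto match (raw counts) and the
#' Jensen-Shannon divergence (normalized, equal weights, bits).
#'
#' @param train_props,gen_props data.frames from [compute_properties()].
#' @return data.frame with columns `property`, `tanimoto`, `jsd`.
#' @export
property_match <- function(train_props, gen_props) {
  rows <- lapply(property_panel(), function(pn) {
    hr <- shared_histograms(train_props[[pn]], gen_props[[pn]], pn)
    hn <- shared_histograms(train_props[[pn]], gen_props[[pn]], pn,
                            normalized = TRUE)
    data.frame(property = pn,
               tanimoto = tanimoto_match(hr$b, hr$a),
               jsd = jsd(hn$b, hn$a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- novelty -----------------------------------------------------------

#' Chunked novelty and efficiency analysis
#'
#' The generation stream is split into consecutive chunks (default
#' 10,000 strings). Within chunk t, a valid molecule is novel when its
#' identity key was never seen in chunks 1..t, including earlier in the
#' same chunk; `novelty%` is novel / valid per chunk (`NA` when a chunk
#' has no valid molecule). `cumulative_unique` accumulates distinct keys;
#' `efficiency` is valid unique molecules over total generated strings.
#'
#' @param verdicts data.frame from [check_validity()], in generation
#'   order.
#' @param chunk_size strings per chunk (default 10000).
#' @return object of class `novelty_series`: data.frame `series` (chunk,
#'   n_generated, n_valid, n_novel, novelty, cumulative_unique) plus
#'   `efficiency` and `chunk_size`.
#' @export
novelty_analysis <- function(verdicts, chunk_size = 10000L) {
  stopifnot(chunk_size >= 1)
  n <- nrow(verdicts)
  chunk <- ceiling(seq_len(n) / chunk_size)
  valid <- verdicts$is_valid
  novel <- logical(n)
  novel[valid] <- !duplicated(verdicts$identity_key[valid])
  series <- data.frame(chunk = sort(unique(chunk)))
  series$n_generated <- as.vector(table(chunk))
  series$n_valid <- as.vector(tapply(valid, chunk, sum))
  series$n_novel <- as.vector(tapply(novel, chunk, sum))
  series$novelty <- ifelse(series$n_valid > 0,
                           100 * series$n_novel / series$n_valid, NA_real_)
  series$cumulative_unique <- cumsum(series$n_novel)
  structure(list(series = series,
                 efficiency = 100 * sum(novel) / n,
                 chunk_size = as.integer(chunk_size)),
            class = "novelty_series")
}

#' @export
print.novelty_series <- function(x, ...) {
  cat("<novelty_series>", nrow(x$series), "chunks of", x$chunk_size,
      sprintf("; efficiency %.1f%%\n", x$efficiency))
  invisible(x)
}

#' Novelty analysis stratified by heavy atom count
#'
#' Chunks are defined on the global stream position; novelty is then
#' aggregated per (chunk, HAC) cell. Cells with no valid molecule are
#' reported as `NA`, not zero.
#'
#' @param verdicts data.frame from [check_validity()], in generation
#'   order.
#' @param hac integer vector of heavy atom counts aligned with `verdicts`
#'   (values for invalid rows are ignored).
#' @param chunk_size strings per chunk.
#' @return long data.frame: `hac`, `chunk`, `n_valid`, `n_novel`,
#'   `novelty`.
#' @export
novelty_by_hac <- function(verdicts, hac, chunk_size = 10000L) {
  stopifnot(length(hac) == nrow(verdicts), chunk_size >= 1)
  n <- nrow(verdicts)
  chunk <- ceiling(seq_len(n) / chunk_size)
  valid <- verdicts$is_valid
  novel <- logical(n)
  novel[valid] <- !duplicated(verdicts$identity_key[valid])
  cells <- expand.grid(hac = sort(unique(hac[valid])),
                       chunk = sort(unique(chunk)))
  cells$n_valid <- mapply(function(h, t) sum(valid & hac == h & chunk == t),
                          cells$hac, cells$chunk)
  cells$n_novel <- mapply(function(h, t) sum(novel & hac == h & chunk == t),
                          cells$hac, cells$chunk)
  cells$novelty <- ifelse(cells$n_valid > 0,
                          100 * cells$n_novel / cells$n_valid, NA_real_)
  cells
}
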