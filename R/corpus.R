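# Corpus preparation: organic filtering, stereochemistry removal, the
# single-character token substitution, deduplication and randomized-SMILES
# augmentation.

# Ordered longest-token-first so multi-character tokens are consumed before
# any single character could match inside them.
SUBSTITUTIONS <- c("[nH]" = "A", "Cl" = "L", "Br" = "R")

#' Replace multi-character SMILES tokens by single characters
#'
#' `Cl` -> `L`, `Br` -> `R`, `[nH]` -> `A`, longest token first. The
#' substituted alphabet is what the character-level network sees, so every
#' chemical token occupies exactly one position in the sequence.
#'
#' @param smiles character vector (stereochemistry already removed).
#' @return character vector of substituted strings.
#' @seealso [desubstitute_tokens()] for the exact inverse.
#' @export
substitute_tokens <- function(smiles) {
  bad <- grepl("[LRA]", smiles)
  if (any(bad)) {
    stop("input already contains reserved characters L, R or A: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "))
  }
  for (tok in names(SUBSTITUTIONS)) {
    smiles <- gsub(tok, SUBSTITUTIONS[[tok]], smiles, fixed = TRUE)
  }
  smiles
}

#' Invert the single-character token substitution
#'
#' `L` -> `Cl`, `R` -> `Br`, `A` -> `[nH]`; exact inverse of
#' [substitute_tokens()] on its image. Applied to every generated string
#' before validity checking.
#'
#' @param encoded character vector of substituted strings.
#' @return character vector of standard SMILES.
#' @export
desubstitute_tokens <- function(encoded) {
  for (tok in names(SUBSTITUTIONS)) {
    encoded <- gsub(SUBSTITUTIONS[[tok]], tok, encoded, fixed = TRUE)
  }
  encoded
}

# Tetrahedral tokens, longest first so "[C@@H]" is never seen as "[C@@]"+"H".
STEREO_TOKENS <- c("[C@@H]", "[C@H]", "[C@@]", "[C@]")

#' Remove stereochemistry from SMILES
#'
#' Replaces the tetrahedral tokens `[C@@H]`, `[C@H]`, `[C@@]`, `[C@]` by
#' plain `C` and deletes the double-bond markers `/` and `\`; the result is
#' re-canonicalized through RDKit (disable with `recanonicalize = FALSE`
#' for pure string surgery).
#'
#' @param smiles character vector of valid SMILES.
#' @param recanonicalize logical; re-derive the canonical form of the
#'   stripped string (default `TRUE`).
#' @return character vector of stereo-free SMILES.
#' @export
strip_stereo <- function(smiles, recanonicalize = TRUE) {
  out <- smiles
  for (tok in STEREO_TOKENS) out <- gsub(tok, "C", out, fixed = TRUE)
  out <- gsub("[/\\\\]", "", out)
  if (recanonicalize) {
    res <- rdkit_analyze(out)
    if (any(!res$ok)) {
      stop("stereo stripping produced unparseable SMILES: ",
           paste(utils::head(out[!res$ok], 3), collapse = ", "))
    }
    out <- res$canonical
  }
  out
}

#' Organic-subset filter
#'
#' A molecule is retained when it contains at least one carbon atom and
#' every atom's element lies in H, B, C, N, O, F, S, Cl, Br, I.
#'
#' @param smiles character vector of parseable SMILES.
#' @return logical vector.
#' @export
filter_organic <- function(smiles) {
  res <- rdkit_analyze(smiles)
  if (any(!res$ok)) {
    stop("unparseable SMILES passed to filter_organic: ",
         paste(utils::head(smiles[!res$ok], 3), collapse = ", "))
  }
  res$organic
}

#' Prepare a raw SMILES list for training
#'
#' Pipeline: split multi-fragment lines on `.`; drop unparseable fragments
#' (counted, not fatal); keep organic fragments only; strip
#' stereochemistry; canonicalize; de-duplicate by canonical SMILES keeping
#' first-occurrence order.
#'
#' @param raw_smiles character vector, one SMILES per element.
#' @return data.frame with columns `source_smiles`, `canonical_smiles`,
#'   `identity_key` (InChIKey); attribute `report` holds the counts
#'   (`input_lines`, `fragments`, `skipped_parse`, `skipped_nonorganic`,
#'   `duplicates`, `kept`).
#' @export
prepare_corpus <- function(raw_smiles) {
  raw_smiles <- raw_smiles[nzchar(trimws(raw_smiles))]
  frags_by_line <- strsplit(trimws(raw_smiles), ".", fixed = TRUE)
  frags <- unlist(frags_by_line, use.names = FALSE)
  src <- rep(raw_smiles, lengths(frags_by_line))
  keep <- nzchar(frags)
  frags <- frags[keep]; src <- src[keep]

  first <- rdkit_analyze(frags)
  n_parse_fail <- sum(!first$ok)
  n_nonorganic <- sum(first$ok & !first$organic)
  sel <- first$ok & first$organic

  frags <- frags[sel]; src <- src[sel]
  stripped <- strip_stereo(frags, recanonicalize = FALSE)
  final <- rdkit_analyze(stripped)
  # stripping a valid fragment must stay parseable; anything else is a bug
  stopifnot(all(final$ok))

  dup <- duplicated(final$canonical)
  out <- data.frame(
    source_smiles = src[!dup],
    canonical_smiles = final$canonical[!dup],
    identity_key = final$inchikey[!dup],
    stringsAsFactors = FALSE)
  attr(out, "report") <- list(
    input_lines = length(raw_smiles),
    fragments = sum(keep),
    skipped_parse = n_parse_fail,
    skipped_nonorganic = n_nonorganic,
    duplicates = sum(dup),
    kept = nrow(out))
  out
}

#' Offline randomized-SMILES augmentation
#'
#' For every molecule, `factor` random-atom-order SMILES are attempted;
#' results are de-duplicated globally (across attempts and molecules), so
#' the realized augmentation factor is usually below `factor` -- symmetric
#' molecules admit fewer distinct writings.
#'
#' @param molecules data.frame as returned by [prepare_corpus()] (only
#'   `canonical_smiles` is used).
#' @param factor attempts per molecule (>= 1). `canonical_only = TRUE`
#'   ignores `factor` and returns the canonical strings themselves.
#' @param seed integer seed for the randomized atom orders.
#' @param canonical_only logical; identity augmentation.
#' @return character vector of unique SMILES; attribute
#'   `effective_factor` = length(output) / nrow(molecules).
#' @export
augment_randomized <- function(molecules, factor, seed = 42L,
                               canonical_only = FALSE) {
  stopifnot(is.data.frame(molecules), nrow(molecules) > 0, factor >= 1)
  if (canonical_only) {
    out <- unique(molecules$canonical_smiles)
  } else {
    variants <- rdkit_random_smiles(molecules$canonical_smiles,
                                    n_attempts = factor, seed = seed)
    out <- unique(unlist(variants, use.names = FALSE))
  }
  attr(out, "effective_factor") <- length(out) / nrow(molecules)
  out
}
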