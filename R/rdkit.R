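# Bridge to the bundled RDKit helper (inst/python/rdkit_worker.py).
#
# All cheminformatics primitives -- SMILES parsing, canonicalization,
# InChIKey identity, randomized SMILES and the descriptor panel -- are
# delegated to RDKit through a batch subprocess: one `python` invocation
# per *vector* of SMILES, never per molecule. Callers must therefore batch.

.gensmiles_env <- new.env(parent = emptyenv())

rdkit_script <- function() {
  path <- system.file("python", "rdkit_worker.py", package = "gensmiles")
  if (!nzchar(path)) stop("bundled rdkit_worker.py not found; is gensmiles installed?")
  path
}

#' Is the RDKit Python helper available?
#'
#' Checks (once per session) that `python` is on the PATH and can import
#' RDKit. All parsing, identity and descriptor computations require it.
#'
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function() {
  if (!is.null(.gensmiles_env$rdkit_ok)) return(.gensmiles_env$rdkit_ok)
  ok <- nzchar(Sys.which("python")) &&
    identical(
      suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                               stdout = FALSE, stderr = FALSE)), 0L)
  .gensmiles_env$rdkit_ok <- ok
  ok
}

rdkit_run <- function(op, smiles, args = character()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character())
  if (any(grepl("[\t\n]", smiles))) stop("SMILES input must not contain tabs or newlines")
  out <- suppressWarnings(system2(
    "python", c(shQuote(rdkit_script()), op, args),
    input = smiles, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("rdkit helper failed (op=", op, ", status=", status, ")")
  }
  out
}

#' Parse, canonicalize and fingerprint a batch of SMILES
#'
#' One RDKit pass over a character vector: parseability, the organic-subset
#' test (at least one carbon; elements within H, B, C, N, O, F, S, Cl, Br,
#' I), canonical SMILES, InChIKey and heavy atom count.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `ok`, `organic`, `canonical`,
#'   `inchikey`, `hac`. `ok` is parse success; failed rows carry empty
#'   strings and `hac = 0`.
#' @export
rdkit_analyze <- function(smiles) {
  if (length(smiles) == 0) {
    return(data.frame(smiles = character(), ok = logical(), organic = logical(),
                      canonical = character(), inchikey = character(),
                      hac = integer(), stringsAsFactors = FALSE))
  }
  out <- rdkit_run("analyze", smiles)
  stopifnot(length(out) == length(smiles))
  parts <- strsplit(out, "\t", fixed = TRUE)
  get <- function(i, def = "") vapply(parts, function(p) if (length(p) >= i) p[i] else def, "")
  data.frame(
    smiles = smiles,
    ok = get(1) == "1",
    organic = get(2) == "1",
    canonical = get(3),
    inchikey = get(4),
    hac = as.integer(get(5, "0")),
    stringsAsFactors = FALSE)
}

#' Randomized SMILES for a batch of molecules
#'
#' Unrestricted atom-order randomization via RDKit, seeded for
#' reproducibility (each molecule gets a seed derived from `seed` and its
#' position).
#'
#' @param smiles character vector of parseable SMILES.
#' @param n_attempts randomized strings requested per molecule.
#' @param seed integer seed.
#' @return list of character vectors (possibly containing duplicates;
#'   empty for unparseable inputs), one per input.
#' @export
rdkit_random_smiles <- function(smiles, n_attempts, seed = 42L) {
  if (length(smiles) == 0) return(list())
  out <- rdkit_run("random", smiles,
                   args = c(as.character(as.integer(n_attempts)),
                            as.character(as.integer(seed))))
  stopifnot(length(out) == length(smiles))
  lapply(strsplit(out, "\t", fixed = TRUE),
         function(p) p[nzchar(p)])
}

#' The 12-property descriptor panel
#'
#' Size (canonical SMILES length, heavy atom count, molecular weight),
#' polarity (Crippen logP, TPSA), topology (rotatable bonds, fractions of
#' cyclic / conjugated / aromatic heavy atoms) and elemental composition
#' (fractions of C, N, O among heavy atoms).
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with `smiles`, `ok` and the 12 numeric property
#'   columns; unparseable rows have `ok = FALSE` and `NaN` values.
#' @export
rdkit_properties <- function(smiles) {
  if (length(smiles) == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric()), 12), property_panel()))
    return(cbind(data.frame(smiles = character(), ok = logical(),
                            stringsAsFactors = FALSE), df))
  }
  out <- rdkit_run("props", smiles)
  con <- textConnection(out)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  stopifnot(nrow(df) == length(smiles))
  df$ok <- df$ok == 1
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE), df)
}

#' Names of the 12-property panel
#' @return character vector of property column names in canonical order.
#' @export
property_panel <- function() {
  c("smiles_length", "hac", "mw", "logp", "tpsa", "rot_bonds",
    "frac_cyclic", "frac_conjugated", "frac_aromatic",
    "frac_c", "frac_n", "frac_o")
}
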