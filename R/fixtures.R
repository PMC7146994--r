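# Synthetic corpus generation: random fragment-sized organic molecules,
# valid by construction, so every other module is testable without any
# external dataset. Molecules are trees of structural units (chain atoms,
# benzene / pyrrole aromatic rings, cycloalkanes) grown under standard
# valences and written out with globally unique ring-closure digits.

ATOM_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L, S = 2L, Cl = 1L, Br = 1L)

#' Specification for a synthetic fixture corpus
#'
#' Emulates the fragment-sized organic regime of public compound
#' libraries: heavy atom counts in a bounded range, a carbon-dominated
#' element palette, and tunable ring / branch / aromatic content.
#'
#' @param n_molecules number of molecules to generate.
#' @param hac_range integer pair, inclusive heavy-atom-count bounds
#'   (within `[1, 60]`).
#' @param element_weights named weights over `C,N,O,F,S,Cl,Br` for chain
#'   atoms (normalized internally).
#' @param ring_probability chance a growth step opens a cycloalkane ring.
#' @param branch_probability chance each optional attachment point grows a
#'   branch.
#' @param aromatic_probability chance a growth step inserts an aromatic
#'   ring (benzene, occasionally pyrrole).
#' @param seed integer seed; corpora are deterministic given the spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 1000L,
                         hac_range = c(5L, 40L),
                         element_weights = c(C = 0.70, N = 0.10, O = 0.12,
                                             F = 0.03, S = 0.03,
                                             Cl = 0.01, Br = 0.01),
                         ring_probability = 0.20,
                         branch_probability = 0.25,
                         aromatic_probability = 0.30,
                         seed = 42L) {
  stopifnot(n_molecules >= 1,
            length(hac_range) == 2, hac_range[1] >= 1, hac_range[2] <= 60,
            hac_range[1] <= hac_range[2],
            all(names(element_weights) %in% names(ATOM_VALENCE)),
            ring_probability >= 0, ring_probability <= 1,
            branch_probability >= 0, branch_probability <= 1,
            aromatic_probability >= 0, aromatic_probability <= 1)
  if (aromatic_probability > 0 && hac_range[2] < 5) {
    stop("aromatic rings need at least 5 heavy atoms; raise hac_range")
  }
  if (ring_probability > 0 && hac_range[2] < 5) {
    stop("rings need at least 5 heavy atoms; raise hac_range")
  }
  element_weights <- element_weights / sum(element_weights)
  structure(list(n_molecules = as.integer(n_molecules),
                 hac_range = as.integer(hac_range),
                 element_weights = element_weights,
                 ring_probability = ring_probability,
                 branch_probability = branch_probability,
                 aromatic_probability = aromatic_probability,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# ring digit allocator: globally unique per molecule, %nn beyond 9
next_ring_digit <- function(env) {
  d <- env$ring_counter
  env$ring_counter <- d + 1L
  if (d <= 9L) as.character(d) else paste0("%", d)
}

# grow one unit and its subtree; returns its SMILES, spending env$remaining
grow_unit <- function(spec, env, force_atom = FALSE, has_parent = TRUE) {
  rem <- env$remaining
  u <- stats::runif(1)
  kind <- "atom"
  if (!force_atom) {
    if (u < spec$aromatic_probability && rem >= 6L) {
      kind <- if (stats::runif(1) < 0.2 && rem >= 5L) "pyrrole" else "benzene"
      if (kind == "benzene" && rem < 6L) kind <- "atom"
    } else if (u < spec$aromatic_probability + spec$ring_probability &&
               rem >= 6L) {
      kind <- "cycloalkane"
    }
  }
  if (kind == "atom") {
    el <- sample(names(spec$element_weights), 1,
                 prob = spec$element_weights)
    env$remaining <- env$remaining - 1L
    n_slots <- ATOM_VALENCE[[el]] - as.integer(has_parent)
    children <- grow_children(spec, env, n_slots)
    return(paste0(el, format_branches(children)))
  }
  if (kind == "benzene") {
    atoms <- rep("c", 6L)
    env$remaining <- env$remaining - 6L
  } else if (kind == "pyrrole") {
    atoms <- c("c", "c", "[nH]", "c", "c")
    env$remaining <- env$remaining - 5L
  } else {
    m <- if (rem >= 6L && stats::runif(1) < 0.5) 6L else 5L
    atoms <- rep("C", m)
    env$remaining <- env$remaining - m
  }
  d <- next_ring_digit(env)
  m <- length(atoms)
  # one optional substituent per ring atom (never on the pyrrole [nH])
  parts <- character(m)
  for (i in seq_len(m)) {
    kid <- ""
    # the first ring atom carries the bond to the parent unit: no slot left
    slot_free <- atoms[i] != "[nH]" && !(i == 1L && has_parent)
    if (slot_free && env$remaining > 0L &&
        stats::runif(1) < spec$branch_probability) {
      kid <- grow_unit(spec, env)
    }
    parts[i] <- if (i == 1L) {
      paste0(atoms[i], d, if (nzchar(kid)) paste0("(", kid, ")") else "")
    } else if (i == m) {
      # closure digit first, substituent continues the chain after the ring
      paste0(atoms[i], d, kid)
    } else {
      paste0(atoms[i], if (nzchar(kid)) paste0("(", kid, ")") else "")
    }
  }
  paste0(parts, collapse = "")
}

# children of a chain atom: the first slot keeps growing while budget
# remains; the rest branch stochastically
grow_children <- function(spec, env, n_slots) {
  kids <- character(0)
  for (s in seq_len(n_slots)) {
    if (env$remaining <= 0L) break
    go <- if (s == 1L) TRUE else stats::runif(1) < spec$branch_probability
    if (go) kids <- c(kids, grow_unit(spec, env))
  }
  kids
}

format_branches <- function(kids) {
  n <- length(kids)
  if (n == 0) return("")
  if (n == 1) return(kids)  # paste0(collapse=) treats length-0 as "", avoid
  paste0(paste0("(", kids[-n], ")", collapse = ""), kids[n])
}

generate_one <- function(spec) {
  target <- sample(spec$hac_range[1]:spec$hac_range[2], 1)
  env <- new.env(parent = emptyenv())
  env$remaining <- target
  env$ring_counter <- 1L
  smi <- grow_unit(spec, env, has_parent = FALSE)
  list(smiles = smi, hac = target - env$remaining)
}

#' Generate a valid-by-construction SMILES corpus
#'
#' Grows random molecular trees under standard valences (see
#' [fixture_spec()]); every output is asserted to parse in the
#' cheminformatics toolkit. Deterministic given the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @param assert_parse verify every string with RDKit (default `TRUE`).
#' @return character vector of `n_molecules` SMILES.
#' @export
generate_fixture_corpus <- function(spec, assert_parse = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  out <- character(spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    for (try in 1:100) {
      g <- generate_one(spec)
      if (g$hac >= spec$hac_range[1] && g$hac <= spec$hac_range[2]) break
      g <- NULL
    }
    if (is.null(g)) stop("could not satisfy hac_range; spec too constrained")
    out[i] <- g$smiles
  }
  if (assert_parse) {
    res <- rdkit_analyze(out)
    if (any(!res$ok)) {
      stop("internal error: fixture generator emitted unparseable SMILES: ",
           paste(utils::head(out[!res$ok], 3), collapse = " "))
    }
  }
  out
}

#' Corrupt a valid SMILES into a guaranteed-invalid string
#'
#' Negative fixtures for the validity checker. `drop_ring_digit` removes
#' one occurrence of a ring-closure digit, `unbalance_paren` removes one
#' parenthesis -- both leave an unmatched partner, so the result cannot
#' parse. `illegal_char` inserts `!`, which no SMILES dialect accepts.
#'
#' @param smiles a valid SMILES string.
#' @param mode one of `"drop_ring_digit"`, `"unbalance_paren"`,
#'   `"illegal_char"`.
#' @param seed integer seed choosing the corruption site.
#' @return the corrupted string.
#' @export
mutate_to_invalid <- function(smiles,
                              mode = c("drop_ring_digit", "unbalance_paren",
                                       "illegal_char"),
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  chars <- strsplit(smiles, "")[[1]]
  # positions outside square brackets
  in_br <- cumsum(chars == "[") - cumsum(c(FALSE, utils::head(chars == "]", -1))) > 0
  if (mode == "drop_ring_digit") {
    cand <- which(grepl("[0-9]", chars) & !in_br &
                    c("", utils::head(chars, -1)) != "%")
    if (length(cand) == 0) stop("inapplicable: no ring-closure digit present")
    drop <- if (length(cand) == 1) cand else sample(cand, 1)
    return(paste(chars[-drop], collapse = ""))
  }
  if (mode == "unbalance_paren") {
    cand <- which(chars %in% c("(", ")"))
    if (length(cand) == 0) stop("inapplicable: no parenthesis present")
    drop <- if (length(cand) == 1) cand else sample(cand, 1)
    return(paste(chars[-drop], collapse = ""))
  }
  pos <- sample(seq_len(length(chars) + 1L), 1)
  paste(append(chars, "!", after = pos - 1L), collapse = "")
}

#' Scripted mock generator with an exact validity schedule
#'
#' A stand-in for a trained model whose examination-time validity is fully
#' controlled: at its e-th call it emits a sample in which exactly
#' `round(validity_schedule[e] * n)` strings are valid fixtures and the
#' rest are guaranteed-invalid mutants. Calling past the end of the
#' schedule is an error.
#'
#' @param validity_schedule numeric vector of per-epoch valid fractions in
#'   `[0, 1]`.
#' @param pool optional character vector of valid SMILES to draw from
#'   (defaults to a small internally generated fixture set).
#' @return object of class `gen_mock_generator`, usable wherever
#'   [sample_strings()] accepts a generator.
#' @export
scripted_mock_generator <- function(validity_schedule, pool = NULL) {
  stopifnot(all(validity_schedule >= 0), all(validity_schedule <= 1))
  if (is.null(pool)) {
    pool <- generate_fixture_corpus(
      fixture_spec(n_molecules = 200L, seed = 7L), assert_parse = FALSE)
  }
  invalid_pool <- vapply(seq_along(pool), function(i) {
    mutate_to_invalid(pool[i], "illegal_char", seed = i)
  }, "")
  state <- new.env(parent = emptyenv())
  state$epoch <- 0L
  structure(list(schedule = validity_schedule, pool = pool,
                 invalid_pool = invalid_pool, state = state),
            class = "gen_mock_generator")
}

#' @export
sample_strings.gen_mock_generator <- function(generator, vocab, n, seed, ...) {
  st <- generator$state
  st$epoch <- st$epoch + 1L
  if (st$epoch > length(generator$schedule)) {
    stop("scripted validity schedule exhausted at call ", st$epoch)
  }
  frac <- generator$schedule[st$epoch]
  n_valid <- round(frac * n)
  set.seed(seed)
  valid <- sample(generator$pool, n_valid, replace = TRUE)
  invalid <- sample(generator$invalid_pool, n - n_valid, replace = TRUE)
  sample(c(valid, invalid))
}
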