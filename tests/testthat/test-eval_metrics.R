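# Evaluation metrics: verdicts, rates, the property panel, histogram
# matching and novelty.

test_that("check_validity verdicts and failure classes", {
  v <- check_validity(c("CCO", "C1CC", "C(C", "c1ccccc1", "CC!O", ""))
  expect_equal(v$is_valid, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(v$failure_class[2], "ring_branch_mismatch")
  expect_equal(v$failure_class[3], "ring_branch_mismatch")
  expect_equal(v$failure_class[5], "parse_error")
  # identity key present iff valid
  expect_equal(!is.na(v$identity_key), v$is_valid)
})

test_that("ring/branch scanner ignores digits inside brackets and handles %nn", {
  scan <- gensmiles:::ring_branch_balanced
  expect_true(scan("C1CCC1"))
  expect_false(scan("C1CCC"))
  expect_true(scan("[13CH4]"))          # isotope digit is not a ring bond
  expect_true(scan("C%10CCCC%10"))
  expect_false(scan("C%10CCCC"))
  expect_true(scan("C1CC1C2CC2"))       # digit reuse after closure
  expect_false(scan(")CC("))            # depth goes negative
})

test_that("summary_rates implements the three ratios", {
  v <- check_validity(c("CCO", "CCN", "C1CC"))
  r <- summary_rates(v, training_keys = character())
  expect_equal(unname(r["validity"]), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(unname(r["uniqueness"]), 100)
  expect_equal(unname(r["training"]), 0)

  v10 <- check_validity(rep("CCO", 10))
  r10 <- summary_rates(v10, character())
  expect_equal(unname(r10["validity"]), 100)
  expect_equal(unname(r10["uniqueness"]), 10)

  keys <- unique(v$identity_key[v$is_valid])
  rall <- summary_rates(v, keys)
  expect_equal(unname(rall["training"]), 100)
  expect_error(summary_rates(v[0, ], character()), "empty")
})

test_that("the property panel computes documented values", {
  p <- compute_properties(c("CCO", "c1ccccc1"))
  expect_equal(names(p), property_panel())
  expect_equal(p$hac, c(3, 6))
  expect_equal(p$smiles_length, c(3, 8))
  expect_equal(p$frac_c[1], 2 / 3)
  expect_equal(p$frac_o[1], 1 / 3)
  expect_equal(p$frac_aromatic, c(0, 1))
  expect_equal(p$frac_cyclic, c(0, 1))
  expect_equal(p$mw[1], 46.07, tolerance = 1e-3)
  expect_error(compute_properties("C1CC"), "invalid")
})

test_that("tanimoto match identities", {
  A <- property_histogram(c(1, 1, 2, 3, 3, 3), "hac")
  expect_equal(tanimoto_match(A, A), 100)
  B <- A; B$counts <- 2 * A$counts
  expect_equal(tanimoto_match(A, B), 100 * 2 / 3, tolerance = 1e-12)
  # joint rescaling leaves the match unchanged
  A2 <- A; A2$counts <- A$counts * 7.3
  B2 <- B; B2$counts <- B$counts * 7.3
  expect_equal(tanimoto_match(A2, B2), tanimoto_match(A, B))
  # disjoint supports
  P <- property_histogram(c(0.5, 1.5), "hac", 0:4)
  Q <- property_histogram(c(2.5, 3.5), "hac", 0:4)
  expect_equal(tanimoto_match(P, Q), 0)
  Z <- A; Z$counts <- A$counts * 0
  expect_error(tanimoto_match(Z, Z), "all-zero")
  D <- property_histogram(1:10, "hac")
  expect_error(tanimoto_match(A, D), "bin edges")
})

test_that("jsd identities, bound and symmetry", {
  A <- property_histogram(c(1, 1, 2, 3), "hac", normalized = TRUE)
  expect_equal(jsd(A, A), 0, tolerance = 1e-12)

  # disjoint equal-weight distributions: exactly 1 bit
  edges <- 0:4
  P <- property_histogram(c(0.5, 0.5), "hac", edges, normalized = TRUE)
  Q <- property_histogram(c(2.5, 3.5), "hac", edges, normalized = TRUE)
  expect_equal(jsd(P, Q), 1, tolerance = 1e-12)
  expect_lte(jsd(P, Q, base = exp(1)), log(2) + 1e-12)

  raw <- property_histogram(c(1, 1, 2), "hac")
  expect_error(jsd(raw, raw), "normalized")

  set.seed(19)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    e <- 0:n
    x <- property_histogram(runif(30, 0, n), "hac", e, normalized = TRUE)
    y <- property_histogram(runif(30, 0, n), "hac", e, normalized = TRUE)
    expect_equal(jsd(x, y), jsd(y, x), tolerance = 1e-12)
    expect_gte(jsd(x, y), 0)
    expect_lte(jsd(x, y), 1 + 1e-12)
  }
})

test_that("property_match emits one row per panel property", {
  smi <- fixture_corpus()
  ok <- fixture_analysis()$ok
  props <- compute_properties(smi[ok])
  half <- nrow(props) %/% 2
  pm <- property_match(props[1:half, ], props[(half + 1):nrow(props), ])
  expect_equal(pm$property, property_panel())
  expect_true(all(pm$tanimoto >= 0 & pm$tanimoto <= 100))
  expect_true(all(pm$jsd >= 0 & pm$jsd <= 1))
})

test_that("novelty analysis equals a brute-force set-based replay", {
  # constructed stream: valid molecules with a known duplicate schedule
  smi <- fixture_corpus()
  keys <- fixture_analysis()$inchikey
  ok <- fixture_analysis()$ok & !duplicated(keys)
  pool_smi <- smi[ok][1:100]
  pool_key <- keys[ok][1:100]
  set.seed(5)
  n <- 3000
  pick <- sample(100, n, replace = TRUE, prob = 1 / (1:100))
  stream_smi <- pool_smi[pick]
  invalid_at <- sample(n, 300)
  stream_smi[invalid_at] <- "C1CC("
  verdicts <- data.frame(
    smiles = stream_smi,
    is_valid = !(seq_len(n) %in% invalid_at),
    identity_key = ifelse(seq_len(n) %in% invalid_at, NA, pool_key[pick]),
    failure_class = "none", stringsAsFactors = FALSE)

  res <- novelty_analysis(verdicts, chunk_size = 500)

  # oracle: replay with an explicit set
  seen <- character(0)
  for (t in 1:6) {
    rows <- ((t - 1) * 500 + 1):(t * 500)
    vv <- verdicts[rows, ]
    novel <- 0L; valid <- 0L
    for (i in seq_len(nrow(vv))) {
      if (!vv$is_valid[i]) next
      valid <- valid + 1L
      if (!(vv$identity_key[i] %in% seen)) {
        novel <- novel + 1L
        seen <- c(seen, vv$identity_key[i])
      }
    }
    expect_equal(res$series$n_valid[t], valid)
    expect_equal(res$series$n_novel[t], novel)
    expect_equal(res$series$novelty[t], 100 * novel / valid)
    expect_equal(res$series$cumulative_unique[t], length(seen))
  }
  expect_equal(res$efficiency, 100 * length(seen) / n)
  # conservation: cumulative uniques = cardinality of the key set
  expect_equal(res$series$cumulative_unique[6],
               length(unique(na.omit(verdicts$identity_key))))
  expect_true(all(diff(res$series$cumulative_unique) >= 0))
})

test_that("novelty with no duplicates or invalids is 100% everywhere", {
  smi <- fixture_corpus()
  keys <- fixture_analysis()$inchikey
  ok <- fixture_analysis()$ok & !duplicated(keys)
  v <- data.frame(smiles = smi[ok], is_valid = TRUE,
                  identity_key = keys[ok], failure_class = "none",
                  stringsAsFactors = FALSE)
  res <- novelty_analysis(v, chunk_size = 50)
  expect_true(all(res$series$novelty == 100))
  expect_equal(res$efficiency, 100)
})

test_that("novelty_by_hac stratifies and guards empty cells", {
  v <- data.frame(
    smiles = c("CCO", "CCO", "CCN", "c1ccccc1", "bad"),
    is_valid = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    identity_key = c("K1", "K1", "K2", "K3", NA),
    failure_class = "none", stringsAsFactors = FALSE)
  hac <- c(3L, 3L, 3L, 6L, 0L)
  out <- novelty_by_hac(v, hac, chunk_size = 2)
  # single-HAC substream reduces to novelty_analysis
  h3 <- out[out$hac == 3, ]
  ref <- novelty_analysis(v[hac == 3 | !v$is_valid, ][1:3, ], chunk_size = 2)
  expect_equal(h3$n_novel[h3$chunk == 1], ref$series$n_novel[1])
  # chunk 3 has only the invalid: HAC-6 cell there is NA
  expect_true(is.na(out$novelty[out$hac == 6 & out$chunk == 3]))
  expect_equal(out$novelty[out$hac == 6 & out$chunk == 2], 100)
})
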