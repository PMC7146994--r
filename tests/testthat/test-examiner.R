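# Statistical-quality-control margins and the early-stopping automaton.

test_that("normal-approximation margins match the closed form", {
  cfg <- sqc_config(0.97, 300)
  m <- ci_margins(cfg)
  z <- qnorm(0.975)
  half <- z * sqrt(0.97 * 0.03 / 300)
  expect_equal(unname(m["lower"]), 0.97 - half, tolerance = 1e-12)
  expect_equal(unname(m["upper"]), 0.97 + half, tolerance = 1e-12)
  # the values the closed form gives in the operating regime
  expect_equal(unname(m["lower"]), 0.9507, tolerance = 1e-4)
  expect_equal(unname(m["upper"]), 0.9893, tolerance = 1e-4)
})

test_that("normal margins bracket the exact binomial quantiles within 0.5/n", {
  n <- 300
  m <- ci_margins(sqc_config(0.97, n))
  exact_lo <- qbinom(0.025, n, 0.97) / n
  exact_hi <- qbinom(0.975, n, 0.97) / n
  # the exact quantiles lie inside the normal interval widened by 0.5/n;
  # the lower margins additionally agree to within 0.5/n (the upper pair
  # differs by ~0.8/n because the binomial quantile is discrete and the
  # distribution is left-skewed at p = 0.97)
  expect_gte(exact_lo, m[["lower"]] - 0.5 / n)
  expect_lte(exact_hi, m[["upper"]] + 0.5 / n)
  expect_lt(abs(m[["lower"]] - exact_lo), 0.5 / n + 1e-12)
  me <- ci_margins(sqc_config(0.97, n, method = "exact"))
  expect_equal(unname(me["lower"]), exact_lo)
  expect_equal(unname(me["upper"]), exact_hi)
})

test_that("margins shrink with sample size and finite population", {
  widths <- vapply(c(30, 100, 300, 1000, 3000), function(n) {
    m <- ci_margins(sqc_config(0.9, n))
    m[["upper"]] - m[["lower"]]
  }, 0)
  expect_true(all(diff(widths) < 0))

  # census: no sampling error
  m <- ci_margins(sqc_config(0.9, 300, population_size = 300))
  expect_equal(unname(m), c(0.9, 0.9))
  # Npop decreasing toward Nsample narrows the margins monotonically
  w <- vapply(c(100000, 10000, 1000, 400, 300), function(Np) {
    m <- ci_margins(sqc_config(0.9, 300, population_size = Np))
    m[["upper"]] - m[["lower"]]
  }, 0)
  expect_true(all(diff(w) < 0))

  # strict bracketing for all proper configs
  for (p in c(0.1, 0.5, 0.97)) {
    m <- ci_margins(sqc_config(p, 50, population_size = 500))
    expect_lt(m[["lower"]], p)
    expect_gt(m[["upper"]], p)
  }
  expect_warning(ci_margins(sqc_config(1, 300)), "degenerate")
})

test_that("the automaton reproduces the hand-simulated traces", {
  cfg <- sqc_config(0.97, 300, patience = 3)
  # margins are ~ (95.07, 98.93) percent
  r1 <- run_examination(c(96, 97, 96), cfg)
  expect_true(r1$converged)
  expect_equal(r1$stopped_epoch, 3L)
  expect_equal(r1$selected_epoch, 1L)

  r2 <- run_examination(c(96, 94, 96, 96, 96), cfg)
  expect_equal(r2$records$streak_length_after, c(1, 0, 1, 2, 3))
  expect_equal(r2$stopped_epoch, 5L)
  expect_equal(r2$selected_epoch, 3L)

  # validity exactly at the lower margin counts as stable
  lower <- r1$lower_margin
  r3 <- run_examination(rep(lower, 3), cfg)
  expect_true(r3$converged)
  # above the upper margin also counts as stable by default
  r4 <- run_examination(c(99.9, 99.9, 99.9), cfg)
  expect_true(r4$converged)
  # ... but resets under the strict two-sided variant
  cfg2 <- sqc_config(0.97, 300, patience = 3, two_sided = TRUE)
  r5 <- run_examination(rep(99.9, 10), cfg2)
  expect_false(r5$converged)

  # never-stable trace: non-convergence flagged
  r6 <- run_examination(rep(50, 8), cfg)
  expect_false(r6$converged)
  expect_equal(r6$stopped_epoch, 8L)

  expect_error(run_examination(numeric(), cfg), "empty")
})

test_that("run_examination equals the brute-force replay on random traces", {
  set.seed(31)
  for (i in 1:150) {
    patience <- sample(c(1L, 3L, 10L), 1)
    cfg <- sqc_config(0.97, 300, patience = patience)
    lower <- 100 * ci_margins(cfg)[["lower"]]
    n <- sample(3:40, 1)
    trace <- pmin(100, pmax(0, rnorm(n, mean = 96, sd = 3)))
    got <- run_examination(trace, cfg)
    want <- replay_examination_bruteforce(trace, lower, patience)
    expect_equal(got$stopped_epoch, want$stopped)
    expect_equal(got$selected_epoch, want$selected)
    expect_equal(got$converged, want$converged)
  }
})

test_that("EpochRecord invariant: streak resets exactly when below lower", {
  cfg <- sqc_config(0.5, 300, patience = 100)
  r <- run_examination(c(60, 30, 60, 60, 20, 60), cfg)
  expect_equal(r$records$streak_length_after == 0, r$records$below_lower)
})

test_that("examine_epoch measures a scripted generator exactly", {
  cfg <- sqc_config(0.5, sample_size = 40, patience = 3)
  mock <- scripted_mock_generator(c(1.0, 0.5, 0.25))
  r1 <- examine_epoch(mock, NULL, cfg, prior_streak = 0L, seed = 1, epoch = 1)
  expect_equal(r1$validity, 100)
  expect_equal(r1$streak_length_after, 1L)
  r2 <- examine_epoch(mock, NULL, cfg, prior_streak = r1$streak_length_after,
                      seed = 2, epoch = 2)
  expect_equal(r2$validity, 50)
  expect_equal(r2$streak_length_after, 2L)
  r3 <- examine_epoch(mock, NULL, cfg, prior_streak = r2$streak_length_after,
                      seed = 3, epoch = 3)
  expect_equal(r3$validity, 25)
  expect_true(r3$below_lower)
  expect_equal(r3$streak_length_after, 0L)
  expect_error(examine_epoch(mock, NULL, cfg, 0L, seed = 4, epoch = 4),
               "exhausted")
})

test_that("mock generator on a stable schedule stops at patience", {
  cfg <- sqc_config(0.95, sample_size = 100, patience = 10)
  mock <- scripted_mock_generator(rep(0.96, 12))
  streak <- 0L; vals <- numeric(0)
  for (e in 1:12) {
    rec <- examine_epoch(mock, NULL, cfg, streak, seed = e, epoch = e)
    streak <- rec$streak_length_after
    vals <- c(vals, rec$validity)
    if (streak >= cfg$patience) break
  }
  res <- run_examination(vals, cfg)
  expect_equal(res$stopped_epoch, 10L)
  expect_equal(res$selected_epoch, 1L)
})

test_that("examination log round-trips through CSV", {
  cfg <- sqc_config(0.97, 300, patience = 2)
  res <- run_examination(c(96, 90, 97, 96.5), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_examination_log(res, path)
  df <- read.csv(path)
  expect_equal(nrow(df), res$stopped_epoch)
  expect_equal(df$validity, res$records$validity)
  expect_equal(sum(df$selected), 1L)
})
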