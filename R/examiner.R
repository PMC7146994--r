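# The examination mechanism: after every training epoch an independent
# examiner draws a sample of generated strings, measures the percentage of
# valid SMILES, and tests it against binomial confidence-interval control
# margins. A streak of `patience` consecutive in-control epochs stops
# training; the earliest model of that streak is selected. The examiner
# has no feedback path into the generator's weights or optimizer.

#' Statistical-quality-control configuration
#'
#' @param target_rate target validity proportion p in (0, 1) (e.g. 0.97).
#' @param sample_size strings generated per examination (default 300).
#' @param population_size optional finite population size Npop
#'   (>= sample_size); when given, margins shrink by the finite population
#'   correction `sqrt((Npop - n) / (Npop - 1))`.
#' @param confidence two-sided confidence level (default 0.95).
#' @param patience consecutive in-control epochs required to stop
#'   (default 10).
#' @param two_sided when `TRUE`, an epoch above the upper margin also
#'   resets the streak; default `FALSE` (only falling below the lower
#'   margin resets -- above-target validity counts as stable).
#' @param method `"normal"` (default) for the normal-approximation margins
#'   or `"exact"` for binomial quantile margins.
#' @return object of class `sqc_config`.
#' @export
sqc_config <- function(target_rate, sample_size = 300L,
                       population_size = NULL, confidence = 0.95,
                       patience = 10L, two_sided = FALSE,
                       method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(target_rate >= 0, target_rate <= 1, sample_size >= 1,
            confidence > 0, confidence < 1, patience >= 1)
  if (!is.null(population_size)) {
    stopifnot(population_size >= sample_size)
  }
  structure(list(target_rate = target_rate,
                 sample_size = as.integer(sample_size),
                 population_size = population_size,
                 confidence = confidence,
                 patience = as.integer(patience),
                 two_sided = isTRUE(two_sided),
                 method = method),
            class = "sqc_config")
}

#' Confidence-interval control margins
#'
#' Normal-approximation binomial margins around the target rate:
#' `p +/- z * sqrt(p (1 - p) / n) * FPC`, with z the two-sided normal
#' quantile for the confidence level and FPC the finite population
#' correction when a population size is given (a census, Npop = n, has
#' zero sampling error). Margins are clamped to `[0, 1]`. With
#' `method = "exact"`, binomial quantiles `qbinom(alpha/2, n, p)/n` and
#' `qbinom(1 - alpha/2, n, p)/n` are used instead; in the operating regime
#' (p near 0.97, n = 300) the two agree within `0.5 / n`.
#'
#' @param config an [sqc_config()].
#' @return named numeric vector `c(lower =, upper =)`, as proportions.
#' @export
ci_margins <- function(config) {
  stopifnot(inherits(config, "sqc_config"))
  p <- config$target_rate; n <- config$sample_size
  if (p == 0 || p == 1) {
    warning("degenerate target rate: margins collapse to the target")
    return(c(lower = p, upper = p))
  }
  alpha <- 1 - config$confidence
  fpc <- 1
  if (!is.null(config$population_size)) {
    Np <- config$population_size
    fpc <- if (Np > 1) sqrt((Np - n) / (Np - 1)) else 0
  }
  if (config$method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n) * fpc
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    lo <- stats::qbinom(alpha / 2, n, p) / n
    hi <- stats::qbinom(1 - alpha / 2, n, p) / n
    mid <- p
    lo <- mid - (mid - lo) * fpc
    hi <- mid + (hi - mid) * fpc
  }
  c(lower = lo, upper = hi)
}

# streak update rule shared by the online and offline paths.
# validity and margins on the percentage (0..100) scale.
streak_update <- function(validity, prior_streak, lower_pct, upper_pct,
                          two_sided) {
  below <- validity < lower_pct
  out_of_control <- below || (two_sided && validity > upper_pct)
  list(below_lower = below,
       streak = if (out_of_control) 0L else prior_streak + 1L)
}

#' Examine one epoch of a generator
#'
#' Draws `sample_size` strings from the generator (via
#' [sample_strings()]), measures validity% with the same checker used in
#' final evaluation (strings with detectable ring/branch mismatches count
#' as invalid -- they are never excluded from the denominator), and
#' updates the stability streak: the streak resets to zero only when
#' validity falls strictly below the lower margin (or leaves the interval
#' in either direction under `two_sided`).
#'
#' @param generator model handle accepted by [sample_strings()].
#' @param vocab vocabulary for generation.
#' @param config an [sqc_config()].
#' @param prior_streak streak length after the previous epoch.
#' @param seed integer seed for this examination's sample.
#' @param epoch epoch number recorded in the result.
#' @param ... passed to [sample_strings()] (e.g. `max_length`).
#' @return list (one `EpochRecord`): `epoch`, `validity` (percent),
#'   `below_lower`, `streak_length_after`, `n_valid`, `sample_seed`.
#' @export
examine_epoch <- function(generator, vocab, config, prior_streak = 0L,
                          seed = 1L, epoch = NA_integer_, ...) {
  strings <- sample_strings(generator, vocab, config$sample_size, seed = seed,
                            ...)
  verdicts <- check_validity(strings)
  validity <- 100 * mean(verdicts$is_valid)
  margins <- 100 * ci_margins(config)
  upd <- streak_update(validity, prior_streak, margins[["lower"]],
                       margins[["upper"]], config$two_sided)
  list(epoch = epoch, validity = validity,
       below_lower = upd$below_lower,
       streak_length_after = upd$streak,
       n_valid = sum(verdicts$is_valid),
       sample_seed = seed)
}

#' Replay the examination automaton over a validity trace
#'
#' Offline version of the examiner: given per-epoch validity measurements
#' (percent scale), applies the streak rules and reports the stopping and
#' selected epochs. Stopping occurs at the first epoch whose streak
#' reaches `patience`; the selected model is the earliest epoch of that
#' streak (`stopped - patience + 1`). If the trace is exhausted first, the
#' run is flagged non-convergent and the first epoch of the terminal
#' streak is selected (falling back to the best-validity epoch when the
#' last epoch was out of control).
#'
#' @param validities numeric vector of per-epoch validity percentages.
#' @param config an [sqc_config()].
#' @return object of class `gen_examination`: `stopped_epoch`,
#'   `selected_epoch`, `converged`, `records` (data.frame with epoch,
#'   validity, below_lower, streak_length_after), `lower_margin`,
#'   `upper_margin` (percent scale).
#' @export
run_examination <- function(validities, config) {
  if (length(validities) == 0) stop("empty validity stream")
  margins <- 100 * ci_margins(config)
  n <- length(validities)
  streaks <- integer(n); below <- logical(n)
  streak <- 0L
  stopped <- NA_integer_
  for (e in seq_len(n)) {
    upd <- streak_update(validities[e], streak, margins[["lower"]],
                         margins[["upper"]], config$two_sided)
    streak <- upd$streak
    below[e] <- upd$below_lower
    streaks[e] <- streak
    if (streak >= config$patience) { stopped <- e; break }
  }
  examined <- if (is.na(stopped)) n else stopped
  records <- data.frame(
    epoch = seq_len(examined),
    validity = validities[seq_len(examined)],
    below_lower = below[seq_len(examined)],
    streak_length_after = streaks[seq_len(examined)])
  if (!is.na(stopped)) {
    selected <- stopped - config$patience + 1L
    converged <- TRUE
  } else {
    converged <- FALSE
    terminal <- streaks[n]
    selected <- if (terminal > 0) n - terminal + 1L else which.max(validities)
  }
  structure(list(stopped_epoch = examined, selected_epoch = selected,
                 converged = converged, records = records,
                 lower_margin = margins[["lower"]],
                 upper_margin = margins[["upper"]]),
            class = "gen_examination")
}

#' @export
print.gen_examination <- function(x, ...) {
  cat(sprintf("<gen_examination> stopped at epoch %d, selected epoch %d (%s); margins [%.2f, %.2f]%%\n",
              x$stopped_epoch, x$selected_epoch,
              if (x$converged) "converged" else "non-convergent",
              x$lower_margin, x$upper_margin))
  invisible(x)
}

#' Online examiner callback for [train_network()]
#'
#' Builds a stateful callback that examines the model after each epoch
#' with a per-epoch sample seed derived deterministically from
#' `(run_seed, epoch)`, and signals stop once the streak reaches
#' `patience`. Retrieve the accumulated records and selection with
#' `examiner_result(cb)` after training.
#'
#' @param vocab vocabulary for generation.
#' @param config an [sqc_config()].
#' @param run_seed integer run seed.
#' @param generation_args list of extra arguments for [sample_strings()]
#'   (e.g. `max_length`, `window_length`).
#' @return callback `function(model, epoch)` with state in its closure.
#' @export
make_examiner <- function(vocab, config, run_seed = 1L,
                          generation_args = list()) {
  state <- new.env(parent = emptyenv())
  state$streak <- 0L
  state$records <- list()
  cb <- function(model, epoch) {
    seed <- derive_seed(run_seed, epoch)
    rec <- do.call(examine_epoch,
                   c(list(generator = model, vocab = vocab, config = config,
                          prior_streak = state$streak, seed = seed,
                          epoch = epoch), generation_args))
    state$streak <- rec$streak_length_after
    state$records[[epoch]] <- rec
    list(stop = state$streak >= config$patience, record = rec)
  }
  attr(cb, "state") <- state
  attr(cb, "config") <- config
  cb
}

#' Collect the result of an online examiner
#' @param examiner callback created by [make_examiner()].
#' @return a `gen_examination` (see [run_examination()]).
#' @export
examiner_result <- function(examiner) {
  state <- attr(examiner, "state")
  config <- attr(examiner, "config")
  validities <- vapply(state$records, `[[`, 0, "validity")
  run_examination(validities, config)
}

# deterministic per-epoch seed, kept within 32-bit integer range and
# decorrelated across epochs
derive_seed <- function(run_seed, epoch) {
  as.integer((as.numeric(run_seed) * 48271 + as.numeric(epoch) * 16807) %%
               2147483647)
}

#' Write an examination log as CSV
#'
#' One row per examined epoch with the margins and stop/selection flags --
#' the data behind a monitoring plot of validity against the control
#' interval.
#'
#' @param result a `gen_examination`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_examination_log <- function(result, path) {
  df <- result$records
  df$lower_margin <- result$lower_margin
  df$upper_margin <- result$upper_margin
  df$stopped <- df$epoch == result$stopped_epoch & result$converged
  df$selected <- df$epoch == result$selected_epoch
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
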