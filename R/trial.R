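#' Configuration of a single trial
#'
#' Bundles everything one trial needs: the hypothesis posterior, the
#' partition into response alternatives, the query (which behavioral measure
#' is elicited), the stopping rule, the sampler configuration, and the
#' response-time clock.
#'
#' @param spec The trial's [posterior_spec()].
#' @param partition An [partition_spec()].
#' @param query One of `"choice"`, `"probability_judgment"`, `"estimate"`,
#'   `"ci_produce"`, `"ci_evaluate"`, `"choice_plus_estimate"`,
#'   `"choice_plus_confidence"`.
#' @param rule An [stopping_rule()].
#' @param sampler An [sampler_config()].
#' @param anchor Optional comparison value h*: when given, every chain is
#'   initialized at it (overriding cross-trial carryover).
#' @param reinit Re-initialize the chains randomly from this trial's
#'   posterior instead of continuing from the carried-over state.  Used for
#'   batteries of unrelated decision problems; repeated-estimation batteries
#'   leave it `FALSE` so the sampler's location persists across trials.
#' @param correct Index of the objectively correct alternative, or `NULL`;
#'   used for accuracy scoring and as the feedback that adapts the response
#'   prior on the following trial.
#' @param target Alternative index whose probability is judged
#'   (`probability_judgment` query).
#' @param ci_level Coverage level gamma for `ci_produce`.
#' @param eval_interval Length-2 interval `(lo, hi)` for `ci_evaluate`.
#' @param estimate_mode `"last"` (default: the most recent sample) or
#'   `"mean"` (the sample average).
#' @param rate_lambda Sampling rate in samples per second.
#' @param t0 Nondecision time in seconds.
#' @return An object of class `"abs_trial_config"`.
#' @export
trial_config <- function(spec, partition,
                         query = c("choice", "probability_judgment",
                                   "estimate", "ci_produce", "ci_evaluate",
                                   "choice_plus_estimate",
                                   "choice_plus_confidence"),
                         rule = stopping_rule(),
                         sampler = sampler_config(),
                         anchor = NULL, reinit = FALSE, correct = NULL,
                         target = 2L,
                         ci_level = 0.9, eval_interval = NULL,
                         estimate_mode = c("last", "mean"),
                         rate_lambda = 10, t0 = 0) {
  query <- match.arg(query)
  estimate_mode <- match.arg(estimate_mode)
  stopifnot(inherits(spec, "abs_posterior"),
            inherits(partition, "abs_partition"),
            inherits(rule, "abs_stopping_rule"),
            inherits(sampler, "abs_sampler_config"),
            rate_lambda > 0, t0 >= 0, ci_level > 0, ci_level <= 1)
  if (!is.null(eval_interval))
    stopifnot(length(eval_interval) == 2L, eval_interval[1] < eval_interval[2])
  if (query == "ci_evaluate" && is.null(eval_interval))
    stop("ci_evaluate query needs an eval_interval")
  structure(list(spec = spec, partition = partition, query = query,
                 rule = rule, sampler = sampler, anchor = anchor,
                 reinit = isTRUE(reinit),
                 correct = correct, target = as.integer(target),
                 ci_level = ci_level, eval_interval = eval_interval,
                 estimate_mode = estimate_mode,
                 rate_lambda = rate_lambda, t0 = t0),
            class = "abs_trial_config")
}

#' Run one trial end to end
#'
#' Samples hypotheses until the stopping rule fires, converts the samples
#' into the queried behavioral measures, draws a response time, and returns
#' the sampler state after the last sample for cross-trial carryover.  If the
#' trial supplies an anchor h*, the chains are re-initialized there first.
#'
#' @param config An [trial_config()].
#' @param state An `"abs_sampler_state"` (from [init_state()] or a previous
#'   trial via [carryover()]).
#' @param prior An [response_prior()] over the partition's alternatives.
#' @return A list with `record` (class `"abs_trial_record"`: samples, tallies,
#'   choice, accuracy, RT, confidence, probability judgment, estimate, and
#'   interval, as applicable) and the updated `state`.
#' @export
run_trial <- function(config, state, prior) {
  stopifnot(inherits(config, "abs_trial_config"),
            inherits(state, "abs_sampler_state"),
            inherits(prior, "abs_response_prior"),
            prior$M == config$partition$n_alternatives)
  spec <- config$spec
  smp <- config$sampler
  if (!is.null(config$anchor))
    state$chain_positions <- rep(as.numeric(config$anchor), smp$n_chains)
  else if (isTRUE(config$reinit))
    state$chain_positions <- posterior_draw(spec, smp$n_chains)

  sc <- spec_cpp(spec)
  out <- cpp_collect_samples(pos_to_cpp(state$chain_positions, spec),
                             sc$family, sc$mean, sc$sd, sc$gv, sc$glm,
                             alg_code(smp$algorithm), smp$temperatures,
                             prop_sd_abs(smp, spec), smp$swap_prob,
                             config$partition$boundaries, prior$alphas,
                             match(config$rule$kind,
                                   c("fixed_n", "max_minus_next")) - 1L,
                             config$rule$n_fixed, config$rule$delta,
                             config$rule$n_max)
  state$chain_positions <- pos_from_cpp(out$positions, spec)
  samples <- out$samples
  counts <- out$counts
  n <- length(samples)

  rec <- list(samples = samples, counts = counts, n_samples = n,
              choice = NA_integer_, correct = NA, rt = NA_real_,
              confidence = NA_real_, prob_judgment = NA_real_,
              estimate = NA_real_, ci = c(NA_real_, NA_real_))
  q <- config$query
  if (q %in% c("choice", "choice_plus_estimate", "choice_plus_confidence")) {
    rec$choice <- out$chosen
    rec$confidence <- confidence_at_stop(prior, counts, out$chosen)
    if (!is.null(config$correct)) rec$correct <- out$chosen == config$correct
  }
  if (q == "probability_judgment")
    rec$prob_judgment <- probability_estimate(prior, counts, config$target)
  if (q == "estimate" || q == "choice_plus_estimate")
    rec$estimate <- estimate_from_samples(samples, config$estimate_mode)
  if (q == "ci_produce")
    rec$ci <- ci_produce(samples, config$ci_level)
  if (q == "ci_evaluate")
    rec$prob_judgment <- ci_evaluate(samples, config$eval_interval)
  rec$rt <- rt_draw(n, config$rate_lambda, config$t0)
  class(rec) <- "abs_trial_record"
  list(record = rec, state = state)
}

#' @export
print.abs_trial_record <- function(x, ...) {
  cat(sprintf("Trial record: %d samples, rt = %.3f s\n", x$n_samples, x$rt))
  if (!is.na(x$choice))
    cat(sprintf("  choice %d (confidence %.3f)\n", x$choice, x$confidence))
  if (!is.na(x$estimate)) cat(sprintf("  estimate %.3f\n", x$estimate))
  if (!is.na(x$prob_judgment))
    cat(sprintf("  probability judgment %.3f\n", x$prob_judgment))
  if (!is.na(x$ci[1]))
    cat(sprintf("  interval [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Point estimate from a set of hypothesis samples
#'
#' With autocorrelated samples the most recent sample is least biased by the
#' starting point, so `"last"` is the default; `"mean"` (the sample average)
#' is the aggregate-equivalent alternative.
#'
#' @param samples Numeric vector of samples (at least one).
#' @param mode `"last"` or `"mean"`.
#' @return The estimate.
#' @export
estimate_from_samples <- function(samples, mode = c("last", "mean")) {
  mode <- match.arg(mode)
  if (length(samples) < 1L) stop("no samples to form an estimate")
  if (mode == "last") samples[length(samples)] else mean(samples)
}

#' Produce a confidence interval from samples by sample coverage
#'
#' The interval's bounds are placed at the symmetric fractional order
#' statistics that cover a fraction `gamma` of the sample: with order
#' statistics `x_(1..N)` and covered count `m = gamma * N`, the bounds sit at
#' fractional ranks `r = (N - m) / 2 + 1` and `s = r + m - 1`, linearly
#' interpolated between adjacent order statistics and clamped to the sample
#' range.  For five samples and gamma = 0.6 this returns the second and
#' fourth order statistics.
#'
#' @param samples At least two samples.
#' @param gamma Requested coverage level in (0, 1].
#' @return Numeric `c(lo, hi)`.
#' @examples
#' ci_produce(c(10, 12, 14, 16, 18), 0.6) # c(12, 16)
#' @export
ci_produce <- function(samples, gamma) {
  if (length(samples) < 2L) stop("need at least two samples")
  stopifnot(gamma > 0, gamma <= 1)
  x <- sort(samples)
  n <- length(x)
  m <- gamma * n
  r <- (n - m) / 2 + 1
  s <- r + m - 1
  at <- function(rank) {
    rank <- min(max(rank, 1), n)
    lo <- floor(rank)
    fr <- rank - lo
    if (lo >= n) x[n] else x[lo] + fr * (x[lo + 1] - x[lo])
  }
  c(at(r), at(s))
}

#' Evaluate a given interval by the proportion of samples it contains
#'
#' The judged probability that the stimulus falls in `interval` is the
#' fraction of samples inside the closed interval — an unbiased estimator of
#' the true coverage.  Optionally the raw proportion can be tempered by a
#' response prior, treating inside/outside as a binary event.
#'
#' @param samples At least one sample.
#' @param interval Numeric `c(lo, hi)`.
#' @param prior Optional [response_prior()] (binary) for tempering; default
#'   is the raw proportion.
#' @return A probability.
#' @examples
#' ci_evaluate(c(10, 12, 14, 16, 18), c(11, 17)) # 0.6
#' @export
ci_evaluate <- function(samples, interval, prior = NULL) {
  if (length(samples) < 1L) stop("need at least one sample")
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  inside <- sum(samples >= interval[1] & samples <= interval[2])
  if (is.null(prior)) return(inside / length(samples))
  probability_estimate(prior, c(inside, length(samples) - inside), 1L)
}

#' Draw a response time for a trial of n samples
#'
#' Samples are generated at a constant rate by a Poisson process, so the
#' time to produce `n` samples is the sum of `n` i.i.d. exponential waits —
#' an Erlang(`n`, `lambda`) variate — plus the nondecision time `t0`.
#'
#' @param n Number of samples (0 gives `t0` exactly).
#' @param lambda Sampling rate, samples per second.
#' @param t0 Nondecision time, seconds.
#' @return Response time in seconds.
#' @export
rt_draw <- function(n, lambda, t0 = 0) {
  stopifnot(n >= 0, lambda > 0, t0 >= 0)
  if (n == 0L) return(t0)
  t0 + sum(rexp(n, lambda))
}

#' Run a sequence of trials with carryover and an adaptive prior
#'
#' Trials are executed in order.  The sampler state is carried across trials
#' (unless a trial supplies an anchor), and when `adaptive = TRUE` the
#' response prior is rebuilt each trial from the previous trial's feedback
#' (reset to uniform plus one pseudocount on the previously correct
#' alternative).  With `adaptive = FALSE` the supplied prior is used on every
#' trial.
#'
#' @param battery A list of [trial_config()]s.
#' @param prior The initial [response_prior()].
#' @param adaptive Adapt the prior to feedback trial by trial?
#' @param state Optional initial sampler state; defaults to a random
#'   initialization from the first trial's posterior.
#' @param keep_samples Also return the per-trial sample vectors.
#' @return A data frame with one row per trial (columns `trial_index`,
#'   `query`, `n_samples`, `choice`, `correct`, `rt`, `confidence`,
#'   `prob_judgment`, `estimate`, `ci_lo`, `ci_hi`); if `keep_samples`, the
#'   samples are attached as attribute `"samples"` (a list).
#' @export
run_trials <- function(battery, prior, adaptive = FALSE, state = NULL,
                       keep_samples = FALSE) {
  stopifnot(length(battery) >= 1L)
  nt <- length(battery)
  if (is.null(state))
    state <- init_state(battery[[1L]]$sampler, "random", battery[[1L]]$spec)
  base_prior <- prior
  query <- character(nt)
  n_samples <- choice <- correct_alt <- integer(nt)
  correct <- logical(nt); correct[] <- NA
  rt <- confidence <- prob_judgment <- estimate <- ci_lo <- ci_hi <-
    numeric(nt)
  all_samples <- if (keep_samples) vector("list", nt) else NULL
  prev_correct <- NULL
  for (i in seq_len(nt)) {
    cfg <- battery[[i]]
    p <- if (adaptive) adapt_from_feedback(base_prior, prev_correct)
         else base_prior
    res <- run_trial(cfg, state, p)
    state <- carryover(res$state, cfg$spec)
    r <- res$record
    query[i] <- cfg$query
    n_samples[i] <- r$n_samples
    choice[i] <- r$choice
    correct[i] <- r$correct
    correct_alt[i] <- if (is.null(cfg$correct)) NA_integer_
                      else as.integer(cfg$correct)
    rt[i] <- r$rt
    confidence[i] <- r$confidence
    prob_judgment[i] <- r$prob_judgment
    estimate[i] <- r$estimate
    ci_lo[i] <- r$ci[1]
    ci_hi[i] <- r$ci[2]
    if (keep_samples) all_samples[[i]] <- r$samples
    prev_correct <- cfg$correct
  }
  out <- data.frame(trial_index = seq_len(nt), query = query,
                    n_samples = n_samples, choice = choice,
                    correct = correct, correct_alt = correct_alt, rt = rt,
                    confidence = confidence, prob_judgment = prob_judgment,
                    estimate = estimate, ci_lo = ci_lo, ci_hi = ci_hi,
                    stringsAsFactors = FALSE)
  if (keep_samples) attr(out, "samples") <- all_samples
  out
}
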