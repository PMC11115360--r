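#' Model variants used in the simulation battery
#'
#' The full model draws autocorrelated samples by parallel tempering (MC3),
#' tempers evidence with an adaptive Beta/Dirichlet response prior, and stops
#' choices by the max-minus-next rule.  The ablations each remove one
#' ingredient: `no_prior` sets every pseudocount to zero (raw relative
#' frequencies, no adaptation), `direct_sampling` replaces the local sampler
#' with i.i.d. draws, and `fixed_sample_size` replaces optional stopping with
#' a fixed N = 5 samples for every response.
#'
#' @param name One of `"full"`, `"no_prior"`, `"direct_sampling"`,
#'   `"fixed_sample_size"`.
#' @param sampler Base [sampler_config()] for the local-sampling variants.
#' @return An object of class `"abs_variant"` with fields `name`,
#'   `sampler`, `alpha` (symmetric pseudocount), `adaptive`, and
#'   `fixed_n` (`NA` unless the variant fixes the sample size).
#' @export
abs_variant <- function(name = c("full", "no_prior", "direct_sampling",
                                 "fixed_sample_size"),
                        sampler = sampler_config()) {
  name <- match.arg(name)
  v <- list(name = name, sampler = sampler, alpha = 1, adaptive = TRUE,
            fixed_n = NA_integer_)
  if (name == "no_prior") {
    v$alpha <- 0
    v$adaptive <- FALSE
  } else if (name == "direct_sampling") {
    v$sampler <- sampler_config("direct")
  } else if (name == "fixed_sample_size") {
    v$fixed_n <- 5L
  }
  structure(v, class = "abs_variant")
}

#' @export
print.abs_variant <- function(x, ...) {
  cat(sprintf("Model variant: %s\n", x$name))
  print(x$sampler)
  cat(sprintf("  response prior: symmetric alpha = %g (%s)\n", x$alpha,
              if (x$adaptive) "adaptive to feedback" else "static"))
  if (!is.na(x$fixed_n))
    cat(sprintf("  fixed sample size N = %d for all responses\n", x$fixed_n))
  invisible(x)
}

variant_prior <- function(variant, m = 2L) response_prior(rep(variant$alpha, m))

# choice rule: the variant's stopping policy at threshold delta
variant_choice_rule <- function(variant, delta, n_max = 1000L) {
  if (!is.na(variant$fixed_n))
    stopping_rule("fixed_n", n_fixed = variant$fixed_n, n_max = n_max)
  else
    stopping_rule("max_minus_next", delta = delta, n_max = n_max)
}

#' Bundle a model configuration
#'
#' Convenience constructor pairing a variant with task-independent
#' parameters; `simulate()` on the result runs a sequence of identical
#' trials, which is the quickest way to see the model produce behavior.
#'
#' @param variant An [abs_variant()] or a variant name.
#' @param rate_lambda Sampling rate (samples/second).
#' @param t0 Nondecision time (seconds).
#' @return An object of class `"abs_model"`.
#' @examples
#' m <- abs_model("full")
#' print(m)
#' @export
abs_model <- function(variant = "full", rate_lambda = 10, t0 = 0.2) {
  if (is.character(variant)) variant <- abs_variant(variant)
  stopifnot(inherits(variant, "abs_variant"), rate_lambda > 0, t0 >= 0)
  structure(list(variant = variant, rate_lambda = rate_lambda, t0 = t0),
            class = "abs_model")
}

#' @export
print.abs_model <- function(x, ...) {
  cat("Autocorrelated Bayesian sampler model\n")
  print(x$variant)
  cat(sprintf("  sampling rate %g samples/s, nondecision time %g s\n",
              x$rate_lambda, x$t0))
  invisible(x)
}

#' Simulate repeated trials from a model configuration
#'
#' Runs `nsim` consecutive trials of the same task with cross-trial
#' carryover and (for adaptive variants) feedback adaptation of the response
#' prior.
#'
#' @param object An [abs_model()].
#' @param nsim Number of trials.
#' @param seed Optional seed.
#' @param spec Trial posterior; default Gaussian(27, 3).
#' @param boundary Decision boundary; default 25.
#' @param query Trial query (see [trial_config()]).
#' @param delta Max-minus-next threshold for choice queries.
#' @param n_fixed Sample size for judgment-type queries.
#' @param ... Unused.
#' @return The trial data frame from [run_trials()].
#' @export
simulate.abs_model <- function(object, nsim = 100, seed = NULL,
                               spec = posterior_spec("gaussian", 27, 3),
                               boundary = 25,
                               query = "choice", delta = 2L, n_fixed = 5L,
                               ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- object$variant
  part <- partition_spec(boundary, labels = c("lower", "greater"))
  correct <- if (spec$family == "gaussian" && spec$mean >= boundary) 2L else 1L
  rule <- if (query %in% c("choice", "choice_plus_estimate",
                           "choice_plus_confidence"))
    variant_choice_rule(v, delta)
  else stopping_rule("fixed_n", n_fixed = n_fixed)
  battery <- replicate(nsim, trial_config(
    spec, part, query = query, rule = rule, sampler = v$sampler,
    correct = correct, rate_lambda = object$rate_lambda, t0 = object$t0),
    simplify = FALSE)
  run_trials(battery, variant_prior(v), adaptive = v$adaptive)
}
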