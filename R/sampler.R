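#' Configuration of the hypothesis-sampling algorithm
#'
#' Three sampling algorithms are available.  `"mc3"` (Metropolis-coupled
#' MCMC, parallel tempering) runs several Metropolis chains on tempered
#' versions of the posterior and occasionally proposes swapping adjacent
#' chains; the cold chain's positions are the reported samples.  `"rwm"` is a
#' single random-walk Metropolis chain.  `"direct"` draws independent samples
#' and is the i.i.d. reference variant.
#'
#' Local proposals are Gaussian with standard deviation
#' `proposal_sd * posterior sd` for Gaussian targets (`proposal_sd` is in
#' units of the posterior spread, so locality is scale free); on a discrete
#' grid the proposal is a symmetric one-cell step.
#'
#' @param algorithm `"mc3"`, `"rwm"`, or `"direct"`.
#' @param n_chains Number of tempered chains (`mc3` only).
#' @param temperatures Increasing temperature ladder; first entry must be 1
#'   (the cold chain).
#' @param proposal_sd Local proposal scale, as a multiple of the posterior
#'   standard deviation.
#' @param swap_prob Probability of proposing one adjacent-pair swap per
#'   iteration.
#' @return An object of class `"abs_sampler_config"`.
#' @export
sampler_config <- function(algorithm = c("mc3", "rwm", "direct"),
                           n_chains = 4L,
                           temperatures = NULL,
                           proposal_sd = 0.25,
                           swap_prob = 1) {
  algorithm <- match.arg(algorithm)
  if (algorithm != "mc3") n_chains <- 1L
  if (is.null(temperatures))
    temperatures <- default_temperatures(n_chains)
  stopifnot(length(temperatures) == n_chains,
            temperatures[1] == 1,
            all(diff(temperatures) > 0) || n_chains == 1L,
            proposal_sd > 0, swap_prob >= 0, swap_prob <= 1)
  structure(list(algorithm = algorithm, n_chains = as.integer(n_chains),
                 temperatures = as.numeric(temperatures),
                 proposal_sd = proposal_sd, swap_prob = swap_prob),
            class = "abs_sampler_config")
}

# geometric ladder: 1, 8, 64, ... -- hot chains relax slowly on wide targets,
# contributing the long timescales behind 1/f structure in repeated estimates
default_temperatures <- function(n_chains) 8^(seq_len(n_chains) - 1)

#' @export
print.abs_sampler_config <- function(x, ...) {
  cat(sprintf("Sampler: %s", x$algorithm))
  if (x$algorithm == "mc3")
    cat(sprintf(", %d chains at T = (%s), swap prob %.2f",
                x$n_chains, paste(x$temperatures, collapse = ", "),
                x$swap_prob))
  if (x$algorithm != "direct")
    cat(sprintf(", proposal sd %.3g x posterior sd", x$proposal_sd))
  cat("\n")
  invisible(x)
}

#' Initialize the sampler state
#'
#' All chains start at `start` when a numeric value is given (this is how a
#' comparison value from a preceding question anchors the sampler); with
#' `start = "random"` each chain draws its initial hypothesis independently
#' from the posterior.
#'
#' @param config An [sampler_config()] object.
#' @param start Numeric start value, or `"random"`.
#' @param spec The trial's [posterior_spec()] (needed for random starts and
#'   grid targets).
#' @return An object of class `"abs_sampler_state"` with per-chain hypothesis
#'   positions and a trial counter.
#' @export
init_state <- function(config, start = "random", spec = NULL) {
  stopifnot(inherits(config, "abs_sampler_config"))
  if (identical(start, "random")) {
    stopifnot(inherits(spec, "abs_posterior"))
    pos <- posterior_draw(spec, config$n_chains)
  } else {
    stopifnot(is.numeric(start), length(start) == 1L, is.finite(start))
    pos <- rep(as.numeric(start), config$n_chains)
  }
  structure(list(chain_positions = pos, trial_index = 0L),
            class = "abs_sampler_state")
}

#' Carry the sampler state over to the next trial
#'
#' The chain positions are retained verbatim as the initialization for the
#' next trial, so the first hypothesis that comes to mind on trial t + 1 is
#' close to the last one entertained on trial t.  An explicit anchor given to
#' [run_trial()] overrides carryover.
#'
#' @param state An `"abs_sampler_state"`.
#' @param next_spec Unused except for validation; the upcoming trial's
#'   posterior.
#' @return The state with `trial_index` incremented.
#' @export
carryover <- function(state, next_spec = NULL) {
  stopifnot(inherits(state, "abs_sampler_state"))
  state$trial_index <- state$trial_index + 1L
  state
}

# --- internal bridges to the C++ kernels --------------------------------

# positions are hypothesis values at the R level; grid targets use 0-based
# indices inside C++ (nearest grid cell on entry, relevant after carryover
# between different grids)
spec_cpp <- function(spec) {
  if (spec$family == "gaussian")
    list(family = 0L, mean = spec$mean, sd = spec$sd,
         gv = numeric(0), glm = numeric(0))
  else
    list(family = 1L, mean = 0, sd = 1,
         gv = spec$grid_values, glm = spec$grid_logmass)
}

pos_to_cpp <- function(pos, spec) {
  if (spec$family == "gaussian") return(pos)
  vapply(pos, function(p) which.min(abs(spec$grid_values - p)) - 1L, 0L)
}

pos_from_cpp <- function(pos, spec) {
  if (spec$family == "gaussian") return(pos)
  spec$grid_values[as.integer(pos) + 1L]
}

prop_sd_abs <- function(config, spec) {
  if (spec$family == "gaussian") config$proposal_sd * spec$sd
  else config$proposal_sd # unused for grid targets (one-cell steps)
}

#' Draw the next autocorrelated hypothesis sample(s)
#'
#' Advances the sampler by `n` reported samples.  One reported sample is: one
#' Metropolis step per chain (cold to hot) followed by at most one swap
#' proposal (`mc3`); one Metropolis step (`rwm`); or one i.i.d. draw
#' (`direct`).  A rejected proposal repeats the current position, and the
#' repeated value is still a reported sample.
#'
#' @param state An `"abs_sampler_state"`.
#' @param spec The trial's [posterior_spec()].
#' @param config An [sampler_config()].
#' @param n Number of reported samples to draw.
#' @return A list with `samples` (length `n`, cold-chain hypothesis values)
#'   and the updated `state`.
#' @export
draw_samples <- function(state, spec, config, n = 1L) {
  stopifnot(inherits(state, "abs_sampler_state"),
            inherits(spec, "abs_posterior"),
            inherits(config, "abs_sampler_config"), n >= 1L)
  sc <- spec_cpp(spec)
  out <- cpp_draw_samples(pos_to_cpp(state$chain_positions, spec),
                          sc$family, sc$mean, sc$sd, sc$gv, sc$glm,
                          alg_code(config$algorithm), config$temperatures,
                          prop_sd_abs(config, spec), config$swap_prob,
                          as.integer(n))
  state$chain_positions <- pos_from_cpp(out$positions, spec)
  list(samples = pos_from_cpp(out$samples, spec), state = state)
}

#' @rdname draw_samples
#' @export
next_sample <- function(state, spec, config) {
  out <- draw_samples(state, spec, config, 1L)
  list(sample = out$samples, state = out$state)
}

alg_code <- function(a) match(a, c("mc3", "rwm", "direct")) - 1L

#' Single Metropolis update of one chain
#'
#' A symmetric local proposal is accepted with probability
#' `min(1, (pi(h') / pi(h))^(1 / T))` for the chain's temperature `T`.
#' Exposed for inspection and testing; [draw_samples()] composes the same
#' kernel.
#'
#' @inheritParams draw_samples
#' @param chain Chain index (1 is the cold chain).
#' @return The updated state.
#' @export
mh_step <- function(state, spec, config, chain = 1L) {
  stopifnot(chain >= 1L, chain <= config$n_chains)
  sc <- spec_cpp(spec)
  pos <- cpp_mh_step(pos_to_cpp(state$chain_positions, spec), chain - 1L,
                     sc$family, sc$mean, sc$sd, sc$gv, sc$glm,
                     config$temperatures, prop_sd_abs(config, spec))
  state$chain_positions <- pos_from_cpp(pos, spec)
  state
}

#' Single adjacent-pair swap proposal between tempered chains
#'
#' With probability `swap_prob` a uniformly chosen adjacent pair (i, i + 1)
#' is proposed for exchange and accepted with the tempered Metropolis ratio;
#' positions are exchanged, never created, so the multiset of positions is
#' preserved.
#'
#' @inheritParams draw_samples
#' @return The updated state.
#' @export
swap_step <- function(state, spec, config) {
  if (config$n_chains < 2L) return(state)
  sc <- spec_cpp(spec)
  pos <- cpp_swap_step(pos_to_cpp(state$chain_positions, spec),
                       sc$family, sc$mean, sc$sd, sc$gv, sc$glm,
                       config$temperatures, config$swap_prob)
  state$chain_positions <- pos_from_cpp(pos, spec)
  state
}
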