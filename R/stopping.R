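#' Stopping rules for sample generation
#'
#' `"fixed_n"` draws exactly `n_fixed` samples and is used for probability
#' judgments, estimates, and confidence intervals.  `"max_minus_next"` is the
#' optional-stopping rule used for choices: sampling terminates as soon as
#' the pseudocount-inclusive evidence total for the leading alternative
#' exceeds the runner-up by at least `delta`.  Because the prior's
#' pseudocounts seed the accumulator, a biased prior can satisfy the
#' threshold before any sample is drawn.  A cap of `n_max` samples forces a
#' majority decision if the threshold is unreachable.
#'
#' @param kind `"fixed_n"` or `"max_minus_next"`.
#' @param n_fixed Sample size for the fixed rule.
#' @param delta Integer evidence-difference threshold (>= 1).
#' @param n_max Hard cap on samples per trial.
#' @return An object of class `"abs_stopping_rule"`.
#' @export
stopping_rule <- function(kind = c("max_minus_next", "fixed_n"),
                          n_fixed = 5L, delta = 2L, n_max = 1000L) {
  kind <- match.arg(kind)
  stopifnot(n_fixed >= 1L, delta >= 1L, n_max >= 1L)
  if (kind == "fixed_n") stopifnot(n_max >= n_fixed)
  structure(list(kind = kind, n_fixed = as.integer(n_fixed),
                 delta = as.integer(delta), n_max = as.integer(n_max)),
            class = "abs_stopping_rule")
}

#' @export
print.abs_stopping_rule <- function(x, ...) {
  if (x$kind == "fixed_n")
    cat(sprintf("Stopping rule: fixed N = %d\n", x$n_fixed))
  else
    cat(sprintf("Stopping rule: max-minus-next, Delta = %d (cap %d)\n",
                x$delta, x$n_max))
  invisible(x)
}

#' Test whether sampling should stop, and with which choice
#'
#' Evidence totals are `alpha_m + S_m`.  Under the fixed rule, stopping
#' occurs exactly at `n_fixed` samples; under max-minus-next, when the top
#' total leads the second by at least `delta`, or at the `n_max` cap with a
#' majority choice.  Argmax ties are broken uniformly at random.
#'
#' @param rule An [stopping_rule()].
#' @param prior An [response_prior()].
#' @param counts Current evidence tallies.
#' @return A list with `stop` (flag) and `chosen` (alternative index, or
#'   `NULL` while sampling continues).
#' @export
should_stop <- function(rule, prior, counts) {
  stopifnot(inherits(rule, "abs_stopping_rule"),
            inherits(prior, "abs_response_prior"),
            length(counts) == prior$M, all(counts >= 0))
  n <- sum(counts)
  totals <- prior$alphas + counts
  pick <- function() {
    tied <- which(totals == max(totals))
    if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
  }
  if (rule$kind == "fixed_n") {
    if (n >= rule$n_fixed) return(list(stop = TRUE, chosen = pick()))
    return(list(stop = FALSE, chosen = NULL))
  }
  srt <- sort(totals, decreasing = TRUE)
  if (srt[1] - srt[2] >= rule$delta || n >= rule$n_max)
    return(list(stop = TRUE, chosen = pick()))
  list(stop = FALSE, chosen = NULL)
}

#' Optimal stopping policy (not implemented)
#'
#' The dynamic-programming solution of the optimal sampling/stopping
#' trade-off is intentionally not provided; the max-minus-next heuristic is
#' the supported optional-stopping rule.
#'
#' @param delta_grid,cost_params Unused.
#' @export
optimal_stop_reference <- function(delta_grid = NULL, cost_params = NULL) {
  stop("not implemented: use the max-minus-next heuristic stopping rule")
}
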