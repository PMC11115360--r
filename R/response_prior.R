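#' Beta/Dirichlet prior on response alternatives
#'
#' Pseudocounts over the `M` response alternatives.  Together with the tally
#' of samples supporting each alternative they give the posterior-mean
#' probability that each alternative is correct; the same quantity is
#' reported as a probability judgment and as decision confidence.  An
#' all-zero prior reduces every estimate to the raw relative frequency of
#' samples.
#'
#' @param alphas Nonnegative pseudocounts, one per alternative (length >= 2).
#' @return An object of class `"abs_response_prior"`.
#' @examples
#' response_prior(c(1, 1))   # noninformative Beta(1,1)
#' response_prior(c(0, 0))   # no-prior variant: raw relative frequency
#' @export
response_prior <- function(alphas) {
  stopifnot(is.numeric(alphas), length(alphas) >= 2L, all(alphas >= 0),
            all(is.finite(alphas)))
  structure(list(alphas = as.numeric(alphas), M = length(alphas)),
            class = "abs_response_prior")
}

#' @export
print.abs_response_prior <- function(x, ...) {
  kind <- if (x$M == 2L) "Beta" else "Dirichlet"
  cat(sprintf("Response prior: %s(%s)\n", kind,
              paste(x$alphas, collapse = ", ")))
  invisible(x)
}

#' Posterior-mean probability estimate from sample tallies
#'
#' The reported probability that alternative `target` is correct after
#' tallying `counts` samples:
#' `(alpha_target + S_target) / (N + sum(alpha))`.
#' Small samples are thereby tempered toward the prior mean rather than
#' reported as raw (and often extreme) relative frequencies.
#'
#' @param prior An [response_prior()].
#' @param counts Nonnegative integer tally of samples per alternative.
#' @param target Index of the queried alternative.
#' @return A probability in `[0, 1]`.
#' @examples
#' probability_estimate(response_prior(c(1, 1)), c(2, 0), 1) # 0.75
#' @export
probability_estimate <- function(prior, counts, target) {
  stopifnot(inherits(prior, "abs_response_prior"),
            length(counts) == prior$M, all(counts >= 0),
            target >= 1L, target <= prior$M)
  tot <- sum(prior$alphas) + sum(counts)
  if (tot <= 0) stop("no information: all-zero prior with no samples")
  (prior$alphas[target] + counts[target]) / tot
}

#' Adapt the response prior to the previous trial's feedback
#'
#' The prior is reset to a uniform Beta/Dirichlet(1, ..., 1) with one extra
#' pseudocount on whichever alternative the immediately preceding trial's
#' feedback marked correct; only that one trial is used, so the prior resets
#' rather than accumulates.  With no feedback (the first trial) the uniform
#' prior is returned unchanged.
#'
#' @param base An [response_prior()] (defines the number of alternatives).
#' @param correct Index of the previously correct alternative, or `NULL`.
#' @return The adapted `"abs_response_prior"`.
#' @examples
#' adapt_from_feedback(response_prior(c(1, 1)), 1) # Beta(2, 1)
#' @export
adapt_from_feedback <- function(base, correct = NULL) {
  stopifnot(inherits(base, "abs_response_prior"))
  a <- rep(1, base$M)
  if (!is.null(correct)) {
    stopifnot(correct >= 1L, correct <= base$M)
    a[correct] <- a[correct] + 1
  }
  response_prior(a)
}

#' Decision confidence at the moment of stopping
#'
#' The posterior-mean probability that the chosen alternative is correct,
#' given the evidence tallies at stopping.  For a binary choice with prior
#' Beta(i, j) this equals `(i + j + N + Delta) / (2 * (i + j + N))` where
#' `Delta` is the achieved pseudocount-inclusive evidence difference, so
#' confidence falls as more samples were needed to reach the threshold.
#'
#' @param prior An [response_prior()].
#' @param counts Evidence tallies at stopping.
#' @param chosen Index of the chosen alternative.
#' @return Confidence as a probability.
#' @examples
#' confidence_at_stop(response_prior(c(1, 1)), c(2, 0), 1)   # 0.75
#' confidence_at_stop(response_prior(c(1, 1)), c(51, 49), 1) # 52/102
#' @export
confidence_at_stop <- function(prior, counts, chosen) {
  probability_estimate(prior, counts, chosen)
}

#' Confidence for the chosen option in a multialternative choice
#'
#' With accumulated (pseudocount-inclusive) evidence `i > j > k ...` for the
#' ranked options and achieved max-minus-next difference `Delta = i - j`,
#' the confidence in the chosen option is `i / (i + j + k + ...)`, which can
#' equivalently be written as `Diff * i / Delta` with
#' `Diff = (i - j) / (i + j + k + ...)`.
#'
#' @param evidence Evidence totals per option, best first.
#' @param delta The achieved max-minus-next difference (must be positive and
#'   equal `evidence[1] - evidence[2]`).
#' @return Confidence as a probability.
#' @examples
#' confidence_multialt(c(5, 3, 2), delta = 2) # 0.5
#' @export
confidence_multialt <- function(evidence, delta) {
  stopifnot(is.numeric(evidence), length(evidence) >= 2L,
            all(diff(evidence) <= 0))
  if (delta <= 0) stop("achieved difference must be positive")
  stopifnot(isTRUE(all.equal(evidence[1] - evidence[2], delta)))
  evidence[1] / sum(evidence)
}

#' Predicted explicit-subadditivity bias
#'
#' When the probabilities of `m_prime` mutually exclusive components and of
#' their disjunction are each judged separately as binary events with a
#' symmetric Beta(`alpha0`, `alpha0`) prior and a fixed sample size `n`, the
#' expected excess of the summed component judgments over the disjunction
#' judgment is `(m_prime - 1) * alpha0 / (n + 2 * alpha0)`.  When the
#' components are mutually exhaustive (their disjunction is certain, so it is
#' not queried) the bias is `(m_prime - 2) * alpha0 / (n + 2 * alpha0)`,
#' which vanishes for binary complements.
#'
#' @param m_prime Number of component hypotheses (>= 1).
#' @param n Sample size per judgment.
#' @param alpha0 Symmetric prior pseudocount.
#' @param exhaustive Components exhaust the space (disjunction certain)?
#' @return The predicted bias.
#' @examples
#' subadditivity_bias(3, 5, 1)                      # 2/7
#' subadditivity_bias(2, 5, 1, exhaustive = TRUE)   # 0
#' @export
subadditivity_bias <- function(m_prime, n, alpha0, exhaustive = FALSE) {
  stopifnot(m_prime >= 1, alpha0 >= 0, n + 2 * alpha0 > 0)
  (m_prime - 1 - as.numeric(exhaustive)) * alpha0 / (n + 2 * alpha0)
}
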