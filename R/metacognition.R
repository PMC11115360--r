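#' Signal-detection discriminability (d-prime)
#'
#' `qnorm(hit_rate) - qnorm(fa_rate)`.
#'
#' @param hit_rate,fa_rate Rates strictly inside (0, 1); use
#'   [clamp_rate()] first when finite-sample rates can hit 0 or 1.
#' @return d-prime.
#' @examples
#' dprime(0.8413447, 0.1586553) # ~2
#' @export
dprime <- function(hit_rate, fa_rate) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Clamp a finite-sample rate away from 0 and 1
#'
#' The 1/(2n) correction: a rate computed from `n` trials is pulled into
#' `[1/(2n), 1 - 1/(2n)]` so the normal quantile stays finite.
#'
#' @param rate Observed proportion.
#' @param n Number of trials behind it.
#' @return Clamped rate.
#' @export
clamp_rate <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))

#' Type-1 d-prime from a trial table
#'
#' Treats `signal` as the "yes" stimulus class and response `signal` as the
#' "yes" response; rates get the 1/(2n) clamp.
#'
#' @param trials Data frame with columns `stimulus` and `response` holding
#'   alternative identifiers (two classes).
#' @param signal The identifier of the signal class (default: first sorted
#'   unique stimulus).
#' @return d-prime.
#' @export
dprime_from_trials <- function(trials, signal = NULL) {
  r <- type1_rates(trials, signal, criterion = -Inf)
  dprime(r$hit, r$fa)
}

type1_rates <- function(trials, signal = NULL, criterion = -Inf) {
  stopifnot(all(c("stimulus", "response") %in% names(trials)))
  if (is.null(signal)) signal <- sort(unique(trials$stimulus))[1]
  is_sig <- trials$stimulus == signal
  if (!any(is_sig) || all(is_sig)) stop("need trials from both classes")
  yes <- trials$response == signal &
    (if (is.finite(criterion)) trials$confidence >= criterion else TRUE)
  n_sig <- sum(is_sig); n_noise <- sum(!is_sig)
  list(hit = clamp_rate(sum(yes & is_sig) / n_sig, n_sig),
       fa = clamp_rate(sum(yes & !is_sig) / n_noise, n_noise),
       n_signal = n_sig, n_noise = n_noise)
}

#' Criterion-dependent meta-d-prime
#'
#' Recomputes hit and false-alarm rates counting only high-confidence signal
#' responses (confidence at or above the criterion) as the "yes" event, then
#' maps the rates through the normal quantile.  At a criterion at or below
#' the lowest confidence this reduces to ordinary d-prime.  When confidence
#' is built from small discrete sample tallies rather than Gaussian
#' evidence, this quantity falls below d-prime and decreases as the
#' criterion rises — apparent metacognitive inefficiency without any added
#' confidence noise.
#'
#' @param trials Data frame with columns `stimulus`, `response`,
#'   `confidence`.
#' @param criterion Confidence criterion c.
#' @param signal Signal-class identifier (default: first sorted unique
#'   stimulus).
#' @return meta-d-prime at the given criterion.
#' @export
meta_dprime <- function(trials, criterion, signal = NULL) {
  stopifnot("confidence" %in% names(trials))
  r <- type1_rates(trials, signal, criterion = criterion)
  dprime(r$hit, r$fa)
}

#' Metacognitive-efficiency curve over confidence criteria
#'
#' Evaluates [meta_dprime()] on the achievable confidence grid of the data
#' (or a supplied set of criteria) and returns the ratio to type-1 d-prime.
#'
#' @inheritParams meta_dprime
#' @param criteria Criteria to evaluate; default: the distinct confidence
#'   values observed.
#' @return Data frame with columns `criterion`, `meta_d`, `d`, `ratio`.
#' @export
metacog_curve <- function(trials, criteria = NULL, signal = NULL) {
  if (is.null(criteria)) criteria <- sort(unique(trials$confidence))
  d <- dprime_from_trials(trials, signal)
  meta <- vapply(criteria, function(c) meta_dprime(trials, c, signal), 0)
  data.frame(criterion = criteria, meta_d = meta, d = d, ratio = meta / d)
}
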