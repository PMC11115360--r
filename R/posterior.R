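#' Posterior distribution over fine-grained hypotheses
#'
#' A trial's target distribution: the posterior over specific candidate
#' answers (for example, the exact number of dots shown on screen) from which
#' the sampler draws hypotheses.  Two families are supported: a continuous
#' Gaussian, the default for numerosity-style tasks, and an arbitrary
#' tabulated distribution on a discrete grid.
#'
#' @param family `"gaussian"` or `"discrete_grid"`.
#' @param mean,sd Gaussian location and spread, in hypothesis units.
#' @param grid_values Strictly increasing hypothesis values (grid family).
#' @param grid_logmass Unnormalized log probabilities, one per grid value.
#' @return An object of class `"abs_posterior"`.
#' @examples
#' posterior_spec("gaussian", mean = 24, sd = 3)
#' posterior_spec("discrete_grid", grid_values = 1:3, grid_logmass = log(c(.2, .5, .3)))
#' @export
posterior_spec <- function(family = c("gaussian", "discrete_grid"),
                           mean = NULL, sd = NULL,
                           grid_values = NULL, grid_logmass = NULL) {
  family <- match.arg(family)
  if (family == "gaussian") {
    stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
              is.numeric(sd), length(sd) == 1L, sd > 0)
    spec <- list(family = family, mean = mean, sd = sd)
  } else {
    stopifnot(is.numeric(grid_values), is.numeric(grid_logmass),
              length(grid_values) == length(grid_logmass),
              length(grid_values) >= 1L,
              all(diff(grid_values) > 0))
    if (all(grid_logmass == -Inf)) stop("degenerate posterior: no mass")
    if (any(is.na(grid_logmass)) || any(grid_logmass == Inf))
      stop("grid_logmass must be finite or -Inf")
    lz <- logsumexp(grid_logmass)
    spec <- list(family = family, grid_values = as.numeric(grid_values),
                 grid_logmass = as.numeric(grid_logmass - lz),
                 grid_prob = exp(grid_logmass - lz))
  }
  structure(spec, class = "abs_posterior")
}

logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' @export
print.abs_posterior <- function(x, ...) {
  if (x$family == "gaussian") {
    cat(sprintf("Hypothesis posterior: Gaussian(mean = %g, sd = %g)\n",
                x$mean, x$sd))
  } else {
    cat(sprintf("Hypothesis posterior: discrete grid, %d values in [%g, %g]\n",
                length(x$grid_values), min(x$grid_values), max(x$grid_values)))
  }
  invisible(x)
}

#' Combine a prior and a likelihood on a common hypothesis grid
#'
#' Applies Bayes' rule cell by cell in log space: the posterior log mass is
#' `prior + likelihood - log Z`, with `log Z` the log marginal probability of
#' the stimulus.
#'
#' @param prior_logmass,likelihood_logmass Equal-length vectors of log masses
#'   (unnormalized; `-Inf` allowed for empty cells).
#' @param grid_values Optional hypothesis values; defaults to cell indices.
#' @return An `"abs_posterior"` on the discrete grid, with the log marginal
#'   stored in attribute `"logZ"`.
#' @examples
#' posterior_from_prior_likelihood(log(c(.5, .5)), log(c(.8, .2)))
#' @export
posterior_from_prior_likelihood <- function(prior_logmass, likelihood_logmass,
                                            grid_values = NULL) {
  if (length(prior_logmass) != length(likelihood_logmass))
    stop("prior and likelihood must have the same length")
  if (length(prior_logmass) < 1L) stop("empty hypothesis grid")
  joint <- prior_logmass + likelihood_logmass
  if (all(joint == -Inf)) stop("degenerate posterior: no mass")
  if (is.null(grid_values)) grid_values <- seq_along(joint)
  lz <- logsumexp(joint)
  spec <- posterior_spec("discrete_grid", grid_values = grid_values,
                         grid_logmass = joint - lz)
  attr(spec, "logZ") <- lz
  spec
}

#' Log density (or log mass) of a hypothesis posterior
#'
#' Local evaluation of the target, as used by the Metropolis acceptance rule;
#' only differences of log densities matter, so the Gaussian branch returns
#' the proper log density while grid values return normalized log mass.
#'
#' @param spec An [posterior_spec()] object.
#' @param h Hypothesis value(s).  For a grid posterior, `h` must lie on the
#'   grid.
#' @return Numeric vector of log densities.
#' @export
log_density <- function(spec, h) {
  stopifnot(inherits(spec, "abs_posterior"), is.numeric(h), all(is.finite(h)))
  if (spec$family == "gaussian")
    return(dnorm(h, spec$mean, spec$sd, log = TRUE))
  i <- match(h, spec$grid_values)
  if (anyNA(i)) stop("hypothesis value off the posterior grid")
  spec$grid_logmass[i]
}

#' Draw independent samples from a hypothesis posterior
#'
#' Exact i.i.d. draws, used for random sampler initialization and for the
#' direct-sampling model variant.
#'
#' @param spec An [posterior_spec()] object.
#' @param n Number of draws.
#' @return Numeric vector of hypothesis values.
#' @export
posterior_draw <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "abs_posterior"))
  if (spec$family == "gaussian") return(rnorm(n, spec$mean, spec$sd))
  spec$grid_values[sample.int(length(spec$grid_values), n, replace = TRUE,
                              prob = spec$grid_prob)]
}

#' Partition of the hypothesis space into response alternatives
#'
#' Cut points split the hypothesis axis into `length(boundaries) + 1`
#' half-open intervals `[b_k, b_{k+1})`; a hypothesis exactly on a boundary
#' belongs to the upper interval.  Each interval is one response alternative.
#'
#' @param boundaries Strictly increasing cut points, in hypothesis units.
#' @param labels Optional alternative labels (length `length(boundaries) + 1`).
#' @return An object of class `"abs_partition"`.
#' @examples
#' partition_spec(25, labels = c("lower", "greater"))
#' @export
partition_spec <- function(boundaries, labels = NULL) {
  stopifnot(is.numeric(boundaries), length(boundaries) >= 1L,
            all(is.finite(boundaries)), all(diff(boundaries) > 0))
  m <- length(boundaries) + 1L
  if (is.null(labels)) labels <- paste0("alt", seq_len(m))
  stopifnot(length(labels) == m)
  structure(list(boundaries = as.numeric(boundaries), n_alternatives = m,
                 labels = as.character(labels)),
            class = "abs_partition")
}

#' @export
print.abs_partition <- function(x, ...) {
  cat(sprintf("Hypothesis partition: %d alternatives, cuts at %s\n",
              x$n_alternatives, paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

#' Convert a hypothesis sample into a piece of categorical evidence
#'
#' Each sample supports exactly the alternative whose interval contains it:
#' with a single boundary at 25, a sampled count of 23 is evidence for
#' "fewer than 25" and 27 for "greater".
#'
#' @param partition An [partition_spec()] object.
#' @param h Hypothesis value(s).
#' @param as_index Return integer interval indices instead of labels.
#' @return Alternative labels (or indices), one per element of `h`.
#' @export
classify <- function(partition, h, as_index = FALSE) {
  stopifnot(inherits(partition, "abs_partition"), is.numeric(h),
            all(is.finite(h)))
  idx <- findInterval(h, partition$boundaries) + 1L
  if (as_index) idx else partition$labels[idx]
}

#' Read a tabulated posterior from a two-column CSV file
#'
#' @param path CSV with columns `value` and `unnormalized_mass`.
#' @return An `"abs_posterior"` on the discrete grid.
#' @export
read_grid_posterior <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("value", "unnormalized_mass") %in% names(d)))
  posterior_spec("discrete_grid", grid_values = d$value,
                 grid_logmass = log(d$unnormalized_mass))
}
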