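#' Periodogram and log-log spectral slope of a trial series
#'
#' Mean-detrends the series, computes the raw periodogram at the Fourier
#' frequencies k/N (k = 1 .. N/2, DC excluded), and fits an ordinary
#' least-squares line to log10 power versus log10 frequency.  The slope
#' classifies the series' serial structure: ~0 for white noise, ~-1 for
#' long-range (1/f) dependence, ~-2 for a random walk.
#'
#' @param series Numeric series of length >= 64 (e.g., trial-by-trial
#'   estimates or response times).
#' @param freq_range Optional `c(lo, hi)` band (cycles/trial) to restrict
#'   the slope fit.
#' @return An object of class `"abs_spectrum"`: `frequencies`, `power`,
#'   `slope`, `intercept`.
#' @export
power_spectrum <- function(series, freq_range = NULL) {
  stopifnot(is.numeric(series), all(is.finite(series)))
  n <- length(series)
  if (n < 64L) stop("series too short for spectral analysis (need >= 64)")
  x <- series - mean(series)
  if (all(x == 0)) stop("constant series has no spectrum")
  per <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  freq <- k / n
  pow <- per[k + 1L]
  keep <- pow > 0
  if (!is.null(freq_range))
    keep <- keep & freq >= freq_range[1] & freq <= freq_range[2]
  fit <- lm(log10(pow[keep]) ~ log10(freq[keep]))
  structure(list(frequencies = freq, power = pow,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "abs_spectrum")
}

#' @export
print.abs_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d frequencies, log-log slope %.3f (%s)\n",
              length(x$frequencies), x$slope, classify_noise(x$slope)))
  invisible(x)
}

#' @export
plot.abs_spectrum <- function(x, ...) {
  graphics::plot(log10(x$frequencies), log10(x$power),
                 xlab = "log10 frequency (cycles/trial)",
                 ylab = "log10 power", pch = 16, cex = 0.4, ...)
  graphics::abline(x$intercept, x$slope, col = 2, lwd = 2)
  invisible(x)
}

#' Classify a spectral slope as white, 1/f, or random-walk noise
#'
#' Long-range serial dependence (1/f noise) corresponds to slopes between
#' -1.5 and -0.5; near-zero slopes (|slope| < 0.25) are white; slopes at or
#' below -1.75 indicate a random walk; anything else is `"unclassified"`.
#'
#' @param slope Fitted log-log spectral slope.
#' @return One of `"one_over_f"`, `"white"`, `"random_walk"`,
#'   `"unclassified"`.
#' @export
classify_noise <- function(slope) {
  stopifnot(is.finite(slope))
  if (slope >= -1.5 && slope <= -0.5) return("one_over_f")
  if (abs(slope) < 0.25) return("white")
  if (slope <= -1.75) return("random_walk")
  "unclassified"
}
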