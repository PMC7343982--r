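#' Least-squares (Lomb-Scargle) spectral analysis
#'
#' The classic Scargle normalized periodogram of a mean-centered, unevenly
#' sampled series - the least-squares generalization of Fourier analysis.
#' At angular frequency `w`, with the phase offset `tau` defined by
#' `tan(2 w tau) = sum(sin 2 w t) / sum(cos 2 w t)`,
#' power is `[ (sum y_c cos w(t - tau))^2 / sum cos^2 w(t - tau) +`
#' `(sum y_c sin w(t - tau))^2 / sum sin^2 w(t - tau) ] / (2 s^2)` where
#' `y_c` is the centered series and `s^2` its sample variance. On evenly
#' spaced data this equals the classical periodogram at the Fourier
#' frequencies. Power is invariant to adding a constant to the values and
#' to translating the time axis.
#'
#' @param times Strictly increasing sampling times (e.g. non-reset
#'   normalized cycle days).
#' @param values Measure at each time.
#' @param min_period,max_period Period range (days) the frequency grid spans
#'   (defaults 2-56).
#' @param oversample Frequency oversampling factor (default 8): grid spacing
#'   is `1 / (oversample * span(times))`.
#' @param min_points Minimum grid size (default 400).
#' @param freq Optional explicit frequency grid (cycles/day, strictly
#'   increasing); overrides the period range and oversampling.
#' @return Object of class `"cyclo_spectrum"`: tibble with `frequency`
#'   (cycles/day), `period` (days) and `power`, plus attributes `n` and
#'   `times_span`. A constant series has zero power everywhere.
#' @export
#' @examples
#' t <- 1:70
#' sp <- lssa(t, sin(2 * pi * t / 28))
#' peak_periods(sp, 1)
lssa <- function(times, values, min_period = 2, max_period = 56,
                 oversample = 8, min_points = 400, freq = NULL) {
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 8) abort("need at least 8 points for spectral analysis")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  span <- diff(range(times))
  if (is.null(freq)) {
    df <- 1 / (oversample * span)
    freq <- seq(1 / max_period, 1 / min_period, by = df)
    if (length(freq) < min_points) {
      freq <- seq(1 / max_period, 1 / min_period, length.out = min_points)
    }
  }
  y <- values - mean(values)
  s2 <- var(values)
  if (!is.finite(s2) || s2 <= 0) {
    power <- rep(0, length(freq))
  } else {
    nt <- length(times)
    power <- vapply(freq, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
      ct <- cos(w * (times - tau))
      st <- sin(w * (times - tau))
      css <- sum(ct^2)
      sss <- sum(st^2)
      p <- 0
      # a vanishing basis norm (e.g. the sin term at the Nyquist frequency of
      # integer sampling) carries no information; its component is dropped
      if (css > nt * 1e-12) p <- p + sum(y * ct)^2 / css
      if (sss > nt * 1e-12) p <- p + sum(y * st)^2 / sss
      p / (2 * s2)
    }, numeric(1))
  }
  out <- tibble::tibble(frequency = freq, period = 1 / freq, power = power)
  attr(out, "n") <- length(times)
  attr(out, "times_span") <- span
  class(out) <- c("cyclo_spectrum", class(out))
  out
}

#' Extract dominant periods from a spectrum
#'
#' Local maxima of the periodogram ranked by power; the period of a peak is
#' the inverse of its frequency, rounded to 0.1 day.
#'
#' @param spectrum A [lssa()] result.
#' @param k Number of top peaks to return (default 2; fewer if the spectrum
#'   has fewer local maxima).
#' @return Tibble with `period` (days) and `power`, strongest first; empty
#'   for an all-zero spectrum.
#' @export
peak_periods <- function(spectrum, k = 2) {
  p <- spectrum$power
  if (length(p) == 0 || all(p == 0)) {
    return(tibble::tibble(period = double(), power = double()))
  }
  n <- length(p)
  is_peak <- p > dplyr::lag(p, default = -Inf) &
    p > dplyr::lead(p, default = -Inf)
  idx <- which(is_peak)
  idx <- idx[order(p[idx], decreasing = TRUE)]
  idx <- head(idx, k)
  tibble::tibble(period = round(spectrum$period[idx], 1), power = p[idx])
}
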