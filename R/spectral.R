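# Morlet wavelet time-frequency decomposition on a log-spaced frequency grid.

#' Log-spaced (octave-fraction) frequency grid
#'
#' Builds the analysis grid `f_min * 2^(k * step)` for
#' `k = 0 ... floor(log2(f_max / f_min) / step)`; the upper endpoint is
#' included when it falls exactly on the grid. The default quarter-octave
#' grid from 2^1.5 (~2.83) to 128 Hz has 23 frequencies.
#'
#' @param f_min,f_max Grid limits in Hz (`0 < f_min < f_max`).
#' @param step Grid step in octaves.
#' @param bandwidth Wavelet bandwidth in octaves (one spectral SD), carried as
#'   an attribute for downstream transforms.
#' @return Numeric vector of center frequencies (Hz) of class
#'   `"frequency_grid"` with attributes `step` and `bandwidth`.
#' @examples
#' length(frequency_grid())  # 23
#' frequency_grid(4, 8, step = 1)
#' @export
frequency_grid <- function(f_min = 2^1.5, f_max = 128, step = 0.25,
                           bandwidth = 0.5) {
  if (!is.numeric(f_min) || f_min <= 0) stop("f_min must be positive")
  if (f_max < f_min) stop("f_max must not be below f_min")
  if (step <= 0) stop("step must be positive (octaves)")
  k <- 0:floor(log2(f_max / f_min) / step + 1e-9)
  f <- f_min * 2^(k * step)
  structure(f, step = step, bandwidth = bandwidth, class = "frequency_grid")
}

#' Wavelet standard deviations for a center frequency
#'
#' The bandwidth `b` (in octaves) is interpreted symmetrically in log
#' frequency: one spectral SD spans `[f * 2^(-b/2), f * 2^(+b/2)]`, giving
#' `sigma_f = f * (2^(b/2) - 2^(-b/2)) / 2` and `sigma_t = 1 / (2 pi sigma_f)`.
#'
#' @param frequency Center frequency in Hz.
#' @param bandwidth Bandwidth in octaves (one spectral SD).
#' @return List with `sigma_f` (Hz) and `sigma_t` (seconds).
#' @export
morlet_sd <- function(frequency, bandwidth = 0.5) {
  sigma_f <- frequency * (2^(bandwidth / 2) - 2^(-bandwidth / 2)) / 2
  list(sigma_f = sigma_f, sigma_t = 1 / (2 * pi * sigma_f))
}

# FFT-based complex "valid" correlation of each row of x with kernel kern.
# Returns matrix n_sources x (T - M + 1); column t corresponds to the kernel
# centered on sample t + (M-1)/2 of the input.
morlet_filter <- function(x, kern) {
  nT <- ncol(x)
  M <- length(kern)
  nfft <- 2^ceiling(log2(nT + M - 1))
  kf <- stats::fft(c(kern, complex(real = rep(0, nfft - M))))
  nvalid <- nT - M + 1
  out <- matrix(0i, nrow(x), nvalid)
  for (r in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[r, ], rep(0, nfft - nT)))
    full <- stats::fft(xf * kf, inverse = TRUE) / nfft
    # with kern conjugate-reversed, full[t + M - 1] = sum_j x[t - 1 + j] kernel[j]
    out[r, ] <- full[M:nT]
  }
  out
}

#' Morlet wavelet transform of multichannel signals
#'
#' Convolves each source signal with a Gaussian-envelope complex exponential
#' at one center frequency and returns complex coefficients sampled every half
#' temporal SD. The kernel is truncated at 6 temporal SDs (keeping truncation
#' sidelobes below the Gaussian transfer function out to one octave) and only
#' time steps whose full kernel support lies inside the recording are emitted,
#' so edge transients never enter downstream coupling estimates.
#'
#' The kernel is amplitude-normalized: a unit-amplitude sinusoid at the center
#' frequency yields coefficients of magnitude ~1.
#'
#' @param x Numeric matrix (sources x samples) or vector.
#' @param srate Sampling rate in Hz.
#' @param frequency Wavelet center frequency in Hz.
#' @param bandwidth Bandwidth in octaves (one spectral SD), default 0.5.
#' @return A `"spectral_frame"`: complex matrix (sources x time steps) with
#'   attributes `frequency`, `step_seconds`, `times` (seconds, kernel centers)
#'   and `srate`.
#' @export
morlet_transform <- function(x, srate, frequency, bandwidth = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  nT <- ncol(x)
  sds <- morlet_sd(frequency, bandwidth)
  sigma_t <- sds$sigma_t
  Lh <- ceiling(6 * sigma_t * srate)
  min_len <- ceiling(6 * sigma_t * srate)
  if (nT < max(min_len, 2 * Lh + 2)) {
    stop(sprintf(
      "signal too short for %.3g Hz wavelet: %d samples given, >= %d required",
      frequency, nT, max(min_len, 2 * Lh + 2)))
  }
  u <- (-Lh:Lh) / srate
  g <- exp(-u^2 / (2 * sigma_t^2))
  # correlation with g(u) exp(+i 2 pi f u): realised as convolution with the
  # conjugate-reversed kernel (g symmetric)
  kern <- rev(Conj(g * exp(2i * pi * frequency * u))) * (2 / sum(g))
  coef <- morlet_filter(x, kern)
  step_samples <- max(1L, round(sigma_t / 2 * srate))
  centers <- seq(1L, ncol(coef), by = step_samples)  # center = sample Lh+center
  coef <- coef[, centers, drop = FALSE]
  structure(coef,
            frequency = frequency,
            step_seconds = step_samples / srate,
            times = (Lh + centers - 1) / srate,
            srate = srate,
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf(
    "<spectral_frame> %.4g Hz, %d sources x %d steps (step %.4g s)\n",
    attr(x, "frequency"), nrow(x), ncol(x), attr(x, "step_seconds")))
  invisible(x)
}
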