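#' Synthetic EEG as mean membrane voltage
#'
#' The field-potential surrogate: the per-time-step arithmetic mean of the
#' simulated membrane voltages. The clamped driver is excluded by default
#' (its trace is the exogenous noise source, not neural output). The burn-in
#' interval is dropped.
#'
#' @param traces a `critnet_traces`.
#' @param include_driver also average the clamped node's voltage.
#' @param burn_in ms dropped from the start (default: the run's configured
#'   burn-in).
#' @return object of class `critnet_eeg`: `values` (mV), `dt` (ms).
#' @export
synthetic_eeg <- function(traces, include_driver = FALSE, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- traces$config$burn_in
  drop <- round(burn_in / traces$dt)
  n_steps <- ncol(traces$voltages)
  if (drop >= n_steps) stop("burn_in must be shorter than the trace")
  V <- traces$voltages[, (drop + 1L):n_steps, drop = FALSE]
  if (!include_driver) V <- V[-(traces$clamped_node + 1L), , drop = FALSE]
  structure(list(values = colMeans(V), dt = traces$dt),
            class = "critnet_eeg")
}

#' @export
print.critnet_eeg <- function(x, ...) {
  cat(sprintf("synthetic EEG: %d samples at %g kHz (%.3g s)\n",
              length(x$values), 1 / x$dt, length(x$values) * x$dt / 1000))
  invisible(x)
}

as_eeg <- function(x, dt) {
  if (inherits(x, "critnet_eeg")) x
  else structure(list(values = as.numeric(x), dt = dt), class = "critnet_eeg")
}

# periodic Hann window
hann <- function(L) 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L))

#' Welch power spectral density of the synthetic EEG
#'
#' Mean-removed, Hann-windowed, 50%-overlapping averaged periodogram,
#' normalized as a one-sided density: the integral of power over frequency
#' approximates the variance of the mean-removed series (up to windowing
#' loss). When `fit_band` is supplied the high-frequency log-log slope over
#' that band is fitted and stored.
#'
#' @param eeg a `critnet_eeg` (or numeric vector with `dt` supplied).
#' @param segment_sec Welch segment length in seconds (default 1).
#' @param overlap fractional overlap between segments in \[0, 1) (default
#'   0.5).
#' @param fit_band optional `c(f_lo, f_hi)` Hz band for the power-law slope
#'   (default 100–1000 Hz; set NULL to skip).
#' @param dt sample interval in ms when `eeg` is a bare vector.
#' @return object of class `critnet_psd`: `frequencies` (Hz, DC excluded),
#'   `power`, `slope`, `fit_band`, `segment_length`, `n_segments`,
#'   `window = "hann"`, `overlap`.
#' @export
compute_psd <- function(eeg, segment_sec = 1, overlap = 0.5,
                        fit_band = c(100, 1000), dt = NULL) {
  eeg <- as_eeg(eeg, dt)
  fs <- 1000 / eeg$dt
  L <- round(segment_sec * fs)
  x <- eeg$values - mean(eeg$values)
  if (length(x) < 2 * L)
    stop("series too short for Welch PSD: need at least ", 2 * L,
         " samples (2 segments), have ", length(x))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- hann(L)
  scale <- fs * sum(w^2)
  acc <- numeric(L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * scale)
  # one-sided: bins 2..floor(L/2)+1; double all but DC and (even-L) Nyquist
  half <- floor(L / 2)
  idx <- 2:(half + 1)
  p1 <- pxx[idx] * 2
  if (L %% 2 == 0) p1[length(p1)] <- p1[length(p1)] / 2
  freqs <- (idx - 1) * fs / L
  out <- structure(
    list(frequencies = freqs, power = p1, slope = NA_real_,
         fit_band = fit_band, segment_length = L,
         n_segments = length(starts), window = "hann", overlap = overlap),
    class = "critnet_psd")
  if (!is.null(fit_band))
    out$slope <- highfreq_slope(out, fit_band[1], fit_band[2])
  out
}

#' @export
print.critnet_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins to %.4g Hz (%d segments of %d)",
              length(x$frequencies), max(x$frequencies), x$n_segments,
              x$segment_length))
  if (is.finite(x$slope))
    cat(sprintf("; slope %.3g over %g-%g Hz", x$slope,
                x$fit_band[1], x$fit_band[2]))
  cat("\n")
  invisible(x)
}

#' High-frequency power-law slope of a spectrum
#'
#' Least-squares slope of log power against log frequency over
#' `[f_lo, f_hi]` — the exponent of the spectral power law in that band
#' (e.g. -2 for Brownian noise, 0 for white noise).
#'
#' @param spec a `critnet_psd`.
#' @param f_lo,f_hi band edges, Hz; the band must contain at least 10 bins
#'   with positive power.
#' @return the fitted slope (dimensionless).
#' @export
highfreq_slope <- function(spec, f_lo = 100, f_hi = 1000) {
  keep <- spec$frequencies >= f_lo & spec$frequencies <= f_hi &
    spec$power > 0
  if (sum(keep) < 10)
    stop("need >= 10 positive-power bins in [", f_lo, ", ", f_hi,
         "] Hz, have ", sum(keep))
  stats::coef(stats::lm(log(spec$power[keep]) ~
                          log(spec$frequencies[keep])))[[2]]
}

#' Morlet wavelet scalogram
#'
#' Continuous wavelet transform of the mean-removed signal with an analytic
#' Morlet mother wavelet (center-frequency parameter `omega0`, default 6),
#' evaluated by frequency-domain multiplication at `n_freqs` log-spaced
#' analysis frequencies. Returns the coefficient magnitudes — time-frequency
#' energy localization with the wavelet's characteristic resolution
#' trade-off (sharp frequency at low f, sharp time at high f).
#'
#' @param eeg a `critnet_eeg` (or numeric vector with `dt`).
#' @param f_min,f_max analysis band, Hz; `f_max` must not exceed Nyquist.
#' @param n_freqs number of log-spaced frequencies (>= 2).
#' @param omega0 Morlet center-frequency parameter.
#' @param dt sample interval, ms, when `eeg` is a bare vector.
#' @return object of class `critnet_scalogram`: `magnitude`
#'   (`n_freqs x n_samples`), `frequencies` (Hz, increasing), `wavelet`
#'   descriptor string.
#' @export
compute_scalogram <- function(eeg, f_min = 1, f_max = 500, n_freqs = 64,
                              omega0 = 6, dt = NULL) {
  eeg <- as_eeg(eeg, dt)
  fs <- 1000 / eeg$dt
  if (f_max > fs / 2) stop("f_max exceeds Nyquist (", fs / 2, " Hz)")
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  if (n_freqs < 2) stop("n_freqs must be >= 2")
  x <- eeg$values - mean(eeg$values)
  N <- length(x)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  omega <- 2 * pi * fs * c(seq(0, floor(N / 2)),
                           seq(floor(N / 2) + 1, N - 1) - N) / N
  xf <- stats::fft(x)
  mag <- matrix(0, n_freqs, N)
  for (j in seq_len(n_freqs)) {
    scale_j <- omega0 / (2 * pi * freqs[j])
    psi <- numeric(N)
    pos <- omega > 0
    psi[pos] <- exp(-0.5 * (scale_j * omega[pos] - omega0)^2)
    wt <- stats::fft(xf * psi * sqrt(scale_j), inverse = TRUE) / N
    mag[j, ] <- Mod(wt)
  }
  structure(list(magnitude = mag, frequencies = freqs,
                 wavelet = sprintf("analytic Morlet (omega0 = %g)", omega0)),
            class = "critnet_scalogram")
}

#' @export
print.critnet_scalogram <- function(x, ...) {
  cat(sprintf("scalogram: %d frequencies (%.3g-%.4g Hz) x %d samples, %s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              ncol(x$magnitude), x$wavelet))
  invisible(x)
}
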