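#' Design a Butterworth bandpass filter as second-order sections
#'
#' Designs an order-\code{order} Butterworth bandpass prototype (so the
#' polynomial order of the full transfer function is \code{2 * order}, the
#' convention used by Matlab's \code{butter(n, [w1 w2])}). The filter is
#' returned as a cascade of biquad (second-order) sections rather than a
#' single direct-form polynomial: at order 20 the direct-form coefficients
#' are numerically degenerate, while the cascaded realization is stable
#' because every section is individually stable.
#'
#' The design path is fully analytic: closed-form analog lowpass prototype
#' poles, algebraic lowpass-to-bandpass transformation of each pole, and a
#' bilinear transform with frequency prewarping. The overall gain is fixed
#' so that the magnitude response is exactly 1 at the (warped) band center,
#' and is distributed evenly across sections to keep intermediate signals
#' well scaled.
#'
#' @param lowHz,highHz band edges in Hz; \code{0 < lowHz < highHz < rate/2}.
#' @param rate sampling rate in Hz.
#' @param order prototype order (default 20).
#' @return An object of class \code{ButterSos}: a list with elements
#'   \code{sos} (n x 6 matrix of b0,b1,b2,a0,a1,a2 per section),
#'   \code{lowHz}, \code{highHz}, \code{rate}, \code{order}.
#' @seealso [filterResponse()], [sosFiltfilt()], [bandpassFilter()]
#' @export
butterBandpass <- function(lowHz, highHz, rate, order = 20) {
  if (!is.numeric(lowHz) || !is.numeric(highHz) || !is.numeric(rate))
    stop("band edges and rate must be numeric")
  if (lowHz <= 0 || highHz <= lowHz)
    stop("need 0 < lowHz < highHz")
  if (highHz >= rate / 2)
    stop("band edge ", highHz, " Hz is at or above the Nyquist frequency ",
         rate / 2, " Hz")
  fs2 <- 2 * rate
  W1 <- fs2 * tan(pi * lowHz / rate)
  W2 <- fs2 * tan(pi * highHz / rate)
  W0 <- sqrt(W1 * W2)
  B <- W2 - W1

  ## analog Butterworth lowpass prototype poles on the unit circle, Re < 0
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  ## lowpass -> bandpass: each prototype pole yields the two roots of
  ## s^2 - B p s + W0^2 = 0
  half <- B * p / 2
  d <- sqrt(half^2 - W0^2)
  sp <- c(half + d, half - d)
  ## bilinear transform
  zp <- (1 + sp / fs2) / (1 - sp / fs2)

  ## group poles into conjugate pairs (order even and band proper => all
  ## poles strictly complex; pair any numerically-real stragglers together)
  tol <- 1e-9
  up <- zp[Im(zp) > tol]
  re <- sort(Re(zp[abs(Im(zp)) <= tol]))
  if (length(up) * 2 + length(re) != 2 * order || length(re) %% 2 != 0)
    stop("internal pole-pairing failure in Butterworth design")
  sos <- matrix(0, nrow = order, ncol = 6)
  i <- 0L
  for (z in up) {
    i <- i + 1L
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(z), Mod(z)^2)
  }
  while (length(re) >= 2) {
    i <- i + 1L
    r1 <- re[1]; r2 <- re[2]; re <- re[-(1:2)]
    sos[i, ] <- c(1, 0, -1, 1, -(r1 + r2), r1 * r2)
  }

  filt <- structure(list(sos = sos, lowHz = lowHz, highHz = highHz,
                         rate = rate, order = order),
                    class = "ButterSos")
  ## normalize: |H| = 1 at the warped center frequency
  fc <- atan(W0 / fs2) * rate / pi
  g <- 1 / Mod(filterResponse(filt, fc))
  filt$sos[, 1:3] <- filt$sos[, 1:3] * g^(1 / order)
  filt
}

#' Complex frequency response of a second-order-section filter
#'
#' Evaluates the single-pass transfer function analytically at the given
#' frequencies. Note that zero-phase filtering ([sosFiltfilt()]) applies
#' the filter twice, so its magnitude response is \code{Mod(H)^2}.
#'
#' @param filt a \code{ButterSos} object from [butterBandpass()].
#' @param freqHz numeric vector of frequencies (Hz).
#' @return complex vector of the same length as \code{freqHz}.
#' @export
filterResponse <- function(filt, freqHz) {
  zi <- exp(-1i * 2 * pi * freqHz / filt$rate)  # z^-1
  resp <- rep(1 + 0i, length(freqHz))
  for (s in seq_len(nrow(filt$sos))) {
    b <- filt$sos[s, 1:3]
    a <- filt$sos[s, 4:6]
    resp <- resp * (b[1] + b[2] * zi + b[3] * zi^2) /
      (a[1] + a[2] * zi + a[3] * zi^2)
  }
  resp
}

## single forward pass through the section cascade
sosApply <- function(filt, x) {
  for (s in seq_len(nrow(filt$sos))) {
    x <- as.numeric(signal::filter(filt$sos[s, 1:3], filt$sos[s, 4:6], x))
  }
  x
}

#' Zero-phase (forward-backward) filtering through a section cascade
#'
#' Applies the filter forward and then backward, cancelling the phase
#' response. The signal is extended at both ends by odd reflection before
#' filtering to reduce edge transients; the extension is discarded.
#'
#' @param filt a \code{ButterSos} object.
#' @param x numeric signal.
#' @return filtered signal, same length as \code{x}.
#' @export
sosFiltfilt <- function(filt, x) {
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  npad <- min(n - 1, 3L * ceiling(filt$rate / filt$lowHz))
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- c(pre, x, post)
  y <- sosApply(filt, y)
  y <- rev(sosApply(filt, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Bandpass-filter a signal with a zero-phase Butterworth filter
#'
#' @param x numeric signal (finite values).
#' @param band a [BandSpec-class] object or numeric \code{c(low, high)} in Hz.
#' @param rate sampling rate (Hz).
#' @param order Butterworth prototype order (default 20).
#' @return filtered signal, same length as \code{x}.
#' @examples
#' x <- cos(2 * pi * 10 * seq(0, 5, by = 1 / 2000))
#' y <- bandpassFilter(x, bandSpec("theta", 6, 14), rate = 2000)
#' @export
bandpassFilter <- function(x, band, rate, order = 20) {
  if (!all(is.finite(x)))
    stop("signal contains non-finite samples")
  band <- as_band(band)
  filt <- butterBandpass(band@lowHz, band@highHz, rate, order)
  sosFiltfilt(filt, x)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT-based construction of the analytic signal \eqn{x + i\,\hat x}. The
#' complex angle follows the cosine convention: for \eqn{x = \cos(\omega t)}
#' the phase is 0 at the waveform maximum.
#'
#' @param x numeric signal.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  ## keep FFT lengths 2-3-5-smooth; reflect-pad the tail and truncate after
  np <- stats::nextn(n, c(2, 3, 5))
  if (np != n) {
    ext <- np - n
    refl <- 2 * x[n] - x[seq(n - 1, max(1, n - ext))]
    refl <- rep(refl, length.out = ext)
    ## crossfade the extension back to x[1] so the periodic (FFT) view of
    ## the signal stays continuous at the wrap-around
    w <- seq_len(ext) / (ext + 1)
    x <- c(x, (1 - w) * refl + w * x[1])
    return(analyticSignal(x)[seq_len(n)])
  }
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope of a band pair
#'
#' Computes the Hilbert phase of the low-frequency (carrier) band and the
#' Hilbert amplitude envelope of the high-frequency band. Phase is in
#' degrees in [0, 360) with 0 at the carrier waveform maximum.
#'
#' @param filteredLow band-passed carrier signal (e.g. theta).
#' @param filteredHigh band-passed fast signal (e.g. high gamma).
#' @return list with elements \code{phaseDeg} and \code{envelope}.
#' @export
phaseEnvelope <- function(filteredLow, filteredHigh) {
  if (length(filteredLow) != length(filteredHigh))
    stop("low- and high-band signals must have the same length")
  if (max(abs(filteredLow)) < 1e-12)
    stop("low-band signal is (near) zero everywhere: phase is degenerate")
  zl <- analyticSignal(filteredLow)
  zh <- analyticSignal(filteredHigh)
  list(phaseDeg = wrap360(Arg(zl) * 180 / pi),
       envelope = Mod(zh))
}
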