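# IIR filter design and application.
#
# No DSP package is assumed: the band-pass Butterworth is designed from the
# analog prototype (poles on the unit left half-circle), transformed
# lowpass -> bandpass in s, and discretised by the bilinear transform with
# frequency prewarping -- the same construction as MATLAB's butter() and
# scipy.signal.butter. Filtering itself runs through stats::filter (C code):
# a causal direct-form pass, or a forward-backward (zero-phase) pass with
# odd-reflection edge padding.

# polynomial coefficients (descending powers) from roots, kept complex
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Design a Butterworth band-pass filter
#'
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order prototype order `n`; the resulting band-pass has `2n` poles
#'   (the MATLAB `butter(n, c(low, high)/(fs/2))` convention, so the default
#'   `order = 4` is the conventional "fourth-order band-pass").
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`), class `"iir_filter"`.
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (!(low > 0 && low < high)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (high >= fs / 2) {
    stop("high edge must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  n <- as.integer(order)
  stopifnot(n >= 1)
  # analog prototype poles (Butterworth, unit cutoff)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each prototype pole p yields the two roots of
  # s^2 - (bw * p) s + w0^2 = 0
  bp <- bw * p_lp
  disc <- sqrt(bp^2 / 4 - w0^2)
  p_bp <- c(bp / 2 + disc, bp / 2 - disc)
  # bilinear transform z = (2fs + s) / (2fs - s)
  fs2 <- 2 * fs
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  # band-pass zeros: n at s = 0 (z = 1) and n at s = Inf (z = -1)
  z_z <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(z_z))
  # unity gain at the (warped) centre frequency
  wc <- 2 * atan(w0 / fs2)
  resp <- function(coef) sum(coef * exp(-1i * wc * (seq_along(coef) - 1)))
  gain <- abs(resp(a) / resp(b))
  structure(list(b = b * gain, a = a, fs = fs, band = c(low, high),
                 order = n),
            class = "iir_filter")
}

# single causal IIR pass, zero initial conditions (C-speed via stats::filter)
iir_filter_causal <- function(x, flt) {
  b <- flt$b
  a <- flt$a
  nb <- length(b)
  # moving-average part with zero-padded history
  xp <- c(numeric(nb - 1), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    y <- stats::filter(ma, -a[-1], method = "recursive")
    as.numeric(y)
  } else {
    ma
  }
}

#' Apply an IIR filter to a numeric signal
#'
#' @param x numeric vector.
#' @param flt a filter from [butter_bandpass()].
#' @param zero_phase if `TRUE` (offline mode) the filter is applied
#'   forward-backward with odd-reflection edge padding, giving zero phase
#'   distortion; if `FALSE` (real-time mode) a single causal pass is used.
#' @return filtered numeric vector, same length as `x`.
#' @export
apply_filter <- function(x, flt, zero_phase = TRUE) {
  stopifnot(inherits(flt, "iir_filter"), is.numeric(x))
  if (!zero_phase) return(iir_filter_causal(x, flt))
  n <- length(x)
  # reflection long enough for the low corner's transient to die out
  pad <- min(n - 1L, max(3L * (max(length(flt$a), length(flt$b)) - 1L),
                         as.integer(flt$fs)))
  if (pad < 1L) stop("signal too short for zero-phase filtering", call. = FALSE)
  # odd reflection about the end points
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter_causal(xe, flt)
  y <- rev(iir_filter_causal(rev(y), flt))
  y[(pad + 1):(pad + n)]
}
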