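#' Moving-average filter
#'
#' The simplest low-pass filter: each output sample is the mean of the
#' `M + 1` most recent input samples (causal variant,
#' \eqn{y_n = \frac{1}{M+1}\sum_{k=0}^{M} x_{n-k}}) or of a window of
#' `M + 1` samples centred on the current one (non-causal variant). At the
#' sequence edges the window shrinks to the available samples, so the output
#' has the same length as the input. The non-causal variant needs an odd
#' window; an even `M + 1` is incremented with a message.
#'
#' @param x numeric sample sequence.
#' @param M filter order (window length minus one); `M = 0` is the identity.
#' @param causal logical; `TRUE` for the causal variant.
#' @return Filtered sequence, same length as `x`.
#' @seealso [blocking_average()], [fir_apply()]
#' @export
moving_average <- function(x, M, causal = TRUE) {
  if (!is.numeric(M) || length(M) != 1L || M < 0 || M != round(M))
    stop_trapcal("order M must be a non-negative integer", "parameter_error")
  n <- length(x)
  if (n < 1L) stop_trapcal("input sequence is empty", "parameter_error")
  if (M == 0) return(as.numeric(x))
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  if (causal) {
    lo <- pmax(1L, idx - M)
    (cs[idx + 1L] - cs[lo]) / (idx - lo + 1L)
  } else {
    if ((M + 1L) %% 2L == 0L) {
      message("non-causal moving average needs an odd window; using M = ", M + 1L)
      M <- M + 1L
    }
    h <- M %/% 2L
    lo <- pmax(1L, idx - h)
    hi <- pmin(n, idx + h)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Blocking (block-mean) average
#'
#' Replaces each non-overlapping block of `window` consecutive samples by its
#' mean, compressing the record by the block length and dividing the
#' effective sampling rate by `window`. Trailing samples that do not fill a
#' complete block are dropped.
#'
#' @param x numeric sample sequence.
#' @param window block length (samples), `>= 1` and `<= length(x)`.
#' @return Numeric vector of length `floor(length(x)/window)`.
#' @examples
#' blocking_average(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
blocking_average <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window))
    stop_trapcal("window must be a positive integer", "parameter_error")
  if (window > length(x))
    stop_trapcal("window exceeds the number of samples", "parameter_error")
  nb <- length(x) %/% window
  if (window == 1) return(as.numeric(x[seq_len(nb)]))
  colMeans(matrix(x[seq_len(nb * window)], nrow = window))
}

#' Digital filter specification
#'
#' Container for the coefficients of an FIR or IIR difference equation
#' \eqn{y_n = \sum_k b_k x_{n-k} - \sum_l a_l y_{n-l}} together with the
#' design metadata (kind, cutoff, band). `a` is empty for FIR filters.
#'
#' @param kind one of `"moving_average"`, `"blocking"`, `"fir"`, `"iir"`.
#' @param b numerator (feed-forward) coefficients b0..bM.
#' @param a denominator (feedback) coefficients a1..aN; empty for FIR.
#' @param causal logical.
#' @param cutoff design cutoff frequency (Hz), if designed.
#' @param band `"low"`, `"high"`, `"pass"` or `"stop"`.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("fir", "iir", "moving_average", "blocking"),
                        b, a = numeric(), causal = TRUE,
                        cutoff = NA_real_, band = "low") {
  kind <- match.arg(kind)
  if (length(b) < 1L) stop_trapcal("coefficient vector b is empty", "parameter_error")
  structure(list(kind = kind, b = as.numeric(b), a = as.numeric(a),
                 causal = causal, cutoff = cutoff, band = band),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("%s filter: %d feed-forward, %d feedback coefficient(s)%s\n",
              toupper(x$kind), length(x$b), length(x$a),
              if (!is.na(x$cutoff)) sprintf(", %s cutoff %g Hz", x$band, x$cutoff)
              else ""))
  invisible(x)
}

#' Design a windowed-sinc FIR filter
#'
#' Hamming-windowed inversion of the ideal frequency response (the standard
#' `fir1` design), giving a linear-phase low-pass with unit DC gain; high-,
#' band-pass and band-stop variants follow by the usual spectral
#' transformations. For band-pass/stop designs `cutoff` takes the two band
#' edges.
#'
#' @param cutoff cutoff frequency in Hz (two values for `"pass"`/`"stop"`);
#'   must lie strictly below the Nyquist frequency `fs/2`.
#' @param order filter order M (the filter has `M + 1` taps).
#' @param fs sampling frequency (Hz).
#' @param band one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return A [filter_spec()] of kind `"fir"`.
#' @export
design_fir_lowpass <- function(cutoff, order, fs,
                               band = c("low", "high", "pass", "stop")) {
  band <- match.arg(band)
  check_positive_scalar(fs, "fs")
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order))
    stop_trapcal("order must be a positive integer", "parameter_error")
  if (any(!is.finite(cutoff)) || any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop_trapcal("cutoff must lie strictly between 0 and the Nyquist frequency",
                 "parameter_error")
  if (band %in% c("pass", "stop") && length(cutoff) != 2L)
    stop_trapcal("band-pass/stop design needs two cutoff frequencies",
                 "parameter_error")
  if (band %in% c("high", "stop") && order %% 2L == 1L)
    order <- order + 1L  # high/stop need even order for a usable linear-phase design
  b <- as.numeric(unclass(signal::fir1(order, cutoff / (fs / 2), type = band)))
  if (band == "low") b <- b / sum(b)   # exact unit DC gain
  filter_spec("fir", b = b, causal = TRUE,
              cutoff = cutoff[1L], band = band)
}

#' Apply an FIR filter
#'
#' Direct evaluation of the FIR difference equation
#' \eqn{y_n = \sum_{k=0}^{M} b_k x_{n-k}}. Samples before the start of the
#' record are taken as zero, so the first `M` output samples are a start-up
#' transient; output length equals input length. The non-causal variant
#' centres the (odd-length) impulse response on the current sample.
#'
#' @param x numeric sample sequence.
#' @param spec a [filter_spec()] (or plain numeric vector of b coefficients).
#' @param causal logical.
#' @return Filtered sequence, same length as `x`.
#' @export
fir_apply <- function(x, spec, causal = TRUE) {
  b <- if (inherits(spec, "filter_spec")) spec$b else as.numeric(spec)
  if (length(b) < 1L) stop_trapcal("coefficient vector b is empty", "parameter_error")
  n <- length(x)
  M <- length(b) - 1L
  if (causal) {
    y <- stats::filter(c(rep(0, M), x), b, method = "convolution", sides = 1L)
    as.numeric(y[(M + 1L):(M + n)])
  } else {
    if (length(b) %% 2L == 0L)
      stop_trapcal("non-causal application needs an odd number of taps",
                   "parameter_error")
    h <- M %/% 2L
    y <- stats::filter(c(rep(0, h), x, rep(0, h)), b, method = "convolution",
                       sides = 1L)
    as.numeric(y[(M + 1L):(M + n)])
  }
}

#' Apply an IIR filter
#'
#' Evaluates the recursive difference equation
#' \eqn{y_n = \sum_k b_k x_{n-k} - \sum_l a_l y_{n-l}} with zero initial
#' state. With an empty `a` this degenerates to [fir_apply()].
#'
#' @param x numeric sample sequence.
#' @param spec a [filter_spec()] with feedback coefficients `a` (a1..aN).
#' @return Filtered sequence, same length as `x`.
#' @export
iir_apply <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (length(spec$a) == 0L) return(fir_apply(x, spec, causal = TRUE))
  if (any(Mod(polyroot(c(rev(spec$a), 1))) >= 1))
    stop_trapcal("unstable filter: a pole lies on or outside the unit circle",
                 "design_error")
  as.numeric(signal::filter(spec$b, c(1, spec$a), x))
}

#' Design a Butterworth IIR low-pass filter
#'
#' Butterworth prototype mapped by the bilinear transform (the standard
#' `butter` design): maximally flat pass band, unit DC gain, stable by
#' construction. Default order 3.
#'
#' @param cutoff cutoff frequency (Hz), strictly below Nyquist.
#' @param order filter order, `>= 1`.
#' @param fs sampling frequency (Hz).
#' @return A [filter_spec()] of kind `"iir"`.
#' @export
design_iir_lowpass <- function(cutoff, order = 3, fs) {
  check_positive_scalar(fs, "fs")
  check_positive_scalar(cutoff, "cutoff")
  if (cutoff >= fs / 2)
    stop_trapcal("cutoff must lie strictly below the Nyquist frequency",
                 "parameter_error")
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order))
    stop_trapcal("order must be a positive integer", "parameter_error")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  a <- bt$a[-1L] / bt$a[1L]
  b <- bt$b / bt$a[1L]
  if (any(Mod(polyroot(c(rev(a), 1))) >= 1))
    stop_trapcal("designed filter is unstable", "design_error")
  filter_spec("iir", b = b, a = a, causal = TRUE, cutoff = cutoff, band = "low")
}

#' Frequency response of a filter specification
#'
#' Magnitude of \eqn{H(f) = B(e^{-i 2\pi f/f_s}) / A(e^{-i 2\pi f/f_s})}
#' evaluated on the given frequencies.
#'
#' @param spec a [filter_spec()].
#' @param f frequencies (Hz).
#' @param fs sampling frequency (Hz).
#' @return Numeric vector `|H(f)|`.
#' @export
filter_response <- function(spec, f, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  z <- exp(-2i * pi * f / fs)
  num <- outer(z, seq_along(spec$b) - 1L, `^`) %*% spec$b
  den <- if (length(spec$a))
    1 + outer(z, seq_along(spec$a), `^`) %*% spec$a
  else rep(1, length(f))
  as.numeric(Mod(num / den))
}
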