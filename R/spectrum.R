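#' One-sided power spectral density (periodogram)
#'
#' FFT periodogram of a uniformly sampled signal, normalized as a one-sided
#' density: with bin spacing `1/duration`, the density summed over all
#' non-zero frequency bins times the bin width equals the (population)
#' variance of the signal, and the DC bin carries the squared mean. The
#' frequency grid runs from 0 to the Nyquist frequency.
#'
#' @param x numeric sample sequence (length >= 2, finite).
#' @param fs sampling frequency (Hz).
#' @return Object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `density` (signal units squared per Hz), `fs`, `n`.
#' @export
power_spectrum <- function(x, fs) {
  check_positive_scalar(fs, "fs")
  n <- length(x)
  if (n < 2L) stop_trapcal("need at least two samples", "parameter_error")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop_trapcal(sprintf("non-finite sample at index %d", bad[1L]), "data_error")
  X <- stats::fft(x)
  nf <- n %/% 2L + 1L                      # DC .. Nyquist (Nyquist bin only if n even)
  raw <- (Mod(X[seq_len(nf)])^2) / (n * fs)  # two-sided density
  fold <- rep(2, nf); fold[1L] <- 1
  if (n %% 2L == 0L) fold[nf] <- 1
  structure(list(frequencies = (seq_len(nf) - 1) * fs / n,
                 density = raw * fold, fs = fs, n = n),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("One-sided power spectrum: %d bins, 0 to %g Hz (df = %g Hz)\n",
              length(x$frequencies), max(x$frequencies), x$fs / x$n))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ..., log = "xy") {
  keep <- x$frequencies > 0 & x$density > 0
  graphics::plot(x$frequencies[keep], x$density[keep], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD (signal^2/Hz)", ...)
  invisible(x)
}

#' Re-orient a 2-D trajectory by principal component analysis
#'
#' Diagonalizes the 2 x 2 covariance matrix of the two coordinates and
#' rotates the (centred) data so that the first output axis lies along the
#' long axis of the trajectory ellipse and the second along the short axis.
#' Channel means and total variance are preserved. Used to make the per-axis
#' force constants independent of the uncontrolled orientation of the
#' trajectory ellipse relative to the detector axes.
#'
#' @param x,y coordinate vectors of equal length >= 2.
#' @return A list with rotated coordinates `x` and `y` and `rotation`, an
#'   object of class `pca_rotation` holding `angle` (rad, in (-pi/2, pi/2])
#'   and `eigenvalues` (variances along the new axes, descending).
#' @export
pca_rotate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_trapcal("x and y must have equal length >= 2", "parameter_error")
  cv <- stats::cov(cbind(x, y))
  if (all(cv == 0))
    stop_trapcal("zero-variance input: trajectory is degenerate", "degenerate_data_error")
  eg <- eigen(cv, symmetric = TRUE)
  v1 <- eg$vectors[, 1L]
  ang <- atan2(v1[2L], v1[1L])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  ca <- cos(ang); sa <- sin(ang)
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  rot <- structure(list(angle = ang, eigenvalues = eg$values), class = "pca_rotation")
  list(x = mx + (ca * xc + sa * yc),
       y = my + (-sa * xc + ca * yc),
       rotation = rot)
}

#' @export
print.pca_rotation <- function(x, ...) {
  cat(sprintf("PCA rotation: angle %.4g deg, eigenvalues %g, %g\n",
              x$angle * 180 / pi, x$eigenvalues[1L], x$eigenvalues[2L]))
  invisible(x)
}

#' Remove interference spikes from a power spectrum
#'
#' Apparatus vibrations show up in the force spectrum as high, narrow peaks
#' that do not belong to the Lorentzian. Every spectral point is compared to
#' the moving average of `half_window` points on each side of it, excluding
#' the point itself (flanks shrink near the edges); a point exceeding
#' `criterion` times that local average is replaced by the average, all
#' other points are untouched. Detection uses the original values throughout,
#' so the edit never cascades.
#'
#' @param s a [power_spectrum()].
#' @param half_window number of flanking points per side (default 20).
#' @param criterion ratio above the local average that flags a spike (> 1).
#' @return The despiked [power_spectrum()], with the indices of replaced bins
#'   in attribute `"replaced"`.
#' @export
remove_spikes <- function(s, half_window = 20, criterion = 5) {
  stopifnot(inherits(s, "power_spectrum"))
  if (half_window < 1 || half_window != round(half_window))
    stop_trapcal("half_window must be a positive integer", "parameter_error")
  if (criterion <= 1) stop_trapcal("criterion must exceed 1", "parameter_error")
  p <- s$density
  n <- length(p)
  if (n < 2 * half_window + 1)
    stop_trapcal("spectrum shorter than 2*half_window + 1 points", "parameter_error")
  cs <- c(0, cumsum(p))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half_window)
  hi <- pmin(n, idx + half_window)
  # flank mean excluding the point itself
  local_mean <- (cs[hi + 1L] - cs[lo] - p) / (hi - lo)
  spikes <- which(p > criterion * local_mean)
  out <- s
  out$density[spikes] <- local_mean[spikes]
  attr(out, "replaced") <- spikes
  out
}

#' Undo the spectral droop of a blocking average
#'
#' Block-averaging a record by `window` points before decimation multiplies
#' the spectral density by the squared magnitude response of a `window`-point
#' moving average at the original sampling rate (a sinc-like droop that
#' reaches about -0.9 dB at a quarter of the new Nyquist frequency for a
#' 10-point block). Since the blocking filter is known exactly, its in-band
#' attenuation can be divided out before fitting; the corner-frequency bias
#' it would otherwise cause is removed to well under a percent.
#'
#' @param s a [power_spectrum()] of the blocked (decimated) record.
#' @param window the blocking window that produced the record.
#' @param fs0 sampling rate (Hz) at which the blocking filter ran; defaults
#'   to `window` times the spectrum's rate (i.e. blocking happened last).
#' @return The compensated [power_spectrum()].
#' @export
compensate_blocking <- function(s, window, fs0 = s$fs * window) {
  stopifnot(inherits(s, "power_spectrum"))
  if (window < 1 || window != round(window))
    stop_trapcal("window must be a positive integer", "parameter_error")
  if (window == 1) return(s)
  f <- s$frequencies
  num <- sin(pi * f * window / fs0)
  den <- window * sin(pi * f / fs0)
  h2 <- ifelse(f == 0, 1, (num / den)^2)
  s$density <- s$density / h2
  s
}

#' Fit a Lorentzian to the force spectrum
#'
#' Fits \eqn{P(f) = A/(f_c^2 + f^2)} to a one-sided power spectrum within a
#' frequency band and returns the corner frequency \eqn{f_c}. The fit is the
#' analytical least-squares solution of Berg-Sorensen and Flyvbjerg: the
#' reciprocal spectrum is regressed on the frequency basis with
#' density-squared weights, i.e. \eqn{\sum_f (P(f)(\alpha + \beta u(f)) - 1)^2}
#' is minimized, which weights every bin by its relative error and has a
#' closed-form solution.
#'
#' Two frequency bases are available. `"continuum"` uses \eqn{u = f^2}, the
#' continuous-time Lorentzian, and returns
#' \eqn{f_c = \sqrt{\alpha/\beta}}. `"sampled"` uses
#' \eqn{u = \cos(2\pi f/f_s)}, the exact spectral shape of a harmonically
#' trapped bead observed at a finite sampling rate (the sampled
#' Ornstein-Uhlenbeck process), and converts the recovered autoregressive
#' coefficient to \eqn{f_c}; it is free of aliasing bias and is what the
#' calibration pipeline uses on sampled records.
#'
#' @param s a [power_spectrum()].
#' @param band numeric length 2: fit band `[f_min, f_max]` in Hz. Default
#'   5 Hz to a quarter of the Nyquist frequency.
#' @param basis `"continuum"` or `"sampled"` (see Details).
#' @return Object of class `lorentzian_fit`: `corner_frequency` (Hz),
#'   `amplitude` A (signal^2 Hz), `band`, `basis`, `residual` (mean squared
#'   relative residual), `n_bins`.
#' @export
fit_lorentzian <- function(s, band = NULL, basis = c("continuum", "sampled")) {
  stopifnot(inherits(s, "power_spectrum"))
  basis <- match.arg(basis)
  if (is.null(band)) band <- c(5, s$fs / 4)
  if (length(band) != 2L || band[1L] >= band[2L])
    stop_trapcal("band must be an increasing pair of frequencies", "parameter_error")
  keep <- s$frequencies >= band[1L] & s$frequencies <= band[2L]
  f <- s$frequencies[keep]
  p <- s$density[keep]
  if (length(f) < 10L)
    stop_trapcal("fewer than 10 spectral bins inside the fit band", "parameter_error")
  if (any(p <= 0))
    stop_trapcal("non-positive spectral density inside the fit band", "data_error")

  u <- if (basis == "continuum") f^2 else cos(2 * pi * f / s$fs)
  # minimize sum (p*(alpha + beta*u) - 1)^2  ->  2x2 normal equations
  spp <- sum(p * p); sppu <- sum(p * p * u); sppuu <- sum(p * p * u * u)
  sp <- sum(p); spu <- sum(p * u)
  det <- spp * sppuu - sppu^2
  alpha <- (sppuu * sp - sppu * spu) / det
  beta <- (spp * spu - sppu * sp) / det

  if (basis == "continuum") {
    if (!is.finite(alpha / beta) || alpha / beta <= 0)
      stop_trapcal("fit failed: non-positive corner frequency squared; the band may exclude the corner",
                   "fit_failure_error")
    fc <- sqrt(alpha / beta)
    A <- 1 / beta
  } else {
    rho <- beta / alpha
    if (!is.finite(rho) || abs(rho) >= 1 || rho >= 0)
      stop_trapcal("fit failed: spectrum is not compatible with a sampled Lorentzian in this band",
                   "fit_failure_error")
    aa <- (-1 + sqrt(1 - rho^2)) / rho    # AR(1) coefficient in (0, 1)
    fc <- -log(aa) * s$fs / (2 * pi)
    A <- fc^2 / (alpha + beta)            # equivalent low-frequency plateau amplitude
  }
  if (fc <= band[1L] || fc >= band[2L])
    warn_trapcal(sprintf("fitted corner frequency %.4g Hz lies outside the fit band", fc),
                 "band_warning")
  pred <- 1 / (alpha + beta * u)
  structure(list(corner_frequency = fc, amplitude = A, band = band,
                 basis = basis, alpha = alpha, beta = beta,
                 residual = mean((p / pred - 1)^2), n_bins = length(f)),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit (%s basis): f_c = %.6g Hz over [%g, %g] Hz (%d bins)\n",
              x$basis, x$corner_frequency, x$band[1L], x$band[2L], x$n_bins))
  invisible(x)
}

#' Trap stiffness from the corner frequency
#'
#' Converts a fitted corner frequency to the force constant of the trap,
#' \eqn{\kappa = 2\pi\gamma_0 f_c} with the Stokes drag
#' \eqn{\gamma_0 = 6\pi\eta r}, i.e. \eqn{\kappa = 12\pi^2 \eta r f_c}.
#'
#' @param f_c corner frequency (Hz), > 0. A [fit_lorentzian()] result is
#'   also accepted.
#' @param env a [trap_environment()].
#' @return Trap stiffness (N/m).
#' @examples
#' env <- trap_environment(297.25, 0.910e-3, 1.5e-6)
#' stiffness_from_corner(46.27, env)   # 7.48e-6 N/m
#' @export
stiffness_from_corner <- function(f_c, env) {
  if (inherits(f_c, "lorentzian_fit")) f_c <- f_c$corner_frequency
  check_positive_scalar(f_c, "f_c")
  env <- as_trap_environment(env)
  2 * pi * env$gamma0 * f_c
}
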