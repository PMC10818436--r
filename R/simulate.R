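#' Optical trap model for the Brownian-dynamics simulator
#'
#' Describes one harmonic trap (possibly anisotropic, with principal axes
#' rotated against the detector axes) or a pair of traps modelled as two
#' inverted Gaussian potential wells along the line joining their centres.
#'
#' @param stiffness trap stiffness per principal axis, N/m; a scalar means an
#'   isotropic trap. In double-trap mode this sets the transverse stiffness;
#'   the axial stiffness near each well bottom is `well_depths/well_widths^2`.
#' @param angle orientation of the first principal axis against the detector
#'   horizontal axis, rad, in (-pi/2, pi/2].
#' @param centers trap centre coordinates (m): a length-2 vector for a single
#'   trap or a 2 x 2 matrix (one row per trap) for a double trap.
#' @param well_depths,well_widths double-trap mode only: depth (J) and
#'   Gaussian width (m) of each well, recycled to length 2.
#' @return Object of class `trap_model`.
#' @seealso [simulate_bead()], [double_well_potential()]
#' @export
trap_model <- function(stiffness, angle = 0, centers = c(0, 0),
                       well_depths = NULL, well_widths = NULL) {
  stiffness <- rep_len(as.numeric(stiffness), 2L)
  if (any(stiffness <= 0)) stop_trapcal("stiffness must be positive", "parameter_error")
  if (!(angle > -pi / 2 && angle <= pi / 2))
    stop_trapcal("angle must lie in (-pi/2, pi/2]", "parameter_error")
  centers <- if (is.matrix(centers)) centers else matrix(centers, nrow = 1L)
  if (ncol(centers) != 2L || !nrow(centers) %in% 1:2)
    stop_trapcal("centers must be one or two (x, y) coordinate pairs", "parameter_error")
  if (nrow(centers) == 2L) {
    if (is.null(well_depths) || is.null(well_widths))
      stop_trapcal("double-trap mode needs well_depths and well_widths", "parameter_error")
    well_depths <- rep_len(as.numeric(well_depths), 2L)
    well_widths <- rep_len(as.numeric(well_widths), 2L)
    if (any(well_depths <= 0) || any(well_widths <= 0))
      stop_trapcal("well depths and widths must be positive", "parameter_error")
  }
  structure(list(stiffness = stiffness, angle = angle, centers = centers,
                 well_depths = well_depths, well_widths = well_widths),
            class = "trap_model")
}

#' @export
print.trap_model <- function(x, ...) {
  if (nrow(x$centers) == 1L)
    cat(sprintf("Single trap: kappa = (%g, %g) N/m, axis angle %.3g rad\n",
                x$stiffness[1L], x$stiffness[2L], x$angle))
  else
    cat(sprintf("Double trap: depths (%g, %g) J, widths (%g, %g) m, separation %g m\n",
                x$well_depths[1L], x$well_depths[2L],
                x$well_widths[1L], x$well_widths[2L],
                sqrt(sum((x$centers[2L, ] - x$centers[1L, ])^2))))
  invisible(x)
}

#' Position-sensing detector model
#'
#' Converts bead positions to detector voltages: per-axis linear gain (V/m,
#' the reciprocal of the position calibration constant), additive Gaussian
#' electronics noise, optional sinusoidal interference spikes (apparatus
#' vibrations picked up by the electronics) and an aggregated-channel
#' baseline. The defaults reproduce the signal scale of a detector with a
#' calibration constant of about 8.7 nm/mV and electronics noise of 0.1 mV.
#'
#' @param gain position-to-signal gain per axis (V/m), scalar or length 2.
#' @param noise_sd electronics noise standard deviation (V).
#' @param spikes `NULL` or a data frame with columns `frequency` (Hz) and
#'   `amplitude` (V): interference sinusoids added to both difference channels.
#' @param baseline aggregated-channel mean level (V).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(gain = 1e-3 / 8.68e-9, noise_sd = 1e-4,
                           spikes = NULL, baseline = 1) {
  gain <- rep_len(as.numeric(gain), 2L)
  if (any(gain <= 0)) stop_trapcal("gain must be positive", "parameter_error")
  if (noise_sd < 0) stop_trapcal("noise_sd must be >= 0", "parameter_error")
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes)
    if (!all(c("frequency", "amplitude") %in% names(spikes)))
      stop_trapcal("spikes needs columns 'frequency' and 'amplitude'", "parameter_error")
  }
  structure(list(gain = gain, noise_sd = noise_sd, spikes = spikes,
                 baseline = baseline),
            class = "detector_model")
}

#' Simulate the Brownian motion of a trapped bead
#'
#' Overdamped Langevin dynamics of a bead in the given trap. For a single
#' harmonic trap each principal axis is an Ornstein-Uhlenbeck process with
#' relaxation rate \eqn{\kappa/\gamma_0} and stationary variance
#' \eqn{k_B T/\kappa}, propagated with the exact discrete-time transition
#' (mean decay \eqn{e^{-\lambda\Delta t}}, innovation variance
#' \eqn{(k_BT/\kappa)(1-e^{-2\lambda\Delta t})}), so there is no time-step
#' discretisation bias at any sampling rate. A two-centre trap is delegated
#' to [simulate_double_trap_run()].
#'
#' @param trap a [trap_model()].
#' @param env a [trap_environment()].
#' @param fs sampling frequency (Hz).
#' @param duration record length (s); `fs * duration >= 2`.
#' @param seed integer RNG seed; the same seed reproduces the run bit for bit.
#' @return An `fs*duration` x 2 matrix of positions (m) in detector
#'   coordinates, with attributes `sampling_frequency` and `seed`.
#' @examples
#' env <- trap_environment(297.25, 0.910e-3, 1.5e-6)
#' pos <- simulate_bead(trap_model(7.48e-6), env, fs = 1e4, duration = 1, seed = 1)
#' sd(pos[, 1])                      # ~ sqrt(kB T / kappa) = 2.34e-8 m
#' @export
simulate_bead <- function(trap, env, fs, duration, seed = NULL) {
  stopifnot(inherits(trap, "trap_model"))
  env <- as_trap_environment(env)
  check_positive_scalar(fs, "fs")
  check_positive_scalar(duration, "duration")
  n <- round(fs * duration)
  if (n < 2) stop_trapcal("fs * duration must be at least 2 samples", "parameter_error")
  if (nrow(trap$centers) == 2L)
    return(simulate_double_trap_run(trap, env, fs, duration, seed))
  if (!is.null(seed)) set.seed(seed)
  kBT <- env$k_B * env$temperature
  dt <- 1 / fs
  p <- matrix(0, n, 2L)
  for (i in 1:2) {
    lam <- trap$stiffness[i] / env$gamma0
    a <- exp(-lam * dt)
    s2 <- kBT / trap$stiffness[i]
    e <- stats::rnorm(n, sd = sqrt(s2 * (1 - a^2)))
    x0 <- stats::rnorm(1L, sd = sqrt(s2))
    p[, i] <- as.numeric(stats::filter(e, a, method = "recursive", init = x0))
  }
  ca <- cos(trap$angle); sa <- sin(trap$angle)
  out <- cbind(p[, 1L] * ca - p[, 2L] * sa,
               p[, 1L] * sa + p[, 2L] * ca)
  out[, 1L] <- out[, 1L] + trap$centers[1L, 1L]
  out[, 2L] <- out[, 2L] + trap$centers[1L, 2L]
  colnames(out) <- c("x", "y")
  attr(out, "sampling_frequency") <- fs
  attr(out, "seed") <- seed
  out
}

#' Simulate a bead shared between two optical traps
#'
#' The trap pair is modelled as two inverted Gaussian wells along the line
#' joining the trap centres (the potential shape produced when a non-ideal
#' beam splits into neighbouring foci), with an independent harmonic
#' transverse axis, so the potential is separable and the axial stationary
#' distribution is exactly Boltzmann in the axial double-well potential.
#' The axial coordinate is propagated by the Euler-Maruyama scheme; the step
#' is rejected as unstable when `dt * kappa_max / gamma0 > 0.1`, where
#' `kappa_max` is the largest well-bottom curvature `D/w^2`.
#'
#' @inheritParams simulate_bead
#' @return As [simulate_bead()].
#' @export
simulate_double_trap_run <- function(trap, env, fs, duration, seed = NULL) {
  stopifnot(inherits(trap, "trap_model"))
  if (nrow(trap$centers) != 2L)
    stop_trapcal("double-trap simulation needs two trap centers", "parameter_error")
  env <- as_trap_environment(env)
  n <- round(fs * duration)
  if (n < 2) stop_trapcal("fs * duration must be at least 2 samples", "parameter_error")
  dt <- 1 / fs
  kmax <- max(trap$well_depths / trap$well_widths^2)
  if (dt * kmax / env$gamma0 > 0.1)
    stop_trapcal(sprintf(
      "Euler step unstable (dt*kappa/gamma0 = %.3g > 0.1); increase fs",
      dt * kmax / env$gamma0), "parameter_error")
  if (!is.null(seed)) set.seed(seed)
  kBT <- env$k_B * env$temperature

  sep <- trap$centers[2L, ] - trap$centers[1L, ]
  d <- sqrt(sum(sep^2))
  u <- sep / d                       # axial unit vector
  mid <- colMeans(trap$centers)
  sc <- c(-d / 2, d / 2)             # well centres in the axial coordinate
  D <- trap$well_depths; w2 <- trap$well_widths^2

  z <- stats::rnorm(n, sd = sqrt(2 * kBT * dt / env$gamma0))
  s <- numeric(n)
  s[1L] <- sc[1L]                    # start at the bottom of the first well
  idt <- dt / env$gamma0
  for (i in 2:n) {
    si <- s[i - 1L]
    f <- -(D[1L] * (si - sc[1L]) / w2[1L] * exp(-(si - sc[1L])^2 / (2 * w2[1L])) +
           D[2L] * (si - sc[2L]) / w2[2L] * exp(-(si - sc[2L])^2 / (2 * w2[2L])))
    s[i] <- si + f * idt + z[i]
  }

  # transverse axis: exact OU with the model's (first) stiffness
  lam <- trap$stiffness[1L] / env$gamma0
  a <- exp(-lam * dt)
  s2t <- kBT / trap$stiffness[1L]
  e <- stats::rnorm(n, sd = sqrt(s2t * (1 - a^2)))
  tv <- as.numeric(stats::filter(e, a, method = "recursive",
                                 init = stats::rnorm(1L, sd = sqrt(s2t))))

  out <- cbind(mid[1L] + s * u[1L] - tv * u[2L],
               mid[2L] + s * u[2L] + tv * u[1L])
  colnames(out) <- c("x", "y")
  attr(out, "sampling_frequency") <- fs
  attr(out, "seed") <- seed
  out
}

#' Axial double-well potential and its barrier
#'
#' `double_well_potential()` evaluates the axial potential of a two-centre
#' [trap_model()] (sum of two inverted Gaussian wells) at axial coordinates
#' `s` measured from the midpoint between the centres.
#' `double_well_barrier()` locates the two minima and the saddle between them
#' numerically and returns the barrier height above the global minimum.
#'
#' @param trap a two-centre [trap_model()].
#' @param s axial coordinates (m), origin midway between the centres.
#' @return `double_well_potential()`: potential values (J).
#'   `double_well_barrier()`: a list with `minima` (axial positions, m),
#'   `saddle` (m), and `barrier` (J above the global minimum).
#' @export
double_well_potential <- function(trap, s) {
  stopifnot(inherits(trap, "trap_model"))
  if (nrow(trap$centers) != 2L)
    stop_trapcal("trap model has a single centre", "parameter_error")
  d <- sqrt(sum((trap$centers[2L, ] - trap$centers[1L, ])^2))
  sc <- c(-d / 2, d / 2)
  -(trap$well_depths[1L] * exp(-(s - sc[1L])^2 / (2 * trap$well_widths[1L]^2)) +
    trap$well_depths[2L] * exp(-(s - sc[2L])^2 / (2 * trap$well_widths[2L]^2)))
}

#' @rdname double_well_potential
#' @export
double_well_barrier <- function(trap) {
  stopifnot(inherits(trap, "trap_model"))
  if (nrow(trap$centers) != 2L)
    stop_trapcal("trap model has a single centre", "parameter_error")
  d <- sqrt(sum((trap$centers[2L, ] - trap$centers[1L, ])^2))
  lim <- d / 2 + 3 * max(trap$well_widths)
  s <- seq(-lim, lim, length.out = 4001L)
  V <- double_well_potential(trap, s)
  interior <- 2:(length(s) - 1L)
  mins <- interior[V[interior] < V[interior - 1L] & V[interior] <= V[interior + 1L]]
  if (length(mins) < 2L)
    stop_trapcal("potential has a single well: wells have merged", "shape_error")
  mins <- mins[order(V[mins])][1:2]
  mins <- sort(mins)
  sad <- mins[1L] + which.max(V[mins[1L]:mins[2L]]) - 1L
  list(minima = s[mins], saddle = s[sad],
       barrier = V[sad] - min(V[mins]))
}

#' Simulate the detector readout of a position record
#'
#' Maps bead positions through a [detector_model()]: per-axis difference
#' signal = gain x position + Gaussian electronics noise + interference
#' sinusoids; aggregated channel = baseline + noise. Output units are volts.
#'
#' @param positions an n x 2 position matrix (m), e.g. from [simulate_bead()].
#' @param det a [detector_model()].
#' @param fs sampling frequency (Hz); defaults to the matrix attribute.
#' @param seed integer RNG seed for the noise draws.
#' @return A [trajectory()] in volts.
#' @export
simulate_detector <- function(positions, det, fs = NULL, seed = NULL) {
  stopifnot(inherits(det, "detector_model"))
  if (is.null(fs)) fs <- attr(positions, "sampling_frequency")
  if (is.null(fs)) stop_trapcal("sampling frequency not supplied", "config_error")
  if (!all(is.finite(positions)))
    stop_trapcal("positions contain non-finite values", "data_error")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(positions)
  tt <- (seq_len(n) - 1) / fs
  spike_wave <- 0
  if (!is.null(det$spikes) && nrow(det$spikes))
    for (j in seq_len(nrow(det$spikes)))
      spike_wave <- spike_wave +
        det$spikes$amplitude[j] * sin(2 * pi * det$spikes$frequency[j] * tt)
  h <- det$gain[1L] * positions[, 1L] + stats::rnorm(n, sd = det$noise_sd) + spike_wave
  v <- det$gain[2L] * positions[, 2L] + stats::rnorm(n, sd = det$noise_sd) + spike_wave
  agg <- det$baseline + stats::rnorm(n, sd = det$noise_sd)
  trajectory(h, v, agg, sampling_frequency = fs, units = "V")
}
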