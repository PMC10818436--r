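#' Calibrate an optical trap from a detector trajectory
#'
#' Runs the full force and position calibration on a recorded (or simulated)
#' trajectory of a trapped bead:
#'
#' 1. optional blocking average on ingest (reducing the record to the
#'    effective analysis rate);
#' 2. selection of the moving-average denoising window by the curvature of
#'    log(delta) versus log(window) ([select_averaging_window()]), unless a
#'    window is given;
#' 3. re-orientation of the coordinate system by PCA so the axes align with
#'    the trajectory ellipse ([pca_rotate()]);
#' 4. per axis: one-sided FFT power spectrum of the unsmoothed record,
#'    spectral spike removal, Lorentzian corner-frequency fit — on the exact
#'    sampled basis for a native-rate record, or on the continuum basis after
#'    [compensate_blocking()] when the record was blocked on ingest — and
#'    stiffness \eqn{\kappa = 2\pi\gamma_0 f_c} ([stiffness_from_corner()]);
#' 5. per axis: equipartition spread \eqn{\sigma_m = \sqrt{k_BT/\kappa}},
#'    detector spread \eqn{\sigma_{PSD}} of the moving-average-filtered
#'    record, and the sigma-method calibration constant
#'    \eqn{\delta = \sigma_m/\sigma_{PSD}};
#' 6. per axis: calibrated position distribution and Boltzmann-inverted trap
#'    potential.
#'
#' The spectrum is computed from the unsmoothed (only block-averaged) record
#' — moving-average filtering would distort the Lorentzian — while
#' \eqn{\sigma_{PSD}} uses the moving-average-filtered record, as the
#' sigma-method prescribes.
#'
#' @param t a [trajectory()] in `"V"`, `"mV"` or `"a.u."` units.
#' @param env a [trap_environment()].
#' @param block blocking-average window applied on ingest (1 = none).
#' @param pre_blocked blocking factor that the acquisition software already
#'   applied before the record was stored (1 = none): its known spectral
#'   droop is compensated exactly like an ingest block.
#' @param window moving-average window for the sigma-method trajectory, in
#'   samples of the blocked record; `"auto"` selects it by curvature.
#' @param windows candidate windows for the automatic selection.
#' @param pca rotate onto the trajectory-ellipse axes first?
#' @param band Lorentzian fit band (Hz); default 5 Hz to a quarter of the
#'   effective Nyquist frequency.
#' @param spike_half_window,spike_criterion see [remove_spikes()].
#' @param bins histogram bins for the position distribution.
#' @return An object of class `trap_calibration`; see
#'   [print.trap_calibration()], [coef.trap_calibration()],
#'   [simulate.trap_calibration()].
#' @examples
#' env <- trap_environment(297.25, 0.910e-3, 1.5e-6)
#' pos <- simulate_bead(trap_model(7.48e-6), env, fs = 1e4, duration = 20, seed = 1)
#' tr <- simulate_detector(pos, detector_model(), seed = 2)
#' cal <- calibrate_trap(tr, env)
#' cal
#' coef(cal)
#' @export
calibrate_trap <- function(t, env, block = 1, pre_blocked = 1, window = "auto",
                           windows = c(1, 2, 5, 10, 20, 50, 100),
                           pca = TRUE, band = NULL,
                           spike_half_window = 20, spike_criterion = 5,
                           bins = 100) {
  stopifnot(inherits(t, "trajectory"))
  env <- as_trap_environment(env)
  if (t$units == "nm")
    stop_trapcal("trajectory is already position-calibrated", "precondition_error")

  # signal units for reporting: mV for voltage records, a.u. for normalized
  if (t$units == "V") {
    h <- t$horizontal * 1e3; v <- t$vertical * 1e3; sig_units <- "mV"
  } else {
    h <- t$horizontal; v <- t$vertical
    sig_units <- if (t$units == "a.u.") "a.u." else t$units
  }
  fs <- t$sampling_frequency
  if (block > 1) {
    h <- blocking_average(h, block)
    v <- blocking_average(v, block)
    fs <- fs / block
  }

  if (identical(window, "auto")) {
    windows <- windows[windows <= length(h) / 4]
    window <- suppressWarnings(as.integer(select_averaging_window(h, windows)))
  }
  if (window < 1) stop_trapcal("window must be >= 1", "parameter_error")

  if (pca) {
    rot <- pca_rotate(h, v)
    sig <- list(rot$x, rot$y)
    rotation <- rot$rotation
    axes <- c("axis1", "axis2")
  } else {
    sig <- list(h, v)
    rotation <- NULL
    axes <- c("horizontal", "vertical")
  }
  if (is.null(band)) band <- c(5, fs / 4)

  # On an unblocked record the exact sampled-Lorentzian basis absorbs
  # aliasing; on a record blocked by us or by the acquisition software,
  # dividing out the known blocking response(s) restores the continuum
  # Lorentzian in band.
  fs_in <- t$sampling_frequency
  basis <- if (block > 1 || pre_blocked > 1) "continuum" else "sampled"
  per_axis <- lapply(sig, function(x) {
    ps <- power_spectrum(x - mean(x), fs)
    if (block > 1) ps <- compensate_blocking(ps, block, fs0 = fs_in)
    if (pre_blocked > 1)
      ps <- compensate_blocking(ps, pre_blocked, fs0 = fs_in * pre_blocked)
    ps <- remove_spikes(ps, half_window = spike_half_window,
                        criterion = spike_criterion)
    fit <- fit_lorentzian(ps, band = band, basis = basis)
    kappa <- stiffness_from_corner(fit$corner_frequency, env)
    sigma_m <- sigma_from_stiffness(kappa, env$temperature)
    xf <- moving_average(x, window - 1L)
    sigma_psd <- stats::sd(xf)
    delta <- position_calibration_sigma(sigma_m, sigma_psd)
    pos_nm <- (xf - mean(xf)) * delta
    dist <- position_distribution(pos_nm, bins = bins)
    pot <- potential_from_distribution(dist, env$temperature)
    list(spectrum = ps, fit = fit, kappa = kappa, sigma_m = sigma_m,
         sigma_psd = sigma_psd, delta = delta,
         distribution = dist, potential = pot)
  })
  names(per_axis) <- axes

  structure(
    list(axes = axes, per_axis = per_axis, rotation = rotation,
         environment = env,
         settings = list(block = block, pre_blocked = pre_blocked,
                         window = window, band = band,
                         pca = pca, spike_half_window = spike_half_window,
                         spike_criterion = spike_criterion, bins = bins,
                         effective_fs = fs, n = length(h),
                         signal_units = sig_units)),
    class = "trap_calibration")
}

axis_table <- function(x) {
  do.call(rbind, lapply(x$axes, function(ax) {
    p <- x$per_axis[[ax]]
    data.frame(axis = ax,
               corner_frequency_hz = p$fit$corner_frequency,
               kappa_n_per_m = p$kappa,
               kappa_pn_per_um = p$kappa * 1e6,
               sigma_m_nm = p$sigma_m * 1e9,
               sigma_psd = p$sigma_psd,
               delta_nm_per_unit = p$delta)
  }))
}

#' @export
print.trap_calibration <- function(x, ...) {
  cat("Optical-trap calibration (power-spectrum + sigma-method)\n")
  cat(sprintf("  %d samples at %g Hz effective rate; averaging window %d sample(s)\n",
              x$settings$n, x$settings$effective_fs, x$settings$window))
  if (!is.null(x$rotation))
    cat(sprintf("  PCA rotation: %.3g deg\n", x$rotation$angle * 180 / pi))
  tab <- axis_table(x)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-10s f_c = %7.4g Hz   kappa = %.3g pN/um   delta = %.3g nm/%s\n",
                tab$axis[i], tab$corner_frequency_hz[i],
                tab$kappa_pn_per_um[i], tab$delta_nm_per_unit[i],
                x$settings$signal_units))
  invisible(x)
}

#' @export
summary.trap_calibration <- function(object, ...) {
  structure(list(table = axis_table(object),
                 rotation = object$rotation,
                 environment = object$environment,
                 settings = object$settings,
                 residuals = vapply(object$per_axis,
                                    function(p) p$fit$residual, 0)),
            class = "summary.trap_calibration")
}

#' @export
print.summary.trap_calibration <- function(x, ...) {
  cat("Optical-trap calibration summary\n\nEnvironment:\n")
  print(x$environment)
  s <- x$settings
  cat(sprintf("\nSettings: block %d, window %d, band [%g, %g] Hz, %d bins, units %s\n",
              s$block, s$window, s$band[1L], s$band[2L], s$bins, s$signal_units))
  if (!is.null(x$rotation)) print(x$rotation)
  cat("\nPer-axis results:\n")
  print(x$table, row.names = FALSE)
  cat("\nLorentzian mean squared relative residuals:",
      sprintf("%.3g", x$residuals), "\n")
  invisible(x)
}

#' Extract calibration coefficients
#'
#' @param object a `trap_calibration`.
#' @param ... unused.
#' @return Named vector with, per axis, the corner frequency (Hz), stiffness
#'   (N/m) and position calibration constant (nm per signal unit).
#' @export
coef.trap_calibration <- function(object, ...) {
  out <- unlist(lapply(object$axes, function(ax) {
    p <- object$per_axis[[ax]]
    stats::setNames(c(p$fit$corner_frequency, p$kappa, p$delta),
                    paste0(c("fc_", "kappa_", "delta_"), ax))
  }))
  out
}

#' Plot a trap calibration
#'
#' `which = 1`: per-axis power spectra with the fitted Lorentzians (log-log);
#' `which = 2`: calibrated position distributions; `which = 3`: Boltzmann
#' trap potentials.
#'
#' @param x a `trap_calibration`.
#' @param which which panel(s) to draw.
#' @param ... passed to the underlying plot calls.
#' @export
plot.trap_calibration <- function(x, which = 1, ...) {
  for (w in which) {
    if (w == 1) {
      for (ax in x$axes) {
        p <- x$per_axis[[ax]]
        plot(p$spectrum, main = sprintf("%s: f_c = %.4g Hz", ax,
                                        p$fit$corner_frequency), ...)
        f <- p$spectrum$frequencies
        keep <- f >= p$fit$band[1L] & f <= p$fit$band[2L]
        u <- if (p$fit$basis == "sampled") cos(2 * pi * f[keep] / p$spectrum$fs)
             else f[keep]^2
        graphics::lines(f[keep], 1 / (p$fit$alpha + p$fit$beta * u),
                        col = 2, lwd = 2)
      }
    } else if (w == 2) {
      for (ax in x$axes)
        plot(x$per_axis[[ax]]$distribution,
             main = sprintf("%s position distribution (nm)", ax), ...)
    } else if (w == 3) {
      for (ax in x$axes)
        plot(x$per_axis[[ax]]$potential,
             main = sprintf("%s trap potential", ax), ...)
    }
  }
  invisible(x)
}

#' Simulate new trajectories from a fitted calibration
#'
#' Generates detector trajectories from the calibrated model: an
#' Ornstein-Uhlenbeck bead with the fitted per-axis stiffnesses in the
#' calibration's environment, observed through a noiseless detector whose
#' gain is the reciprocal of the fitted calibration constant.
#'
#' @param object a `trap_calibration`.
#' @param nsim number of trajectories.
#' @param seed integer seed (incremented per replicate).
#' @param duration record length (s); default reproduces the fitted record.
#' @param ... unused.
#' @return A [trajectory()] (`nsim = 1`) or list of trajectories.
#' @export
simulate.trap_calibration <- function(object, nsim = 1, seed = NULL,
                                      duration = NULL, ...) {
  s <- object$settings
  if (is.null(duration)) duration <- s$n / s$effective_fs
  kap <- vapply(object$per_axis, function(p) p$kappa, 0)
  del <- vapply(object$per_axis, function(p) p$delta, 0)     # nm per signal unit
  unit_v <- if (s$signal_units == "mV") 1e-3 else 1          # signal unit in V
  gain <- unit_v / (del * 1e-9)                              # V/m
  trap <- trap_model(stiffness = kap,
                     angle = if (!is.null(object$rotation)) object$rotation$angle else 0)
  det <- detector_model(gain = gain, noise_sd = 0)
  out <- lapply(seq_len(nsim), function(i) {
    sd_i <- if (is.null(seed)) NULL else seed + i - 1L
    pos <- simulate_bead(trap, object$environment, fs = s$effective_fs,
                         duration = duration, seed = sd_i)
    simulate_detector(pos, det, seed = sd_i)
  })
  if (nsim == 1) out[[1L]] else out
}
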