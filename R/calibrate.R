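#' Equipartition relations between stiffness and positional spread
#'
#' In a harmonic trap the stationary variance of the bead position is
#' \eqn{\sigma_m^2 = k_B T/\kappa}. [sigma_from_stiffness()] evaluates
#' \eqn{\sigma_m = \sqrt{k_B T/\kappa}}; [stiffness_from_variance()] inverts
#' it, \eqn{\kappa = k_B T/\sigma_m^2} (used per well when calibrating a
#' double trap).
#'
#' @param kappa trap stiffness (N/m).
#' @param temperature absolute temperature (K).
#' @param sigma_m positional standard deviation (m).
#' @return A scalar: \eqn{\sigma_m} in m, or \eqn{\kappa} in N/m.
#' @examples
#' sigma_from_stiffness(7.48e-6, 297.25)   # 2.34e-8 m
#' @export
sigma_from_stiffness <- function(kappa, temperature) {
  check_positive_scalar(kappa, "kappa")
  check_positive_scalar(temperature, "temperature")
  sqrt(.kB * temperature / kappa)
}

#' @rdname sigma_from_stiffness
#' @export
stiffness_from_variance <- function(sigma_m, temperature) {
  check_positive_scalar(sigma_m, "sigma_m")
  check_positive_scalar(temperature, "temperature")
  .kB * temperature / sigma_m^2
}

#' Position calibration constant by the sigma-method
#'
#' The calibration constant \eqn{\delta = \sigma_m/\sigma_{PSD}} relates the
#' equipartition-predicted positional spread (m) to the spread of the
#' recorded detector signal, and is reported in nm per signal unit (nm/mV,
#' nm/V or nm/(a.u.) depending on the record's units).
#'
#' @param sigma_m positional standard deviation (m), e.g. from
#'   [sigma_from_stiffness()].
#' @param sigma_psd standard deviation of the (filtered) detector signal, in
#'   the record's signal units.
#' @return \eqn{\delta} in nm per signal unit.
#' @export
position_calibration_sigma <- function(sigma_m, sigma_psd) {
  check_positive_scalar(sigma_m, "sigma_m")
  check_positive_scalar(sigma_psd, "sigma_psd")
  (sigma_m * 1e9) / sigma_psd
}

#' Choose the moving-average window for trajectory denoising
#'
#' The sigma-method calibration constant depends on the averaging window used
#' to filter the trajectory: too little averaging leaves electronics noise in
#' \eqn{\sigma_{PSD}}, too much flattens genuine trajectory detail. As the
#' window grows, log(delta) first rises steeply while noise is being removed
#' and then flattens; the window at the sharpest bend — the biggest
#' (discrete) curvature of log(delta) versus log(window) — removes most of
#' the noise while sparing the signal. Since \eqn{\sigma_m} only shifts
#' log(delta) by a constant, the curvature is computed from
#' \eqn{-\log\sigma_{PSD}(w)} directly and no stiffness is needed.
#'
#' @param t a [trajectory()] (or plain numeric vector).
#' @param windows candidate window lengths (samples), at least 4, increasing.
#' @param axis channel to use when `t` is a trajectory.
#' @param curvature_tol a curve whose most negative interior curvature does
#'   not reach `-curvature_tol` is declared featureless: a warning is raised
#'   and the smallest candidate returned.
#' @return The selected window (integer), with the per-window log-delta
#'   offsets and curvatures attached as attributes `"log_delta"` and
#'   `"curvature"`.
#' @export
select_averaging_window <- function(t, windows = c(1, 2, 5, 10, 20, 50, 100),
                                    axis = c("horizontal", "vertical"),
                                    curvature_tol = 0.02) {
  x <- if (inherits(t, "trajectory")) t[[match.arg(axis)]] else as.numeric(t)
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) < 4L)
    stop_trapcal("need at least 4 candidate windows", "parameter_error")
  if (any(windows < 1L))
    stop_trapcal("windows must be positive integers", "parameter_error")
  sds <- vapply(windows, function(w) stats::sd(moving_average(x, w - 1L)), 0)
  ld <- -log(sds)                       # log delta up to an additive constant
  lw <- log(windows)
  m <- length(windows)
  cur <- rep(NA_real_, m)
  for (k in 2:(m - 1L)) {
    d1 <- (ld[k] - ld[k - 1L]) / (lw[k] - lw[k - 1L])
    d2 <- (ld[k + 1L] - ld[k]) / (lw[k + 1L] - lw[k])
    cur[k] <- 2 * (d2 - d1) / (lw[k + 1L] - lw[k - 1L])
  }
  if (all(is.na(cur)) || min(cur, na.rm = TRUE) > -curvature_tol) {
    warn_trapcal("no interior curvature maximum: log delta curve is featureless; returning the smallest window",
                 "selection_warning")
    sel <- windows[1L]
  } else {
    sel <- windows[which.min(cur)]
  }
  structure(sel, log_delta = ld, curvature = cur, windows = windows)
}

#' Hydrodynamic position calibration from a deflection table
#'
#' In the hydrodynamic method the stage is moved so that viscous drag
#' deflects the trapped bead by a known amount: the camera measures the
#' displacement in nm while the detector reports it in normalized units.
#' Each direction gives a calibration constant (camera displacement divided
#' by detector deflection); opposite directions are averaged per axis
#' (left/right -> horizontal, down/top -> vertical) and the axis constants
#' are rounded to integer nm/(a.u.) for reporting.
#'
#' @param table a data frame with columns `direction` (left/right/down/top),
#'   `detector_au` (detector deflection, a.u.) and `camera_nm` (camera
#'   displacement, nm), e.g. from [read_deflection_table()].
#' @return Named numeric `c(horizontal =, vertical =)` in nm/(a.u.), rounded
#'   to integers; the unrounded axis means and the per-direction constants
#'   are attached as attributes `"unrounded"` and `"per_direction"`.
#' @examples
#' tab <- data.frame(direction = c("left", "right", "down", "top"),
#'                   detector_au = c(0.363, 0.368, 0.417, 0.333),
#'                   camera_nm = c(380, 330, 620, 510))
#' hydrodynamic_calibration(tab)   # horizontal 972, vertical 1509
#' @export
hydrodynamic_calibration <- function(table) {
  table <- as.data.frame(table)
  if (!all(c("direction", "detector_au", "camera_nm") %in% names(table)))
    stop_trapcal("table needs columns direction, detector_au, camera_nm",
                 "format_error")
  dir <- tolower(trimws(as.character(table$direction)))
  axis <- ifelse(dir %in% c("left", "right"), "horizontal",
          ifelse(dir %in% c("down", "top", "up"), "vertical", NA))
  if (anyNA(axis))
    stop_trapcal("directions must be left/right/down/top", "format_error")
  if (any(table$detector_au == 0))
    stop_trapcal("zero detector deflection", "parameter_error")
  const <- table$camera_nm / table$detector_au
  out <- tapply(const, axis, mean)
  for (ax in c("horizontal", "vertical"))
    if (!ax %in% names(out))
      stop_trapcal(sprintf("no deflection rows for the %s axis", ax), "format_error")
  unrounded <- c(horizontal = unname(out[["horizontal"]]),
                 vertical = unname(out[["vertical"]]))
  structure(round(unrounded),
            unrounded = unrounded,
            per_direction = stats::setNames(const, dir))
}

#' @rdname hydrodynamic_calibration
#' @param path CSV file with header `direction,detector_au,camera_nm`.
#' @export
read_deflection_table <- function(path) {
  d <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("direction", "detector_au", "camera_nm") %in% names(d)))
    stop_trapcal("deflection table needs columns direction,detector_au,camera_nm",
                 "format_error")
  d
}

#' Position distribution of a trapped bead
#'
#' Normalized histogram of the bead coordinate — the sampled stationary
#' (Boltzmann) distribution — with a Gaussian fit per detected mode. Bins
#' span at least mean +/- 5 standard deviations (extended to cover the data
#' range, so probabilities always sum to 1). Modes are local maxima of the
#' lightly smoothed histogram separated by at least 3 bins; one or two modes
#' are fitted (two wells arise when a non-ideal beam forms a pair of traps).
#'
#' @param x coordinate samples (any consistent units).
#' @param bins number of equal-width bins.
#' @return Object of class `position_distribution`: `mids`, `breaks`,
#'   `probabilities` (summing to 1), `bin_width`, `modes` (data frame with
#'   `mean`, `sd`, `weight` per mode) and `n`.
#' @export
position_distribution <- function(x, bins = 100) {
  if (!is.numeric(bins) || bins < 2) stop_trapcal("bins must be >= 2", "parameter_error")
  x <- x[is.finite(x)]
  if (length(x) < 2L || stats::sd(x) == 0)
    stop_trapcal("constant or empty input: no distribution to build",
                 "degenerate_data_error")
  if (length(x) < 100L)
    warn_trapcal("fewer than 100 samples: distribution will be noisy", "data_warning")
  lo <- min(mean(x) - 5 * stats::sd(x), min(x))
  hi <- max(mean(x) + 5 * stats::sd(x), max(x))
  breaks <- seq(lo, hi, length.out = bins + 1L)
  cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  prob <- cnt / length(x)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2

  # mode detection on a 3-bin smoothed histogram
  sm <- moving_average(prob, 2L, causal = FALSE)
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    lo_i <- max(1L, i - 3L); hi_i <- min(n, i + 3L)
    sm[i] > 0 && sm[i] == max(sm[lo_i:hi_i])
  }, TRUE)
  peaks <- which(is_max)
  # ignore stray tail bins; keep peaks separated by >= 3 bins, largest first
  peaks <- peaks[sm[peaks] >= 0.05 * max(sm)]
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  kept <- integer()
  for (p in peaks) if (all(abs(p - kept) >= 3L)) kept <- c(kept, p)
  kept <- sort(utils::head(kept, 2L))

  if (length(kept) == 2L) {
    valley <- which.min(sm[kept[1L]:kept[2L]]) + kept[1L] - 1L
    split <- mids[valley]
    groups <- list(x[x < split], x[x >= split])
  } else {
    groups <- list(x)
  }
  modes <- do.call(rbind, lapply(groups, function(g)
    data.frame(mean = mean(g), sd = stats::sd(g), weight = length(g) / length(x))))

  structure(list(mids = mids, breaks = breaks, probabilities = prob,
                 bin_width = diff(breaks[1:2]), modes = modes, n = length(x)),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  cat(sprintf("Position distribution: %d bins, %d samples, %d mode(s)\n",
              length(x$mids), x$n, nrow(x$modes)))
  for (i in seq_len(nrow(x$modes)))
    cat(sprintf("  mode %d: mean %.4g, sd %.4g, weight %.3g\n",
                i, x$modes$mean[i], x$modes$sd[i], x$modes$weight[i]))
  invisible(x)
}

#' @export
plot.position_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$probabilities, type = "h",
                 xlab = "position", ylab = "probability", ...)
  invisible(x)
}

#' Trap potential by Boltzmann inversion
#'
#' Inverts the stationary position distribution through the Boltzmann
#' relation \eqn{V(x) = -k_B T \ln(P(x)/P(x_{min}))}: the potential in
#' \eqn{k_B T} units is the negative log of the probability relative to its
#' maximum, with the minimum aligned to zero. Empty bins have undefined
#' potential and are returned as `NA`, never infinities.
#'
#' @param d a [position_distribution()].
#' @param temperature absolute temperature (K), kept for reporting the
#'   potential in joule or eV.
#' @return Object of class `trap_potential`: `x` (bin centres), `V`
#'   (potential in \eqn{k_B T} units, minimum 0, `NA` on empty bins),
#'   `x_min`, `temperature`.
#' @export
potential_from_distribution <- function(d, temperature) {
  stopifnot(inherits(d, "position_distribution"))
  check_positive_scalar(temperature, "temperature")
  p <- d$probabilities
  if (all(p == 0)) stop_trapcal("empty distribution", "data_error")
  pmax_ <- max(p)
  V <- ifelse(p > 0, -log(p / pmax_), NA_real_)
  structure(list(x = d$mids, V = V, x_min = d$mids[which.max(p)],
                 temperature = temperature),
            class = "trap_potential")
}

#' @export
print.trap_potential <- function(x, ...) {
  cat(sprintf("Trap potential: %d points (%d defined), minimum at %.4g\n",
              length(x$V), sum(!is.na(x$V)), x$x_min))
  invisible(x)
}

#' @export
plot.trap_potential <- function(x, ...) {
  graphics::plot(x$x, x$V, type = "b", pch = 16, cex = 0.5,
                 xlab = "position", ylab = expression(V ~ (k[B] * T)), ...)
  invisible(x)
}

#' Barrier height of a double-well trap potential
#'
#' Locates the two local minima of a reconstructed potential and returns the
#' maximum of the potential on the path between them (the potential minimum
#' being aligned to zero, this is the barrier above the global minimum). The
#' same number is also reported in eV via \eqn{k_B T} at the potential's
#' temperature.
#'
#' @param p a [trap_potential()] with two wells.
#' @param smooth half-width (bins) of the moving average applied before
#'   locating extrema, to keep bin noise from creating spurious minima.
#' @return Barrier height in \eqn{k_B T} units, with attribute `"eV"` and
#'   attribute `"minima"` (the two well positions).
#' @export
barrier_height <- function(p, smooth = 2) {
  stopifnot(inherits(p, "trap_potential"))
  ok <- which(!is.na(p$V))
  if (length(ok) < 5L) stop_trapcal("too few defined potential points", "data_error")
  V <- p$V[ok]; xx <- p$x[ok]
  Vs <- moving_average(V, 2L * smooth, causal = FALSE)
  n <- length(Vs)
  is_min <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 3L); hi <- min(n, i + 3L)
    Vs[i] == min(Vs[lo:hi]) && (i > 1L && i < n)
  }, TRUE)
  mins <- which(is_min)
  # collapse plateaus of adjacent minima
  if (length(mins) > 1L) mins <- mins[c(TRUE, diff(mins) > 3L)]
  if (length(mins) < 2L)
    stop_trapcal("potential has a single well: no barrier", "shape_error")
  mins <- mins[order(Vs[mins])][1:2]
  mins <- sort(mins)
  barrier <- max(V[mins[1L]:mins[2L]]) - 0
  structure(barrier,
            eV = barrier * .kB * p$temperature / .eV,
            minima = xx[mins])
}
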