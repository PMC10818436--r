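# Reference environment used throughout: the worked calibration example
# (water at 297.25 K, 3 um polystyrene bead).
ref_env <- function() trap_environment(297.25, 0.910e-3, 1.5e-6)

# Brute-force filter oracles: literal term-by-term evaluation of the
# difference equations, independent of the vectorised implementations.
bf_moving_average <- function(x, M, causal = TRUE) {
  n <- length(x)
  if (!causal) {
    h <- M %/% 2L
    return(vapply(seq_len(n), function(i)
      mean(x[max(1L, i - h):min(n, i + h)]), 0))
  }
  vapply(seq_len(n), function(i) mean(x[max(1L, i - M):i]), 0)
}

bf_fir <- function(x, b) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (k in seq_along(b)) {
      j <- i - k + 1L
      if (j >= 1L) acc <- acc + b[k] * x[j]
    }
    acc
  }, 0)
}

bf_iir <- function(x, b, a) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      j <- i - k + 1L
      if (j >= 1L) acc <- acc + b[k] * x[j]
    }
    for (l in seq_along(a)) {
      j <- i - l
      if (j >= 1L) acc <- acc - a[l] * y[j]
    }
    y[i] <- acc
  }
  y
}

# Exact one-sided spectrum of a sampled Ornstein-Uhlenbeck process with
# stationary variance s2 and relaxation rate lambda, observed at rate fs.
sampled_ou_spectrum <- function(f, lambda, s2, fs) {
  a <- exp(-lambda / fs)
  2 * s2 * (1 - a^2) / fs / (1 + a^2 - 2 * a * cos(2 * pi * f / fs))
}

# Build a power_spectrum object from analytic values (for fit oracles).
analytic_spectrum <- function(frequencies, density, fs, n) {
  structure(list(frequencies = frequencies, density = density, fs = fs, n = n),
            class = "power_spectrum")
}

# Compact double-well trap: separation 2.4 widths keeps the inter-well
# saddle far below the outer escape level (depth scales the barrier).
dw_trap <- function(depth_kBT, kBT, width = 1e-7, transverse = 3e-6) {
  d <- 2.4 * width
  trap_model(transverse,
             centers = rbind(c(-d / 2, 0), c(d / 2, 0)),
             well_depths = depth_kBT * kBT, well_widths = width)
}

# Synthetic binary-mixture viscosity data with exactly known structure:
# Arrhenius pure components and a cubic excess whose magnitude is itself
# Arrhenius in T, so every model stage can be inverted exactly.
synthetic_viscosity_data <- function() {
  temps <- c(288.15, 293.15, 298.15, 303.15, 308.15)
  eta_a <- function(tk) exp(-6.8 + 2000 / tk)   # ~ 1 Pa s scale
  eta_b <- function(tk) exp(-7.4 + 2600 / tk)
  exc <- function(xb, tk) -exp(-9 + 1500 / tk) * xb * (1 - xb) * (1 + 0.5 * (xb - 0.5))
  xb <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  rows <- list(data.frame(component = "A", x_b = 0, temperature_k = temps,
                          eta_pa_s = eta_a(temps)),
               data.frame(component = "B", x_b = 1, temperature_k = temps,
                          eta_pa_s = eta_b(temps)))
  for (tk in temps) {
    lin <- eta_a(tk) * (1 - xb) + eta_b(tk) * xb
    rows <- c(rows, list(data.frame(component = "mix", x_b = xb,
                                    temperature_k = tk,
                                    eta_pa_s = lin + exc(xb, tk))))
  }
  list(data = do.call(rbind, rows), eta_a = eta_a, eta_b = eta_b, excess = exc)
}
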