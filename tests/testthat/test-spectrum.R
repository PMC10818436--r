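test_that("PCA rotation aligns, preserves means and total variance", {
  # collinear cloud: 45 degrees, vanishing second eigenvalue
  v <- rnorm(50)
  r <- pca_rotate(v, v)
  expect_equal(r$rotation$angle, pi / 4)
  expect_equal(r$rotation$eigenvalues[2], 0, tolerance = 1e-12)

  # already-aligned anisotropic cloud: angle about zero
  set.seed(8)
  x <- rnorm(20000, sd = 3); y <- rnorm(20000, sd = 1)
  expect_lt(abs(pca_rotate(x, y)$rotation$angle), 0.02)

  # trace invariance and mean preservation on random data
  set.seed(9)
  x <- rnorm(500, mean = 2); y <- 0.4 * x + rnorm(500, mean = -1)
  r2 <- pca_rotate(x, y)
  expect_equal(var(r2$x) + var(r2$y), var(x) + var(y), tolerance = 1e-12)
  expect_equal(mean(r2$x), mean(x), tolerance = 1e-12)
  expect_equal(mean(r2$y), mean(y), tolerance = 1e-12)
  expect_equal(cov(r2$x, r2$y), 0, tolerance = 1e-15)

  expect_error(pca_rotate(rep(1, 10), rep(2, 10)),
               class = "trapcal_degenerate_data_error")
})

test_that("periodogram is one-sided and Parseval-normalized", {
  fs <- 1000
  # constant signal: all power in the DC bin
  ps <- power_spectrum(rep(2, 100), fs)
  expect_equal(ps$frequencies[1], 0)
  expect_lt(max(ps$density[-1]), 1e-12 * ps$density[1])

  # bin-centred unit sinusoid: one bin carrying total power 1/2
  n <- 1000
  t <- (0:(n - 1)) / fs
  f0 <- 50
  ps2 <- power_spectrum(sin(2 * pi * f0 * t), fs)
  df <- fs / n
  pw <- ps2$density * df
  k0 <- which.min(abs(ps2$frequencies - f0))
  expect_equal(pw[k0], 0.5, tolerance = 1e-9)
  expect_equal(sum(pw[-k0]), 0, tolerance = 1e-9)

  # Parseval: non-DC power equals the population variance
  set.seed(10)
  x <- rnorm(512)
  ps3 <- power_spectrum(x, fs)
  expect_equal(sum(ps3$density[-1]) * fs / 512, mean((x - mean(x))^2),
               tolerance = 1e-9)

  xbad <- x; xbad[37] <- NaN
  expect_error(power_spectrum(xbad, fs), "37", class = "trapcal_data_error")
})

test_that("spike removal edits exactly the outlier bins", {
  f <- seq(0, 500, by = 0.5)
  lor <- analytic_spectrum(f, 1e-4 / (50^2 + f^2), 1000, 2000)

  # a smooth noiseless Lorentzian is untouched
  clean <- remove_spikes(lor)
  expect_equal(clean$density, lor$density)
  expect_length(attr(clean, "replaced"), 0)

  # inject one spike: that bin becomes its exclusive flank average, nothing
  # else moves
  spiked <- lor
  k <- 400
  spiked$density[k] <- spiked$density[k] * 100
  ds <- remove_spikes(spiked)
  expect_equal(attr(ds, "replaced"), k)
  flank <- mean(spiked$density[c((k - 20):(k - 1), (k + 1):(k + 20))])
  expect_equal(ds$density[k], flank)
  expect_equal(ds$density[-k], spiked$density[-k])

  # idempotent on the repaired spectrum
  ds2 <- remove_spikes(ds)
  expect_equal(ds2$density, ds$density)

  short <- analytic_spectrum(0:10, rep(1, 11), 10, 22)
  expect_error(remove_spikes(short), class = "trapcal_parameter_error")
})

test_that("Lorentzian fit is exact on data from its own model", {
  f <- seq(0.5, 1000, by = 0.5)
  A <- 3.2e-5
  fc <- 46.27
  s <- analytic_spectrum(f, A / (fc^2 + f^2), 2500, 5000)
  fit <- fit_lorentzian(s, band = c(5, 600))
  expect_equal(fit$corner_frequency, fc, tolerance = 1e-7)
  expect_equal(fit$amplitude, A, tolerance = 1e-7)

  # scaling the density leaves the corner frequency unchanged
  s10 <- s; s10$density <- s$density * 137
  expect_equal(fit_lorentzian(s10, band = c(5, 600))$corner_frequency, fc,
               tolerance = 1e-9)

  # sampled basis is exact on the sampled-OU closed form
  fs <- 1e4
  fgrid <- seq(1, 2500, by = 0.25)
  samp <- analytic_spectrum(fgrid, sampled_ou_spectrum(fgrid, 2 * pi * fc, 1, fs),
                            fs, 2 * length(fgrid))
  fit2 <- fit_lorentzian(samp, band = c(5, 2500), basis = "sampled")
  expect_equal(fit2$corner_frequency, fc, tolerance = 1e-7)

  # a rising spectrum has no Lorentzian corner: fit failure is reported
  bad <- analytic_spectrum(f, 1e-9 * (1 + f^2 / 1e4), 2500, 5000)
  expect_error(fit_lorentzian(bad, band = c(5, 600)),
               class = "trapcal_fit_failure_error")
  expect_warning(fit_lorentzian(s, band = c(100, 600)),
                 class = "trapcal_band_warning")
})

test_that("stiffness follows kappa = 2 pi gamma0 fc (12 pi^2 eta r fc)", {
  env <- ref_env()
  kappa <- stiffness_from_corner(46.27, env)
  expect_equal(signif(kappa, 3), 7.48e-6)
  expect_equal(kappa, 12 * pi^2 * 0.910e-3 * 1.5e-6 * 46.27, tolerance = 1e-12)

  expect_error(stiffness_from_corner(0, env), class = "trapcal_parameter_error")

  # linear in the bead radius at fixed corner frequency
  env2 <- trap_environment(297.25, 0.910e-3, 3.0e-6)
  expect_equal(stiffness_from_corner(46.27, env2), 2 * kappa)
})
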