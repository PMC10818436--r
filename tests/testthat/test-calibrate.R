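test_that("equipartition relations reproduce the worked example and invert", {
  expect_equal(signif(sigma_from_stiffness(7.48e-6, 297.25), 3), 2.34e-8)

  # sqrt scaling and algebraic inversion
  expect_equal(sigma_from_stiffness(4 * 7.48e-6, 297.25),
               sigma_from_stiffness(7.48e-6, 297.25) / 2)
  expect_equal(stiffness_from_variance(2.34e-8, 297.25), 7.49e-6,
               tolerance = 2e-3)
  k0 <- 3.3e-6
  expect_equal(stiffness_from_variance(sigma_from_stiffness(k0, 300), 300), k0,
               tolerance = 1e-12)

  # simulation oracle: sample std of an OU run matches
  env <- ref_env()
  pos <- simulate_bead(trap_model(7.48e-6), env, fs = 1e4, duration = 20, seed = 2)
  expect_equal(sd(pos[, 1]), sigma_from_stiffness(7.48e-6, env$temperature),
               tolerance = 0.03)

  expect_error(sigma_from_stiffness(-1, 300), class = "trapcal_parameter_error")
  expect_error(stiffness_from_variance(0, 300), class = "trapcal_parameter_error")
})

test_that("sigma-method calibration constant is sigma_m over sigma_PSD", {
  # printed means of the worked example: 24.19 nm / 2.80 mV
  expect_equal(position_calibration_sigma(24.19e-9, 2.80), 8.639, tolerance = 1e-3)
  # matched arbitrary units give delta = 1
  expect_equal(position_calibration_sigma(5e-9, 5), 1)
  expect_error(position_calibration_sigma(1e-9, 0), class = "trapcal_parameter_error")

  # simulation oracle: detector gain 1/delta0 is recovered within 5%
  env <- ref_env()
  delta0 <- 8.68  # nm/mV
  det <- detector_model(gain = 1e-3 / (delta0 * 1e-9), noise_sd = 0)
  pos <- simulate_bead(trap_model(7.48e-6), env, fs = 1e4, duration = 20, seed = 5)
  tr <- simulate_detector(pos, det, seed = 6)
  sigma_psd_mv <- sd(tr$vertical) * 1e3
  sm <- sigma_from_stiffness(7.48e-6, env$temperature)
  expect_equal(position_calibration_sigma(sm, sigma_psd_mv), delta0,
               tolerance = 0.05)
})

test_that("averaging-window selection finds the noise-removal bend", {
  env <- ref_env()
  pos <- simulate_bead(trap_model(7.48e-6), env, fs = 1e4, duration = 20, seed = 1)
  sig <- pos[, 1]
  set.seed(501)
  noisy <- sig + rnorm(length(sig), sd = 5 * sd(sig))

  w <- select_averaging_window(noisy)
  expect_true(as.integer(w) %in% c(10, 20))

  # brute-force curvature oracle on the same candidate grid
  cand <- attr(w, "windows")
  ld <- sapply(cand, function(wi) -log(sd(moving_average(noisy, wi - 1))))
  lw <- log(cand)
  cur <- rep(NA_real_, length(cand))
  for (k in 2:(length(cand) - 1)) {
    d1 <- (ld[k] - ld[k - 1]) / (lw[k] - lw[k - 1])
    d2 <- (ld[k + 1] - ld[k]) / (lw[k + 1] - lw[k])
    cur[k] <- 2 * (d2 - d1) / (lw[k + 1] - lw[k - 1])
  }
  expect_equal(attr(w, "curvature"), cur)
  expect_equal(as.integer(w), cand[which.min(cur)])

  # noise-free record: featureless curve, smallest candidate with a warning
  expect_warning(w0 <- select_averaging_window(sig),
                 class = "trapcal_selection_warning")
  expect_equal(as.integer(w0), 1L)

  expect_error(select_averaging_window(noisy, windows = c(1, 5, 10)),
               class = "trapcal_parameter_error")
})

test_that("hydrodynamic calibration averages opposite-direction ratios", {
  tab <- data.frame(direction = c("left", "right", "down", "top"),
                    detector_au = c(0.363, 0.368, 0.417, 0.333),
                    camera_nm = c(380, 330, 620, 510))
  d <- hydrodynamic_calibration(tab)
  expect_equal(d[["horizontal"]], 972)
  expect_equal(d[["vertical"]], 1509)
  expect_equal(attr(d, "per_direction")[["left"]], 380 / 0.363)

  # equal per-direction ratios pass through exactly
  tab2 <- data.frame(direction = c("left", "right", "down", "top"),
                     detector_au = c(0.2, 0.4, 0.25, 0.5),
                     camera_nm = c(200, 400, 250, 500))
  expect_equal(as.numeric(hydrodynamic_calibration(tab2)), c(1000, 1000))

  # invariant under relabeling of the two opposite directions
  tab3 <- tab
  tab3$direction <- c("right", "left", "top", "down")
  expect_equal(attr(hydrodynamic_calibration(tab3), "unrounded"),
               attr(d, "unrounded"))

  tabz <- tab; tabz$detector_au[2] <- 0
  expect_error(hydrodynamic_calibration(tabz), class = "trapcal_parameter_error")
  expect_error(hydrodynamic_calibration(tab[1:2, ]), class = "trapcal_format_error")
})

test_that("position distributions normalize and fit their modes", {
  set.seed(20)
  x <- rnorm(50000, mean = 3, sd = 2)
  d <- position_distribution(x, bins = 100)
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
  expect_equal(nrow(d$modes), 1L)
  expect_equal(d$modes$mean, 3, tolerance = 0.01)
  expect_equal(d$modes$sd, 2, tolerance = 0.02)

  expect_error(position_distribution(rep(1, 500)),
               class = "trapcal_degenerate_data_error")
  expect_warning(position_distribution(rnorm(50)), class = "trapcal_data_warning")
})

test_that("Boltzmann inversion recovers a Gaussian and a double-well potential", {
  # exact Gaussian probabilities: V(sigma) = 0.5 kBT, curvature 1/sigma^2
  sig <- 2.5
  mids <- seq(-5 * sig, 5 * sig, length.out = 201)
  p <- exp(-mids^2 / (2 * sig^2)); p <- p / sum(p)
  d <- structure(list(mids = mids, probabilities = p,
                      bin_width = diff(mids[1:2]),
                      modes = data.frame(mean = 0, sd = sig, weight = 1),
                      n = 1e6), class = "position_distribution")
  pot <- potential_from_distribution(d, 297.25)
  expect_equal(min(pot$V, na.rm = TRUE), 0)
  expect_equal(pot$x_min, 0, tolerance = 1e-9)
  expect_equal(pot$V[which.min(abs(mids - sig))], 0.5, tolerance = 1e-6)
  quad <- lm(V ~ I(x^2), data = data.frame(x = pot$x, V = pot$V))
  expect_equal(coef(quad)[[2]], 1 / (2 * sig^2) * 1, tolerance = 1e-6)

  # empty bins come back NA, never infinite
  p2 <- p; p2[1:3] <- 0; p2 <- p2 / sum(p2)
  d2 <- d; d2$probabilities <- p2
  pot2 <- potential_from_distribution(d2, 297.25)
  expect_true(all(is.na(pot2$V[1:3])))
  expect_false(any(is.infinite(pot2$V)))

  dz <- d; dz$probabilities <- rep(0, length(p))
  expect_error(potential_from_distribution(dz, 297.25), class = "trapcal_data_error")

  # constructed double well: barrier recovered, and in eV
  env <- trap_environment(297.25, 0.910e-3, 0.5e-6)
  kBT <- env$k_B * env$temperature
  trap <- dw_trap(31.4, kBT)   # ~3 kBT barrier
  truth <- double_well_barrier(trap)$barrier / kBT
  s <- seq(-2.5e-7, 2.5e-7, length.out = 201)
  pb <- exp(-double_well_potential(trap, s) / kBT); pb <- pb / sum(pb)
  db <- structure(list(mids = s, probabilities = pb, bin_width = diff(s[1:2]),
                       modes = NULL, n = 1e6), class = "position_distribution")
  potb <- potential_from_distribution(db, env$temperature)
  b <- barrier_height(potb)
  expect_equal(as.numeric(b), truth, tolerance = 0.05)
  expect_equal(attr(b, "eV"), truth * kBT / 1.602176634e-19, tolerance = 0.05)
  expect_equal(sort(attr(b, "minima")), double_well_barrier(trap)$minima,
               tolerance = 0.05)

  # single well: shape error
  expect_error(barrier_height(pot), class = "trapcal_shape_error")
})
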