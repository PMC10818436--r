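test_that("moving average matches the brute-force difference equation", {
  expect_equal(moving_average(rep(3.7, 20), 5), rep(3.7, 20))
  expect_equal(moving_average(rep(3.7, 20), 6, causal = FALSE), rep(3.7, 20))

  # impulse with the shrinking-edge policy
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 2), c(0, 0, 1, 1, 1))

  set.seed(11)
  x <- rnorm(100)
  expect_equal(moving_average(x, 9), bf_moving_average(x, 9))
  expect_equal(moving_average(x, 4, causal = FALSE),
               bf_moving_average(x, 4, causal = FALSE))
  expect_message(y <- moving_average(x, 3, causal = FALSE), "odd")
  expect_equal(y, bf_moving_average(x, 4, causal = FALSE))

  expect_error(moving_average(x, -1), class = "trapcal_parameter_error")
})

test_that("blocking average compresses by the window and conserves the mean", {
  expect_equal(blocking_average(c(1, 2, 3, 4), 2), c(1.5, 3.5))

  # 100 kHz record blocked over 10 points -> 10 samples per millisecond
  x <- rnorm(100000)
  y <- blocking_average(x, 10)
  expect_length(y, 10000)
  expect_equal(mean(y), mean(x))  # window divides the length exactly

  # trailing remainder dropped
  expect_equal(blocking_average(1:7, 3), c(2, 5))

  expect_error(blocking_average(1:4, 5), class = "trapcal_parameter_error")
  expect_error(blocking_average(1:4, 0), class = "trapcal_parameter_error")
})

test_that("FIR design has unit DC gain and -6 dB at the cutoff", {
  for (M in c(10, 33, 64)) {
    sp <- design_fir_lowpass(1000, M, 1e4)
    expect_length(sp$b, M + 1)
    expect_equal(sum(sp$b), 1, tolerance = 1e-12)
  }
  # half-amplitude point sits at the design cutoff for the windowed design
  for (M in c(33, 64))
    expect_equal(filter_response(design_fir_lowpass(1000, M, 1e4), 1000, 1e4),
                 0.5, tolerance = 0.05)
  # uniform taps reduce the FIR equation to the moving average (past the
  # zero-padded start-up transient)
  set.seed(2)
  x <- rnorm(200)
  M <- 7
  yf <- fir_apply(x, rep(1 / (M + 1), M + 1))
  ym <- moving_average(x, M)
  expect_equal(yf[(M + 1):200], ym[(M + 1):200])

  expect_error(design_fir_lowpass(6000, 10, 1e4), class = "trapcal_parameter_error")
  # high-pass and band-stop complements
  hp <- design_fir_lowpass(1000, 34, 1e4, band = "high")
  expect_lt(filter_response(hp, 10, 1e4), 0.05)
  expect_gt(filter_response(hp, 4000, 1e4), 0.9)
  bs <- design_fir_lowpass(c(800, 1200), 64, 1e4, band = "stop")
  expect_lt(filter_response(bs, 1000, 1e4), 0.1)
})

test_that("FIR application is the literal convolution sum", {
  set.seed(3)
  x <- rnorm(60)
  expect_equal(fir_apply(x, 1), x)                      # identity
  expect_equal(fir_apply(x, c(0, 1)), c(0, x[-60]))     # one-sample delay
  b <- rnorm(8)
  expect_equal(fir_apply(x, b), bf_fir(x, b))
  expect_error(fir_apply(x, numeric()), class = "trapcal_parameter_error")
})

test_that("IIR application is the literal recursive difference equation", {
  set.seed(4)
  x <- rnorm(80)
  b <- c(0.2, 0.3, 0.1); a <- c(-0.5, 0.06)
  sp <- filter_spec("iir", b = b, a = a)
  expect_equal(iir_apply(x, sp), bf_iir(x, b, a))

  # empty feedback degenerates to FIR
  sp0 <- filter_spec("iir", b = b)
  expect_equal(iir_apply(x, sp0), fir_apply(x, b))

  # first-order smoother on a unit step: y_n = 1 - alpha^(n+1)
  alpha <- 0.8
  sm <- filter_spec("iir", b = 1 - alpha, a = -alpha)
  y <- iir_apply(rep(1, 30), sm)
  expect_equal(y, 1 - alpha^(1:30))

  # a pole outside the unit circle is refused
  bad <- filter_spec("iir", b = 1, a = -1.5)
  expect_error(iir_apply(x, bad), class = "trapcal_design_error")
})

test_that("Butterworth IIR design is a stable unit-DC-gain low-pass", {
  sp <- design_iir_lowpass(1000, 3, 1e4)
  dc <- sum(sp$b) / (1 + sum(sp$a))
  expect_equal(dc, 1, tolerance = 1e-9)
  expect_true(all(Mod(polyroot(c(rev(sp$a), 1))) < 1))

  set.seed(5)
  noise <- rnorm(5000)
  expect_lt(var(iir_apply(noise, sp)), var(noise))

  step <- iir_apply(rep(1, 400), sp)
  expect_equal(step[400], 1, tolerance = 1e-6)
})

test_that("all filters are linear operators", {
  set.seed(6)
  x <- rnorm(120); z <- rnorm(120)
  al <- 2.5; be <- -1.3
  fir <- design_fir_lowpass(500, 12, 1e4)
  iir <- design_iir_lowpass(500, 3, 1e4)
  apply_all <- list(
    ma = function(v) moving_average(v, 6),
    block = function(v) blocking_average(v, 6),
    fir = function(v) fir_apply(v, fir),
    iir = function(v) iir_apply(v, iir))
  for (fn in apply_all)
    expect_equal(fn(al * x + be * z), al * fn(x) + be * fn(z), tolerance = 1e-10)
})

test_that("causal moving average equals blocking at block-end indices", {
  set.seed(7)
  x <- rnorm(100)
  w <- 5
  ma <- moving_average(x, w - 1)
  bl <- blocking_average(x, w)
  expect_equal(ma[seq(w, 100, by = w)], bl)
})

test_that("every denoising method removes noise-band power but keeps the Lorentzian plateau", {
  env <- ref_env()
  fs <- 1e4
  pos <- simulate_bead(trap_model(7.48e-6), env, fs = fs, duration = 10, seed = 21)
  sig <- pos[, 1]
  set.seed(22)
  noise <- rnorm(length(sig), sd = 3 * sd(sig))
  x <- sig + noise

  plateau <- function(v, f) {
    ps <- power_spectrum(v - mean(v), f)
    keep <- ps$frequencies >= 10 & ps$frequencies <= 40
    mean(ps$density[keep])
  }
  p0 <- plateau(x, fs)

  fir <- design_fir_lowpass(1000, 33, fs)
  iir <- design_iir_lowpass(1000, 3, fs)
  methods <- list(
    ma = function(v) moving_average(v, 9),
    fir = function(v) fir_apply(v, fir),
    iir = function(v) iir_apply(v, iir))
  for (nm in names(methods)) {
    y <- methods[[nm]](x)
    # noise suppression: the filtered pure-noise record shrinks
    expect_lt(var(methods[[nm]](noise)), 0.5 * var(noise))
    # low-frequency plateau preserved within 5%
    expect_equal(plateau(y, fs), p0, tolerance = 0.05)
  }
  yb <- blocking_average(x, 10)
  expect_equal(plateau(yb, fs / 10), p0, tolerance = 0.05)
  expect_lt(var(blocking_average(noise, 10)), 0.5 * var(noise))
})
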