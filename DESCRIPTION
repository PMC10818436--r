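Package: trapcal
Title: Calibration and Signal Processing for Optical-Tweezers Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for calibrating optical-tweezers (laser-trap) instruments
    from position-sensing detector recordings of a trapped microsphere.
    Implements the power-spectrum method of trap-stiffness determination
    (one-sided periodogram, spectral spike removal, Lorentzian corner-frequency
    fitting including the exact spectrum of a discretely sampled harmonic
    trap), equipartition (sigma-method) and hydrodynamic position calibration,
    Boltzmann inversion of the trap potential from position histograms, the
    digital filters used in trajectory denoising (moving average, blocking
    average, FIR and IIR low-pass), a mixed-solvent viscosity model (excess
    viscosity polynomials with simplified Vogel-Fulcher-Tammann temperature
    interpolation), and a Brownian-dynamics simulator of a bead in one or two
    optical traps observed through a noisy detector, so that the whole
    pipeline can be exercised without instrument hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
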