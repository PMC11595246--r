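Package: tdraman
Title: Time-Domain Coherent Raman Hyperspectral Acquisition Simulation and Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-pixel hyperspectral point-scanning microscopy in
    which a fast acousto-optic delay line sweeps the pump-probe delay at every
    macro-pixel, so that raw frames arrive as "time-wrapped" 2D records of
    shape (Nx*Ntau) x Ny. Provides the acquisition-physics calculators (delay
    scaling, electronic bandwidth and Nyquist limits, macro-pixel geometry), a
    synthetic-data generator emulating damped-sinusoid refractive-index
    transients detected as their first time derivative, trigger-edge
    registration of raw records into co-registered hyperspectral cubes
    tolerant to per-line clock jitter and truncated final lines, and spectral
    processing: transmission normalization, multi-window stitching with
    modified-Akima interpolation, Tukey masking of the pump-probe overlap
    artifact, zero-padded FFT spectra, frequency-slice chemical images and
    ROI-averaged spectra. Includes a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
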