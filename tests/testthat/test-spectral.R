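test_that("transmission normalization divides only above the validity floor", {
  # constant transmission 0.5 exactly doubles the trace
  r <- sin(seq(0, 6, length.out = 100))
  out <- normalize_by_transmission(r, rep(0.5, 100))
  expect_true(all(out$valid))
  expect_equal(out$values, 2 * r)
  # envelope zeros at the window edges become invalid, never infinite
  env <- transmission_envelope(100, 0.2)
  out2 <- normalize_by_transmission(r * env, env)
  expect_false(out2$valid[1])
  expect_false(out2$valid[100])
  expect_true(all(is.finite(out2$values[out2$valid])))
  expect_equal(out2$values[out2$valid], r[out2$valid])
  expect_error(normalize_by_transmission(r, rep(0, 100), pixel = "(1,1)"),
               "floor")
  expect_error(normalize_by_transmission(r, rep(0.5, 99)), "equal length")
})

test_that("normalized simulator traces recover the ground-truth transient", {
  cfg <- tiny_config(nx = 3L, ny = 2L)
  ph <- uniform_phantom(cfg, list(vibrational_line(90, 1, 10)), 0.8)
  raw <- simulate_acquisition(ph, cfg, quiet_noise())
  cubes <- reshape_to_cubes(raw)
  nrm <- normalize_by_transmission(cubes$raman_cube[2, 2, ],
                                   cubes$transmission_cube[2, 2, ])
  gt <- raw$ground_truth$transient[2, 2, ]
  err <- abs(nrm$values[nrm$valid] - gt[nrm$valid])
  expect_lt(max(err) / max(abs(gt)), 1e-10)
})

test_that("single-window stitching is the identity on valid samples", {
  cfg <- tiny_config(nx = 1L, ny = 1L)
  ax <- build_delay_axis(cfg, 0L)
  vals <- cos(ax$values / 100)
  valid <- transmission_envelope(270, 0.2) >= 0.05
  st <- stitch_windows(list(list(values = vals, valid = valid)), list(ax))
  expect_s3_class(st, "stitched_trace")
  expect_identical(st$values, vals[valid])
  expect_identical(st$delay, ax$values[valid])
  expect_length(st$junctions, 0)
})

test_that("two-window stitching matches the analytic transient to <1% RMS", {
  cfg <- acquisition_config(n_macro_x = 1L, n_lines_y = 1L, n_windows = 2L)
  lines <- list(vibrational_line(90, 1, 100))
  ph <- phantom(matrix("s", 1, 1), list(s = lines))
  raw <- simulate_acquisition(ph, cfg, quiet_noise(), overlap_amplitude = 0)
  cubes <- reshape_to_cubes(raw)
  axes <- lapply(0:1, build_delay_axis, config = cfg)
  traces <- envs <- vector("list", 2)
  for (w in 1:2) {
    sl <- ((w - 1) * 270 + 1):(w * 270)
    traces[[w]] <- normalize_by_transmission(cubes$raman_cube[1, 1, sl],
                                             cubes$transmission_cube[1, 1, sl])
    envs[[w]] <- cubes$transmission_cube[1, 1, sl]
  }
  st <- stitch_windows(traces, axes, envs)
  # oracle: the analytic damped-cosine derivative on the stitched axis
  oracle <- transient_trace(lines, make_axis(st$delay), overlap_amplitude = 0)
  rms <- sqrt(mean((st$values - oracle)^2))
  expect_lt(rms / max(abs(oracle)), 0.01)
  # one junction between the two windows, inside their overlap
  expect_length(st$junctions, 1)
  expect_gt(st$crossings, 3000)
  expect_lt(st$crossings, 4500)
  # delays uniform and strictly increasing across the junction
  expect_equal(diff(st$delay), rep(delay_step(cfg), length(st$delay) - 1))
  # continuity: no junction jump beyond the largest interior jump
  jumps <- abs(diff(st$values))
  at_junction <- jumps[pmax(1, st$junctions - 3):pmin(length(jumps), st$junctions + 3)]
  expect_lte(max(at_junction), max(jumps))
  # non-overlapping windows refuse to stitch
  cfg_gap <- acquisition_config(n_macro_x = 1L, n_lines_y = 1L,
                                n_windows = 2L, mechanical_step = 6)
  axes_gap <- lapply(0:1, build_delay_axis, config = cfg_gap)
  expect_error(stitch_windows(traces, axes_gap, envs), "overlap")
})

test_that("tukey window matches the reference and its limits", {
  # frozen oracle: scipy 1.17 signal.windows.tukey
  expect_equal(tukey_window(11, 0.5),
               c(0, 0.345491502812526, 0.904508497187474, 1, 1, 1, 1, 1,
                 0.904508497187474, 0.345491502812526, 0),
               tolerance = 1e-12)
  expect_equal(tukey_window(9, 0.25), c(0, rep(1, 7), 0), tolerance = 1e-12)
  expect_equal(tukey_window(64, 0), rep(1, 64))
  w <- tukey_window(128, 0.1)
  expect_equal(w, rev(w))
  expect_error(tukey_window(10, 1.5), "alpha")
})

test_that("overlap masking gates, de-means and tapers the retained region", {
  delay <- seq(0, 4500, by = 4500 / 270)[1:270]
  values <- 5 + cos(delay / 80)
  tr <- list(delay = delay, values = values)
  # alpha = 0 is a rectangular gate at the cut
  m0 <- mask_overlap(tr, cut_delay = 300, tukey_alpha = 0)
  keep <- delay >= 300
  expect_true(all(m0$values[!keep] == 0))
  expect_equal(m0$values[keep], values[keep] - mean(values[keep]))
  # tapered version is bounded by the gated one and zero at the ends
  m1 <- mask_overlap(tr, cut_delay = 300, tukey_alpha = 0.1)
  expect_lte(max(abs(m1$values)), max(abs(m0$values)) + 1e-12)
  expect_equal(m1$values[which(keep)[1]], 0)
  # all-zero trace stays all-zero
  z <- mask_overlap(list(delay = delay, values = numeric(270)), 300, 0.1)
  expect_true(all(z$values == 0))
  expect_error(mask_overlap(tr, cut_delay = 9000), "beyond")
})

test_that("masking the overlap spike leaves the peak position unchanged", {
  sp_spike <- pixel_spectrum(list(vibrational_line(90, 1, 10)))
  sp_clean <- pixel_spectrum(list(vibrational_line(90, 1, 10)),
                             overlap_amplitude = 0)
  p1 <- peak_stats(sp_spike, c(10, 150))$position
  p2 <- peak_stats(sp_clean, c(10, 150))$position
  expect_lt(abs(p1 - p2), sp_spike$wavenumber[2])   # within one bin
})

test_that("spectra obey DFT peak placement and Parseval's identity", {
  dt <- 4500 / 270
  delay <- (0:511) * dt
  omega <- 2 * pi * frequency_from_wavenumber(120) * 1e12 * 1e-15  # rad/fs
  tr <- list(delay = delay, values = cos(omega * delay))
  sp <- compute_spectrum(tr, pad_factor = 8)
  expect_equal(sp$wavenumber[1], 0)
  bin <- diff(sp$wavenumber[1:2])
  expect_lt(abs(peak_stats(sp, c(50, 200))$position - 120), bin)
  # Parseval: time-domain energy equals (1/N) x full DFT energy
  npad <- sp$metadata$n_padded
  one_sided <- sp$magnitude^2
  total <- one_sided[1] + one_sided[length(one_sided)] +
    2 * sum(one_sided[2:(length(one_sided) - 1)])
  expect_equal(sum(tr$values^2), total / npad, tolerance = 1e-10)
  # power mode is the squared magnitude
  sp_pow <- compute_spectrum(tr, pad_factor = 8, mode = "power")
  expect_equal(sp_pow$magnitude, sp$magnitude^2)
  expect_error(compute_spectrum(list(delay = cumsum(runif(64, 0.5, 1.5)),
                                     values = rnorm(64))),
               "non-uniform")
})

test_that("peak FWHM follows the trace length and triangle geometry", {
  # symmetric triangle of base 2w has FWHM w on the given values
  w_axis <- seq(0, 200, by = 0.5)
  tri <- pmax(0, 1 - abs(w_axis - 100) / 40)
  sp_tri <- structure(list(wavenumber = w_axis, magnitude = tri,
                           metadata = list()), class = "raman_spectrum")
  st <- peak_stats(sp_tri, c(20, 180))
  expect_equal(st$position, 100)
  expect_equal(st$fwhm, 40, tolerance = 1e-9)
  expect_equal(st$height, 1)
  expect_false(st$on_edge)
  # undamped cosine: doubling the trace length halves the FWHM (within 5%)
  dt <- 4500 / 270
  omega <- 2 * pi * frequency_from_wavenumber(90) * 1e12 * 1e-15
  mk <- function(n) list(delay = (0:(n - 1)) * dt,
                         values = cos(omega * (0:(n - 1)) * dt))
  f1 <- peak_stats(compute_spectrum(mk(256), 8), c(40, 140))$fwhm
  f2 <- peak_stats(compute_spectrum(mk(512), 8), c(40, 140))$fwhm
  expect_equal(f1 / f2, 2, tolerance = 0.05)
  # band edge peaks are flagged
  st_edge <- peak_stats(sp_tri, c(100.25, 180))
  expect_true(st_edge$on_edge)
  expect_error(peak_stats(sp_tri, c(-10, 500)), "outside")
})

test_that("process_cube equals the manually composed chain and shares one axis", {
  cfg <- tiny_config(nx = 2L, ny = 2L)
  ph <- uniform_phantom(cfg, list(vibrational_line(56, 1, 5)), 0.9)
  raw <- simulate_acquisition(ph, cfg, quiet_noise())
  cubes <- reshape_to_cubes(raw)
  hc <- process_cube(cubes)
  # manual chain on pixel (1, 2)
  ax <- build_delay_axis(cfg, 0L)
  nrm <- normalize_by_transmission(cubes$raman_cube[1, 2, ],
                                   cubes$transmission_cube[1, 2, ])
  st <- stitch_windows(list(nrm), list(ax))
  sp <- compute_spectrum(mask_overlap(st, 300, 0.1), 8)
  expect_equal(hc$values[1, 2, ], sp$magnitude)
  expect_equal(hc$wavenumber, sp$wavenumber)
  expect_equal(hc$n_flagged, 0L)
  expect_true(all(is.finite(hc$values)))
})

test_that("frequency slices smooth, normalize and preserve raw values on demand", {
  cfg <- acquisition_config(n_macro_x = 16L, n_lines_y = 16L, fov = 128)
  ph <- phantom_two_species(cfg)
  raw <- simulate_acquisition(ph, cfg, quiet_noise())
  hc <- process_cube(reshape_to_cubes(raw))
  # no smoothing + no normalization returns the raw cube slice
  bin <- which.min(abs(hc$wavenumber - 56))
  img_raw <- frequency_slice(hc, 56, smooth = FALSE, normalize = "none")
  expect_equal(unclass(img_raw)[, ], hc$values[, , bin],
               ignore_attr = TRUE)
  # image-max normalization puts the brightest pixel at 1
  img_n <- frequency_slice(hc, 56, normalize = "image-max")
  expect_equal(max(img_n), 1)
  # cube-max never exceeds image-max scaling
  img_c <- frequency_slice(hc, 56, normalize = "cube-max")
  expect_lte(max(img_c), 1)
  # chemical contrast: each species lights up at its own line
  roi_a <- phantom_roi(ph, "acetaminophen")
  roi_b <- phantom_roi(ph, "anthracene")
  img56 <- frequency_slice(hc, 56, normalize = "none")
  expect_gte(mean(img56[roi_a]), 5 * mean(img56[roi_b]))
  img37 <- frequency_slice(hc, 37, normalize = "none")
  expect_gte(mean(img37[roi_b]), 5 * mean(img37[roi_a]))
  expect_error(frequency_slice(hc, 1e5), "outside")
})

test_that("ROI spectra average per-pixel spectra exactly", {
  cfg <- tiny_config(nx = 3L, ny = 3L)
  ph <- uniform_phantom(cfg, list(vibrational_line(90, 1, 10)), 0.8)
  hc <- process_cube(reshape_to_cubes(simulate_acquisition(ph, cfg, quiet_noise())))
  # single-pixel ROI returns that pixel's spectrum
  roi1 <- matrix(FALSE, 3, 3); roi1[2, 3] <- TRUE
  expect_equal(roi_spectrum(hc, roi1)$magnitude, hc$values[2, 3, ])
  # brute-force mean oracle over a rectangular ROI
  roi <- matrix(FALSE, 3, 3); roi[1:2, 2:3] <- TRUE
  manual <- (hc$values[1, 2, ] + hc$values[1, 3, ] +
               hc$values[2, 2, ] + hc$values[2, 3, ]) / 4
  expect_equal(roi_spectrum(hc, roi)$magnitude, manual)
  expect_error(roi_spectrum(hc, matrix(FALSE, 3, 3)), "no valid pixel")
})

test_that("whole-field ROI of the two-species phantom shows both signatures", {
  cfg <- acquisition_config(n_macro_x = 16L, n_lines_y = 16L, fov = 128)
  ph <- phantom_two_species(cfg)
  hc <- process_cube(reshape_to_cubes(simulate_acquisition(ph, cfg, quiet_noise())))
  sp <- roi_spectrum(hc, matrix(TRUE, 16, 16))
  bin <- diff(sp$wavenumber[1:2])
  sel <- function(lo, hi) sp$wavenumber >= lo & sp$wavenumber <= hi
  # local maxima near both species' lines
  p56 <- sp$wavenumber[sel(46, 66)][which.max(sp$magnitude[sel(46, 66)])]
  p37 <- sp$wavenumber[sel(27, 46)][which.max(sp$magnitude[sel(27, 46)])]
  expect_lt(abs(p56 - 56), 2 * bin)
  expect_lt(abs(p37 - 37), 2 * bin)
})
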