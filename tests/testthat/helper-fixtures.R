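# Shared fixture builders: everything generated in code, nothing on disk.

tiny_config <- function(nx = 4L, ny = 3L, nt = 270L, nw = 1L, fov = 64, ...) {
  acquisition_config(n_macro_x = nx, n_lines_y = ny, n_delay_samples = nt,
                     n_windows = nw, fov = fov, ...)
}

# delay axis over arbitrary values, for oracle evaluation
make_axis <- function(values, origin = 0) {
  structure(list(values = values, origin = origin,
                 spacing = if (length(values) > 1) values[2] - values[1] else 1,
                 window_index = 0L),
            class = "delay_axis")
}

# one-species phantom covering the whole grid
uniform_phantom <- function(config, lines, transmission = 1) {
  phantom(matrix("s", config$n_lines_y, config$n_macro_x),
          list(s = lines),
          matrix(transmission, config$n_lines_y, config$n_macro_x))
}

quiet_noise <- function(seed = 1L, jitter = 0L)
  noise_model(raman_sigma = 0, transmission_sigma = 0, jitter_max = jitter,
              seed = seed)

# single-pixel end-to-end spectrum for a list of lines
pixel_spectrum <- function(lines, nw = 1L, mode = "magnitude", seed = 1L,
                           noise = quiet_noise(seed), pad_factor = 8, ...) {
  cfg <- acquisition_config(n_macro_x = 1L, n_lines_y = 1L, n_windows = nw)
  ph <- phantom(matrix("s", 1, 1), list(s = lines))
  raw <- simulate_acquisition(ph, cfg, noise, ...)
  hc <- process_cube(reshape_to_cubes(raw), mode = mode,
                     pad_factor = pad_factor)
  roi_spectrum(hc, matrix(TRUE, 1, 1))
}
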