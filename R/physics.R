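# Acquisition timing/geometry model and unit conversions for time-domain
# coherent Raman imaging with an acousto-optic fast delay line.

# speed of light, m/s
C_M_S <- 299792458

#' Acquisition configuration
#'
#' Bundles the scan geometry and delay-line timing of a time-wrapped
#' hyperspectral acquisition: the scanner dwells on each X macro-pixel for one
#' complete delay scan of the acousto-optic delay line, so raw frames have
#' `n_macro_x * n_delay_samples * n_windows` columns per scanned line.
#'
#' @param n_macro_x Number of macro-pixels Nx along the (slowed) X axis.
#' @param n_lines_y Number of scan lines Ny.
#' @param n_delay_samples Samples Ntau acquired per delay window (default 270).
#' @param window_duration Laboratory time of one delay scan, us (default 25);
#'   equal to the macro-pixel dwell time.
#' @param delay_span Optical delay covered by one window, ps (default 4.5).
#' @param delay_scaling alpha_t: optical delay advanced per unit laboratory
#'   time, fs/us (default 161). Used for electronic-frequency conversions.
#' @param fov Field of view along X, um.
#' @param n_windows Number of delay windows recorded per macro-pixel, offset
#'   from one another by `mechanical_step`.
#' @param mechanical_step Mechanical delay increment between successive
#'   windows, ps (default 3).
#' @param mod_freq Amplitude-modulation frequency of the pump, MHz (default 12).
#' @param lia_integration Lock-in integration time, ns (default 100).
#' @param detection_filter Electronic low-pass bandwidth, MHz (default 1).
#' @param trigger_lead Samples by which the trigger edge precedes data
#'   validity (default 0).
#'
#' @details `delay_span` and `delay_scaling` are carried as independent
#'   calibration fields: the delay axis is built from `delay_span /
#'   n_delay_samples`, while `delay_scaling` enters only the
#'   electronic-frequency conversions. See the methods vignette.
#'
#' @return An object of class `acquisition_config`.
#' @seealso [build_delay_axis()], [electronic_frequency()]
#' @export
acquisition_config <- function(n_macro_x = 64L, n_lines_y = 64L,
                               n_delay_samples = 270L, window_duration = 25,
                               delay_span = 4.5, delay_scaling = 161,
                               fov = 500, n_windows = 1L, mechanical_step = 3,
                               mod_freq = 12, lia_integration = 100,
                               detection_filter = 1, trigger_lead = 0L) {
  cfg <- list(
    n_macro_x = as.integer(n_macro_x), n_lines_y = as.integer(n_lines_y),
    n_delay_samples = as.integer(n_delay_samples),
    window_duration = as.numeric(window_duration),
    delay_span = as.numeric(delay_span),
    delay_scaling = as.numeric(delay_scaling), fov = as.numeric(fov),
    n_windows = as.integer(n_windows),
    mechanical_step = as.numeric(mechanical_step),
    mod_freq = as.numeric(mod_freq),
    lia_integration = as.numeric(lia_integration),
    detection_filter = as.numeric(detection_filter),
    trigger_lead = as.integer(trigger_lead)
  )
  counts <- c("n_macro_x", "n_lines_y", "n_delay_samples", "n_windows")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("`", f, "` must be a count >= 1", call. = FALSE)
  }
  pos <- c("window_duration", "delay_span", "delay_scaling", "fov",
           "mod_freq", "lia_integration", "detection_filter")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("`", f, "` must be > 0", call. = FALSE)
  }
  if (cfg$trigger_lead < 0L) stop("`trigger_lead` must be >= 0", call. = FALSE)
  structure(cfg, class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n")
  cat(sprintf("  grid: %d macro-pixels x %d lines, %d delay samples, %d window(s)\n",
              x$n_macro_x, x$n_lines_y, x$n_delay_samples, x$n_windows))
  cat(sprintf("  window: %g us covering %g ps (step %g fs); mechanical step %g ps\n",
              x$window_duration, x$delay_span, delay_step(x), x$mechanical_step))
  cat(sprintf("  delay scaling alpha_t = %g fs/us; FOV %g um (macro-pixel %.3g um)\n",
              x$delay_scaling, x$fov, macro_pixel_length(x$fov, x$n_macro_x)))
  invisible(x)
}

#' Per-sample optical delay step
#'
#' @param config An [acquisition_config()].
#' @return Delay increment between consecutive samples within a window, fs.
#' @export
delay_step <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  config$delay_span * 1000 / config$n_delay_samples
}

#' Convert a vibration frequency to a Raman shift
#'
#' @param f Vibration frequency, THz (non-negative).
#' @return Raman shift in cm^-1: `f * 1e12 / (100 * c)`.
#' @examples
#' wavenumber_from_frequency(29) # ~967 cm^-1
#' @export
wavenumber_from_frequency <- function(f) {
  if (any(f < 0)) stop("frequency must be >= 0", call. = FALSE)
  f * 1e12 / (100 * C_M_S)
}

#' Convert a Raman shift to a vibration frequency
#'
#' Exact inverse of [wavenumber_from_frequency()].
#'
#' @param shift Raman shift, cm^-1 (non-negative).
#' @return Vibration frequency, THz.
#' @export
frequency_from_wavenumber <- function(shift) {
  if (any(shift < 0)) stop("Raman shift must be >= 0", call. = FALSE)
  shift * 100 * C_M_S / 1e12
}

#' Electronic frequency of a vibration after delay scaling
#'
#' The acousto-optic delay line advances the optical delay by `scaling` fs per
#' us of laboratory time, so a vibration at optical frequency nu appears on
#' the photodiode at the down-scaled electronic frequency nu * scaling * 1e-9.
#'
#' @param shift Raman shift, cm^-1 (non-negative).
#' @param scaling Delay scaling alpha_t, fs/us (positive; default 161).
#' @return Electronic frequency, MHz.
#' @examples
#' electronic_frequency(160, 161) # ~0.77 MHz
#' @export
electronic_frequency <- function(shift, scaling = 161) {
  if (any(shift < 0)) stop("Raman shift must be >= 0", call. = FALSE)
  if (any(!is.finite(scaling)) || any(scaling <= 0))
    stop("`scaling` must be > 0", call. = FALSE)
  # optical frequency (Hz) times the dimensionless lab/optical time ratio, in MHz
  shift * 100 * C_M_S * scaling * 1e-15
}

#' Maximum Raman shift passed by an electronic low-pass filter
#'
#' Inverse of [electronic_frequency()] at the filter edge.
#'
#' @param filter_bw Electronic filter bandwidth, MHz (positive).
#' @param scaling Delay scaling alpha_t, fs/us (positive; default 161).
#' @return Raman shift, cm^-1.
#' @examples
#' max_shift_for_filter(1, 161) # ~207 cm^-1
#' @export
max_shift_for_filter <- function(filter_bw, scaling = 161) {
  if (any(!is.finite(filter_bw)) || any(filter_bw <= 0))
    stop("`filter_bw` must be > 0", call. = FALSE)
  if (any(!is.finite(scaling)) || any(scaling <= 0))
    stop("`scaling` must be > 0", call. = FALSE)
  filter_bw / (100 * C_M_S * scaling * 1e-15)
}

#' Nyquist-limited maximum Raman shift for a delay sampling step
#'
#' @param delay_step Per-sample optical delay increment, fs (positive).
#' @return Raman shift, cm^-1, of the highest resolvable vibration
#'   `1/(2 * delay_step)`.
#' @export
nyquist_max_shift <- function(delay_step) {
  if (any(!is.finite(delay_step)) || any(delay_step <= 0))
    stop("`delay_step` must be > 0", call. = FALSE)
  wavenumber_from_frequency(1 / (2 * delay_step * 1e-15) / 1e12)
}

#' Macro-pixel length along X
#'
#' During one delay scan the X mirror keeps moving, elongating the point
#' spread function into a macro-pixel of length FOV / Nx.
#'
#' @param fov Field of view along X, um (positive).
#' @param n_macro_x Number of macro-pixels (>= 1).
#' @return Macro-pixel length, um.
#' @export
macro_pixel_length <- function(fov, n_macro_x) {
  if (any(!is.finite(fov)) || any(fov <= 0)) stop("`fov` must be > 0", call. = FALSE)
  if (any(n_macro_x < 1)) stop("`n_macro_x` must be >= 1", call. = FALSE)
  fov / n_macro_x
}

#' PSF aspect ratio of the macro-pixel
#'
#' @param fov Field of view along X, um.
#' @param n_macro_x Number of macro-pixels.
#' @param y_resolution Optical resolution along Y, um (default 1).
#' @return Dimensionless X/Y aspect ratio of the elongated PSF.
#' @export
psf_aspect_ratio <- function(fov, n_macro_x, y_resolution = 1) {
  if (y_resolution <= 0) stop("`y_resolution` must be > 0", call. = FALSE)
  macro_pixel_length(fov, n_macro_x) / y_resolution
}

#' Build the optical delay axis of one window
#'
#' Sample k (0-based) of window w sits at
#' `w * mechanical_step + k * delay_span / n_delay_samples`
#' (left-aligned, half-open convention: the trigger marks the scan start).
#'
#' @param config An [acquisition_config()].
#' @param window_index 0-based window index, `< n_windows`.
#' @return An object of class `delay_axis`: list with `values` (fs, strictly
#'   increasing, uniform), `origin` (delay of pump-probe overlap, fs),
#'   `spacing` (fs) and `window_index`.
#' @export
build_delay_axis <- function(config, window_index = 0L) {
  stopifnot(inherits(config, "acquisition_config"))
  window_index <- as.integer(window_index)
  if (is.na(window_index) || window_index < 0L ||
      window_index >= config$n_windows)
    stop("`window_index` must be in [0, n_windows); got ", window_index,
         call. = FALSE)
  dt <- delay_step(config)
  offset <- window_index * config$mechanical_step * 1000
  structure(
    list(values = offset + (seq_len(config$n_delay_samples) - 1) * dt,
         origin = 0, spacing = dt, window_index = window_index),
    class = "delay_axis"
  )
}

#' @export
print.delay_axis <- function(x, ...) {
  cat(sprintf("<delay_axis> window %d: %d samples, %.4g..%.4g fs (step %.4g fs)\n",
              x$window_index, length(x$values), x$values[1],
              x$values[length(x$values)], x$spacing))
  invisible(x)
}

#' Read / write an acquisition configuration as JSON
#'
#' The document carries exactly the `acquisition_config` field names.
#'
#' @param config An [acquisition_config()].
#' @param path File path.
#' @return `read_config` returns an [acquisition_config()];
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "acquisition_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(acquisition_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
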