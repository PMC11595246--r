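# Synthetic raw-data generator: time-wrapped scan records with trigger and
# transmission channels, per-line clock jitter and a truncated final line.

#' Refractive-index transient of a set of vibrational lines
#'
#' The impulsively excited vibrations produce a refractive-index modulation
#' `sum_i A_i exp(-tau/T2_i) sin(2 pi nu_i tau + phi_i)` for tau >= 0 (zero
#' before the pump arrives).
#'
#' @param lines List of [vibrational_line()]s (may be empty).
#' @param axis A `delay_axis` (see [build_delay_axis()]).
#' @return Numeric vector, one value per axis sample.
#' @export
refractive_index_transient <- function(lines, axis) {
  stopifnot(inherits(axis, "delay_axis"))
  tau <- axis$values - axis$origin
  out <- numeric(length(tau))
  pos <- tau >= 0
  for (ln in lines) {
    omega <- 2 * pi * ln$center * 100 * C_M_S * 1e-15   # rad/fs
    t2 <- ln$dephasing_time * 1000                      # fs
    out[pos] <- out[pos] + ln$amplitude * exp(-tau[pos] / t2) *
      sin(omega * tau[pos] + ln$phase)
  }
  out
}

#' Detected time trace: derivative transient plus overlap spike
#'
#' Spectral-shift detection reads the *first time derivative* of the
#' refractive-index transient, evaluated analytically, plus a Gaussian
#' pump-probe overlap artifact centred at zero delay.
#'
#' @param lines List of [vibrational_line()]s; an empty list yields the pure
#'   spike.
#' @param axis A `delay_axis`.
#' @param overlap_width FWHM of the Gaussian overlap spike, fs (default 170,
#'   the laser pulse duration).
#' @param overlap_amplitude Spike amplitude; default 10x the largest line's
#'   peak derivative amplitude (`A_i * omega_i`), or 1 if no lines.
#' @return Numeric vector, one value per axis sample.
#' @export
transient_trace <- function(lines, axis, overlap_width = 170,
                            overlap_amplitude = NULL) {
  stopifnot(inherits(axis, "delay_axis"))
  if (length(axis$values) == 0L) stop("empty delay axis", call. = FALSE)
  tau <- axis$values - axis$origin
  out <- numeric(length(tau))
  pos <- tau >= 0
  peak <- 0
  for (ln in lines) {
    omega <- 2 * pi * ln$center * 100 * C_M_S * 1e-15   # rad/fs
    t2 <- ln$dephasing_time * 1000                      # fs
    peak <- max(peak, ln$amplitude * omega)
    # d/dtau [A exp(-tau/T2) sin(omega tau + phi)]
    out[pos] <- out[pos] + ln$amplitude * exp(-tau[pos] / t2) *
      (omega * cos(omega * tau[pos] + ln$phase) -
         sin(omega * tau[pos] + ln$phase) / t2)
  }
  if (is.null(overlap_amplitude))
    overlap_amplitude <- if (length(lines)) 10 * peak else 1
  if (overlap_amplitude != 0) {
    sigma <- overlap_width / (2 * sqrt(2 * log(2)))
    out <- out + overlap_amplitude * exp(-tau^2 / (2 * sigma^2))
  }
  out
}

#' Delay-line transmission envelope of one window
#'
#' The acousto-optic delay line's diffraction efficiency falls off at the
#' edges of each delay window; modelled as raised-cosine ramps flanking a flat
#' top at 1.
#'
#' @param n_samples Samples per window (>= 2).
#' @param edge_fraction Fraction of the window occupied by each ramp, in
#'   (0, 0.5).
#' @return Numeric vector in `[0, 1]`, symmetric, zero at both ends.
#' @export
transmission_envelope <- function(n_samples, edge_fraction = 0.2) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be >= 2", call. = FALSE)
  if (!is.finite(edge_fraction) || edge_fraction <= 0 || edge_fraction >= 0.5)
    stop("`edge_fraction` must lie in (0, 0.5)", call. = FALSE)
  s <- (seq_len(n_samples) - 1) / (n_samples - 1)
  e <- pmin(s, 1 - s)
  ifelse(e >= edge_fraction, 1, 0.5 * (1 - cos(pi * e / edge_fraction)))
}

# Run `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a raw time-wrapped acquisition
#'
#' Generates the three co-registered 2D channel records a frame produces: the
#' Raman (lock-in) channel, the trigger channel (one pulse per
#' macro-pixel-window) and the transmission channel, each of shape
#' `n_lines_y x (n_macro_x * n_windows * n_delay_samples)`. For each line,
#' macro-pixel and window the simulator writes a trigger pulse followed by
#' `n_delay_samples` samples of `envelope * transmission * trace` into the
#' Raman channel and `envelope * transmission` into the transmission channel.
#' Each line is then shifted circularly by a uniform-integer jitter offset,
#' Gaussian noise is added, and optionally the final line is truncated
#' (zeroed) to emulate imperfect trigger synchronization.
#'
#' @param ph A [phantom()] whose maps match the config grid.
#' @param config An [acquisition_config()].
#' @param noise A [noise_model()].
#' @param edge_fraction Envelope ramp fraction, see [transmission_envelope()].
#' @param overlap_width,overlap_amplitude Overlap-spike parameters, see
#'   [transient_trace()]. The default amplitude is 10x the largest derivative
#'   amplitude over the phantom's species; species with no lines (void) carry
#'   no spike.
#' @param baseline Constant offset added to the Raman trace before the
#'   envelope (default 0).
#' @param truncate_samples Number of trailing samples of the final line to
#'   zero out (default 0).
#' @return An object of class `raw_acquisition`: the three channel matrices,
#'   the config, the simulation parameters, and `ground_truth` (clean
#'   pre-jitter cubes and pure per-pixel transients) for testing.
#' @export
simulate_acquisition <- function(ph, config, noise = noise_model(),
                                 edge_fraction = 0.2, overlap_width = 170,
                                 overlap_amplitude = NULL, baseline = 0,
                                 truncate_samples = 0L) {
  stopifnot(inherits(ph, "phantom"), inherits(config, "acquisition_config"))
  ny <- config$n_lines_y; nx <- config$n_macro_x
  nt <- config$n_delay_samples; nw <- config$n_windows
  if (!all(dim(ph$label_map) == c(ny, nx)))
    stop(sprintf("phantom shape %d x %d does not match config %d x %d",
                 nrow(ph$label_map), ncol(ph$label_map), ny, nx),
         call. = FALSE)
  if (noise$jitter_max >= nt / 2)
    stop("`jitter_max` must be < n_delay_samples / 2 (would defeat registration)",
         call. = FALSE)
  truncate_samples <- as.integer(truncate_samples)
  len <- nx * nw * nt
  if (truncate_samples < 0L || truncate_samples > len)
    stop("`truncate_samples` must be in [0, row length]", call. = FALSE)

  axes <- lapply(seq_len(nw) - 1L, build_delay_axis, config = config)
  env <- transmission_envelope(nt, edge_fraction)
  env_full <- rep(env, nw)

  # global spike amplitude: shared by all material pixels
  if (is.null(overlap_amplitude)) {
    peak <- 0
    for (sp in ph$species_table) for (ln in sp)
      peak <- max(peak, ln$amplitude * 2 * pi * ln$center * 100 * C_M_S * 1e-15)
    overlap_amplitude <- if (peak > 0) 10 * peak else 0
  }

  # per-species clean stitched transient (concatenated over windows)
  species_trace <- lapply(ph$species_table, function(lines) {
    amp <- if (length(lines)) overlap_amplitude else 0
    unlist(lapply(axes, function(ax)
      transient_trace(lines, ax, overlap_width, amp)), use.names = FALSE)
  })

  # trigger template row: one pulse at each segment start; the data channels
  # are rolled forward by the trigger lead below (trigger precedes validity)
  pulse_len <- max(2L, nt %/% 10L)
  trig_row <- numeric(len)
  for (j in seq_len(nx * nw)) {
    s <- (j - 1L) * nt + 1L
    trig_row[s:(s + pulse_len - 1L)] <- 1
  }

  raman <- matrix(0, ny, len)
  trans <- matrix(0, ny, len)
  trig <- matrix(rep(trig_row, each = ny), ny, len)
  gt_raman <- array(0, c(ny, nx, nw * nt))
  gt_trans <- array(0, c(ny, nx, nw * nt))
  gt_transient <- array(0, c(ny, nx, nw * nt))

  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      tr <- species_trace[[ph$label_map[y, x]]]
      tf <- ph$transmission_map[y, x]
      r <- env_full * tf * (baseline + tr)
      t <- env_full * tf
      cols <- ((x - 1L) * nw * nt + 1L):(x * nw * nt)
      raman[y, cols] <- r
      trans[y, cols] <- t
      gt_raman[y, x, ] <- r
      gt_trans[y, x, ] <- t
      gt_transient[y, x, ] <- baseline + tr
    }
  }

  jitter <- integer(ny)
  roll <- function(v, k) if (k == 0L) v else c(v[(len - k + 1L):len], v[1:(len - k)])
  if (config$trigger_lead > 0L) {
    # data becomes valid `trigger_lead` samples after its trigger edge
    for (y in seq_len(ny)) {
      raman[y, ] <- roll(raman[y, ], config$trigger_lead)
      trans[y, ] <- roll(trans[y, ], config$trigger_lead)
    }
  }
  with_seed(noise$seed, {
    if (noise$jitter_max > 0L)
      jitter <- sample.int(noise$jitter_max + 1L, ny, replace = TRUE) - 1L
    for (y in seq_len(ny)) {
      k <- jitter[y]
      raman[y, ] <- roll(raman[y, ], k)
      trans[y, ] <- roll(trans[y, ], k)
      trig[y, ] <- roll(trig[y, ], k)
    }
    if (noise$raman_sigma > 0)
      raman <- raman + matrix(stats::rnorm(ny * len, sd = noise$raman_sigma), ny, len)
    if (noise$transmission_sigma > 0)
      trans <- trans + matrix(stats::rnorm(ny * len, sd = noise$transmission_sigma), ny, len)
  })
  if (truncate_samples > 0L) {
    keep <- len - truncate_samples
    raman[ny, (keep + 1L):len] <- 0
    trans[ny, (keep + 1L):len] <- 0
    trig[ny, (keep + 1L):len] <- 0
  }

  structure(list(
    raman = raman, trigger = trig, transmission = trans, config = config,
    ground_truth = list(raman_cube = gt_raman, transmission_cube = gt_trans,
                        transient = gt_transient, axes = axes,
                        envelope = env, jitter = jitter),
    params = list(edge_fraction = edge_fraction, overlap_width = overlap_width,
                  overlap_amplitude = overlap_amplitude, baseline = baseline,
                  truncate_samples = truncate_samples, noise = noise)
  ), class = "raw_acquisition")
}

#' @export
print.raw_acquisition <- function(x, ...) {
  cat(sprintf("<raw_acquisition> %d lines x %d samples (%d macro-pixels, %d window(s), %d delay samples)\n",
              nrow(x$raman), ncol(x$raman), x$config$n_macro_x,
              x$config$n_windows, x$config$n_delay_samples))
  if (x$params$truncate_samples > 0L)
    cat(sprintf("  final line truncated by %d samples\n", x$params$truncate_samples))
  invisible(x)
}
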