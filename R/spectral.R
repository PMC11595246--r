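# Spectral processing: transmission normalization, multi-window stitching,
# overlap masking, zero-padded FFT spectra, chemical images and ROI spectra.

#' Normalize a Raman trace by its transmission
#'
#' Elementwise ratio wherever the transmission is at least `floor_fraction`
#' of its own maximum; samples below the floor (the attenuated window edges)
#' are marked invalid rather than divided, so no non-finite value can be
#' produced.
#'
#' @param raman Numeric Raman trace.
#' @param transmission Non-negative transmission trace of equal length.
#' @param floor_fraction Validity floor as a fraction of `max(transmission)`
#'   (default 0.05).
#' @param pixel Optional pixel label used in error messages.
#' @return List with `values` (ratio, `NA` where invalid) and `valid`
#'   (logical).
#' @export
normalize_by_transmission <- function(raman, transmission,
                                      floor_fraction = 0.05, pixel = NULL) {
  if (length(raman) != length(transmission))
    stop("`raman` and `transmission` must have equal length", call. = FALSE)
  floor_val <- floor_fraction * max(transmission)
  valid <- is.finite(transmission) & transmission >= floor_val & floor_val > 0
  if (!any(valid))
    stop("transmission entirely below the validity floor",
         if (!is.null(pixel)) paste0(" at pixel ", pixel), call. = FALSE)
  values <- rep(NA_real_, length(raman))
  values[valid] <- raman[valid] / transmission[valid]
  list(values = values, valid = valid)
}

new_stitched_trace <- function(delay, values, junctions = integer(0),
                               crossings = numeric(0), window = NULL) {
  structure(list(delay = delay, values = values, junctions = junctions,
                 crossings = crossings,
                 window = window %||% rep(1L, length(delay))),
            class = "stitched_trace")
}

#' @export
print.stitched_trace <- function(x, ...) {
  cat(sprintf("<stitched_trace> %d samples, %.4g..%.4g fs, %d junction(s)\n",
              length(x$values), x$delay[1], x$delay[length(x$delay)],
              length(x$junctions)))
  invisible(x)
}

# Locate the delay at which the falling envelope of window n crosses the
# rising envelope of window n+1 inside their overlap.
envelope_crossing <- function(delay1, env1, delay2, env2) {
  lo <- max(min(delay2), min(delay1))
  hi <- min(max(delay1), max(delay2))
  if (lo >= hi) stop("adjacent windows do not overlap in delay", call. = FALSE)
  g <- seq(lo, hi, length.out = 256L)
  e1 <- stats::approx(delay1, env1, g, rule = 2)$y
  e2 <- stats::approx(delay2, env2, g, rule = 2)$y
  d <- e2 - e1
  idx <- which(d[-1L] >= 0 & d[-length(d)] < 0)
  if (!length(idx)) stop("no envelope crossing found in the window overlap",
                         call. = FALSE)
  i <- idx[1L]
  # linear interpolation of the sign change
  g[i] + (g[i + 1L] - g[i]) * (-d[i]) / (d[i + 1L] - d[i])
}

#' Stitch normalized delay windows into one time trace
#'
#' Adjacent windows overlap in optical delay (the mechanical step between
#' windows is smaller than the window span). For each adjacent pair the delay
#' at which the falling transmission envelope of window n crosses the rising
#' envelope of window n+1 is located; window-n samples before the crossing
#' and window-(n+1) samples after it are retained. A guard of `guard` valid
#' samples on each side of every junction is discarded and re-generated from
#' a modified-Akima interpolant ([makima()]) fitted to the retained flanking
#' samples, enforcing continuity of the signal and its first derivative.
#' The result is resampled onto a uniform axis at the per-window sample
#' spacing.
#'
#' @param traces List of per-window normalized traces: each either a numeric
#'   vector or a list with `values` and `valid` (as returned by
#'   [normalize_by_transmission()]).
#' @param axes List of matching `delay_axis` objects, ordered by increasing
#'   delay offset.
#' @param envelopes List of per-window transmission envelopes (e.g. the
#'   pixel's own transmission trace). Required when more than one window.
#' @param guard Valid samples replaced on each side of a junction (default
#'   2; at the native 16.7 fs sampling a wider guard visibly degrades the
#'   reconstruction of lines near the top of the band).
#' @return A `stitched_trace`: uniform `delay` axis (fs), `values`, junction
#'   indices on that axis, the crossing delays, and per-sample source-window
#'   labels.
#' @export
stitch_windows <- function(traces, axes, envelopes = NULL, guard = 2L) {
  n <- length(traces)
  if (n == 0L) stop("no windows to stitch", call. = FALSE)
  if (length(axes) != n) stop("`traces` and `axes` lengths differ", call. = FALSE)
  norm1 <- function(tr) {
    if (is.list(tr)) list(values = tr$values, valid = tr$valid)
    else list(values = tr, valid = rep(TRUE, length(tr)))
  }
  traces <- lapply(traces, norm1)
  if (n == 1L) {
    v <- traces[[1L]]$valid
    return(new_stitched_trace(axes[[1L]]$values[v], traces[[1L]]$values[v]))
  }
  if (is.null(envelopes) || length(envelopes) != n)
    stop("`envelopes` (one per window) are required to stitch multiple windows",
         call. = FALSE)
  offs <- vapply(axes, function(a) a$values[1L], numeric(1))
  if (any(diff(offs) <= 0))
    stop("windows must be ordered by increasing delay offset", call. = FALSE)

  crossings <- numeric(n - 1L)
  for (w in seq_len(n - 1L)) {
    crossings[w] <- envelope_crossing(axes[[w]]$values, envelopes[[w]],
                                      axes[[w + 1L]]$values, envelopes[[w + 1L]])
  }

  # retained valid samples of each window, cut at the junction crossings
  delay <- numeric(0); values <- numeric(0); window <- integer(0)
  for (w in seq_len(n)) {
    d <- axes[[w]]$values
    keep <- traces[[w]]$valid
    if (w > 1L) keep <- keep & d >= crossings[w - 1L]
    if (w < n) keep <- keep & d < crossings[w]
    delay <- c(delay, d[keep])
    values <- c(values, traces[[w]]$values[keep])
    window <- c(window, rep(w, sum(keep)))
  }
  if (any(diff(delay) <= 0))
    stop("stitched delays not strictly increasing (inconsistent windows)",
         call. = FALSE)

  # drop the guard samples around each crossing; makima bridges the gap
  guard <- max(0L, as.integer(guard))
  node <- rep(TRUE, length(delay))
  for (cr in crossings) {
    left <- which(delay < cr)
    right <- which(delay >= cr)
    if (length(left) < guard + 2L || length(right) < guard + 2L)
      stop("not enough valid samples around a junction for the guard refit",
           call. = FALSE)
    node[utils::tail(left, guard)] <- FALSE
    node[utils::head(right, guard)] <- FALSE
  }

  dt <- axes[[1L]]$spacing
  t_out <- seq(delay[node][1L], delay[node][sum(node)], by = dt)
  v_out <- makima(delay[node], values[node], t_out)
  junctions <- vapply(crossings, function(cr) which.min(abs(t_out - cr)),
                      integer(1))
  w_out <- findInterval(t_out, crossings) + 1L
  new_stitched_trace(t_out, v_out, junctions, crossings, w_out)
}

#' Tukey (tapered-cosine) window
#'
#' `alpha = 0` gives a rectangular window, `alpha = 1` a Hann window; the
#' taper occupies `alpha/2` of the window at each end.
#'
#' @param n Window length.
#' @param alpha Taper fraction in `[0, 1]`.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.1) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (alpha == 0 || n == 1L) return(rep(1, n))
  k <- 0:(n - 1L)
  width <- alpha * (n - 1) / 2
  w <- rep(1, n)
  lo <- k < width
  hi <- k > (n - 1) - width
  w[lo] <- 0.5 * (1 + cos(pi * (k[lo] / width - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((n - 1 - k[hi]) / width - 1)))
  w
}

#' Mask the pump-probe overlap artifact
#'
#' Samples earlier than `cut_delay` are zeroed (excising the strong
#' pump-probe temporal-overlap spike); the retained region has its mean
#' subtracted and is multiplied by a Tukey window whose rising taper begins
#' at `cut_delay`.
#'
#' @param trace A `stitched_trace` (or list with `delay` and `values`).
#' @param cut_delay Delay below which samples are discarded, fs
#'   (default 300).
#' @param tukey_alpha Tukey taper parameter (default 0.1; 0 = rectangular
#'   gate).
#' @return A `stitched_trace` on the same axis with the masked values;
#'   masking parameters attached as attributes.
#' @export
mask_overlap <- function(trace, cut_delay = 300, tukey_alpha = 0.1) {
  delay <- trace$delay; values <- trace$values
  if (cut_delay > delay[length(delay)])
    stop("`cut_delay` lies beyond the end of the trace", call. = FALSE)
  keep <- delay >= cut_delay
  out <- numeric(length(values))
  y <- values[keep]
  y <- y - mean(y)
  out[keep] <- y * tukey_window(sum(keep), tukey_alpha)
  res <- new_stitched_trace(delay, out, trace$junctions %||% integer(0),
                            trace$crossings %||% numeric(0), trace$window)
  attr(res, "mask") <- list(cut_delay = cut_delay, tukey_alpha = tukey_alpha,
                            n_retained = sum(keep))
  res
}

#' Compute the vibrational spectrum of a masked time trace
#'
#' Magnitude (or power) of the discrete Fourier transform of the trace
#' zero-padded to `pad_factor` times the next power of two, with the
#' frequency axis converted to Raman shift (cm^-1) through the optical-delay
#' sampling interval.
#'
#' @param trace A `stitched_trace` (or list with `delay` fs and `values`)
#'   on a uniform axis.
#' @param pad_factor Zero-padding factor (>= 1, default 8).
#' @param mode `"magnitude"` (default) or `"power"`. The instrument's quoted
#'   spectral resolutions correspond to FWHM measured on the power spectrum;
#'   see the methods vignette.
#' @return An object of class `raman_spectrum`: `wavenumber` (cm^-1, from 0
#'   to the Nyquist shift), `magnitude`, and `metadata` (pad factor, FFT
#'   length, trace length, sampling step, mode, mask parameters if present).
#' @export
compute_spectrum <- function(trace, pad_factor = 8, mode = c("magnitude", "power")) {
  mode <- match.arg(mode)
  delay <- trace$delay; values <- trace$values
  n <- length(values)
  if (n < 2L) stop("trace too short for a spectrum", call. = FALSE)
  d <- diff(delay)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("non-uniform delay axis: resample (stitch) before the FFT",
         call. = FALSE)
  if (pad_factor < 1) stop("`pad_factor` must be >= 1", call. = FALSE)
  dt_s <- mean(d) * 1e-15
  npad <- as.integer(round(pad_factor * 2^ceiling(log2(n))))
  ft <- stats::fft(c(values, numeric(npad - n)))
  kmax <- npad %/% 2L
  mag <- Mod(ft[seq_len(kmax + 1L)])
  if (mode == "power") mag <- mag^2
  wavenumber <- (0:kmax) / (npad * dt_s) / (100 * C_M_S)
  structure(list(
    wavenumber = wavenumber, magnitude = mag,
    metadata = list(pad_factor = pad_factor, n_padded = npad, n_trace = n,
                    delay_step_fs = mean(d), mode = mode,
                    mask = attr(trace, "mask"))
  ), class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d bins, 0..%.4g cm^-1 (%.4g cm^-1/bin), mode %s\n",
              length(x$wavenumber), max(x$wavenumber),
              x$wavenumber[2], x$metadata$mode))
  invisible(x)
}

#' Peak position, FWHM and height of a spectrum
#'
#' The peak is the argmax within the search band; its full width at half
#' maximum is obtained by linear interpolation of the half-maximum crossings
#' on either side. The FWHM convention follows the values as given (pass a
#' power-mode spectrum for intensity-FWHM).
#'
#' @param spectrum A `raman_spectrum`.
#' @param band Two-element search band in cm^-1 (default: the full axis).
#' @return List with `position` (cm^-1), `fwhm` (cm^-1, `NA` if a crossing
#'   is not bracketed), `height`, and `on_edge` (TRUE when the peak sits on
#'   the band boundary).
#' @export
peak_stats <- function(spectrum, band = NULL) {
  w <- spectrum$wavenumber; m <- spectrum$magnitude
  if (is.null(band)) band <- range(w)
  if (band[1L] >= band[2L]) stop("invalid search band", call. = FALSE)
  if (band[1L] < min(w) || band[2L] > max(w))
    stop("search band outside the spectrum axis", call. = FALSE)
  sel <- which(w >= band[1L] & w <= band[2L])
  if (length(sel) < 3L) stop("search band too narrow", call. = FALSE)
  i <- sel[which.max(m[sel])]
  height <- m[i]
  half <- height / 2
  on_edge <- i == sel[1L] || i == sel[length(sel)]
  cross <- function(idx_seq) {
    # walk away from the peak until the values drop below half maximum
    for (j in idx_seq) {
      if (m[j] < half) {
        j2 <- j + sign(i - j)  # neighbour towards the peak (>= half)
        return(w[j] + (w[j2] - w[j]) * (half - m[j]) / (m[j2] - m[j]))
      }
    }
    NA_real_
  }
  left <- if (i > 1L) cross((i - 1L):1L) else NA_real_
  right <- if (i < length(w)) cross((i + 1L):length(w)) else NA_real_
  list(position = w[i], fwhm = right - left, height = height,
       on_edge = on_edge || is.na(left) || is.na(right))
}

#' Process a registered cube pair into a hyperspectral cube
#'
#' Runs, for every valid pixel, the chain normalize -> stitch -> mask ->
#' zero-padded FFT on a shared wavenumber axis. The pixel's own transmission
#' trace serves as the per-window envelope for stitching. Pixels that fail
#' (or were masked at registration) are flagged and zero-filled; processing
#' aborts only if every pixel fails.
#'
#' @param cubes A `cube_pair` (see [reshape_to_cubes()]).
#' @param floor_fraction Passed to [normalize_by_transmission()].
#' @param cut_delay,tukey_alpha Passed to [mask_overlap()].
#' @param pad_factor,mode Passed to [compute_spectrum()].
#' @param guard Passed to [stitch_windows()].
#' @return An object of class `raman_hypercube`: `values` array
#'   `(Ny, Nx, Nfreq)`, shared `wavenumber` axis, `pixel_ok` mask,
#'   processing `params`, flagged-pixel count and the config.
#' @export
process_cube <- function(cubes, floor_fraction = 0.05, cut_delay = 300,
                         tukey_alpha = 0.1, pad_factor = 8,
                         mode = "magnitude", guard = 2L) {
  stopifnot(inherits(cubes, "cube_pair"))
  config <- cubes$config
  ny <- config$n_lines_y; nx <- config$n_macro_x
  nt <- config$n_delay_samples; nw <- config$n_windows
  axes <- lapply(seq_len(nw) - 1L, build_delay_axis, config = config)
  win_slice <- lapply(seq_len(nw), function(w) ((w - 1L) * nt + 1L):(w * nt))

  values <- NULL; wavenumber <- NULL
  pixel_ok <- cubes$pixel_ok
  n_flagged <- 0L
  first_err <- NULL
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      if (!pixel_ok[y, x]) next
      sp <- tryCatch({
        r <- cubes$raman_cube[y, x, ]
        t <- cubes$transmission_cube[y, x, ]
        traces <- vector("list", nw); envs <- vector("list", nw)
        for (w in seq_len(nw)) {
          sl <- win_slice[[w]]
          traces[[w]] <- normalize_by_transmission(r[sl], t[sl],
                                                   floor_fraction,
                                                   pixel = sprintf("(%d,%d)", y, x))
          envs[[w]] <- t[sl]
        }
        st <- stitch_windows(traces, axes, envs, guard)
        compute_spectrum(mask_overlap(st, cut_delay, tukey_alpha),
                         pad_factor, mode)
      }, error = function(e) e)
      if (inherits(sp, "error")) {
        pixel_ok[y, x] <- FALSE
        n_flagged <- n_flagged + 1L
        if (is.null(first_err)) first_err <- conditionMessage(sp)
        next
      }
      if (is.null(values)) {
        wavenumber <- sp$wavenumber
        values <- array(0, c(ny, nx, length(wavenumber)))
      }
      if (length(sp$magnitude) != dim(values)[3L]) {
        pixel_ok[y, x] <- FALSE
        n_flagged <- n_flagged + 1L
        next
      }
      values[y, x, ] <- sp$magnitude
    }
  }
  if (is.null(values))
    stop("all pixels failed processing; first error: ", first_err,
         call. = FALSE)
  if (any(!is.finite(values))) values[!is.finite(values)] <- 0
  structure(list(
    values = values, wavenumber = wavenumber, pixel_ok = pixel_ok,
    params = list(floor_fraction = floor_fraction, cut_delay = cut_delay,
                  tukey_alpha = tukey_alpha, pad_factor = pad_factor,
                  mode = mode, guard = guard),
    n_flagged = n_flagged, config = config
  ), class = "raman_hypercube")
}

#' @export
print.raman_hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raman_hypercube> %d x %d pixels x %d bins (0..%.4g cm^-1), %d flagged\n",
              d[1], d[2], d[3], max(x$wavenumber), x$n_flagged))
  invisible(x)
}

# small 2x2 Gaussian smoothing with replicate padding
smooth_2x2 <- function(img, sigma = 0.8) {
  k <- exp(-c(0, 1, 1, 2) / (2 * sigma^2))
  k <- k / sum(k)
  ny <- nrow(img); nx <- ncol(img)
  yp <- pmin(seq_len(ny) + 1L, ny)
  xp <- pmin(seq_len(nx) + 1L, nx)
  k[1] * img + k[2] * img[, xp] + k[3] * img[yp, ] + k[4] * img[yp, xp]
}

#' Chemical image at a chosen Raman shift
#'
#' Extracts the nearest-bin frequency slice (or the mean over a stated band)
#' from a hyperspectral cube, optionally smooths it with a 2x2 Gaussian
#' filter, and normalizes it.
#'
#' @param hcube A `raman_hypercube`.
#' @param shift Raman shift of the slice, cm^-1 (within the axis range).
#' @param band Optional two-element band, cm^-1; when given, the slice is
#'   the per-pixel mean over the band instead of a single bin.
#' @param smooth Apply the 2x2 Gaussian spatial filter (default TRUE).
#' @param sigma Gaussian sigma of the 2x2 kernel, pixels (default 0.8).
#' @param normalize One of `"none"`, `"image-max"` (brightest pixel of this
#'   image = 1) or `"cube-max"` (brightest voxel of the whole cube = 1).
#' @return `Ny x Nx` numeric matrix; the shift actually used is attached as
#'   attribute `"shift"`.
#' @export
frequency_slice <- function(hcube, shift, band = NULL, smooth = TRUE,
                            sigma = 0.8,
                            normalize = c("none", "image-max", "cube-max")) {
  stopifnot(inherits(hcube, "raman_hypercube"))
  normalize <- match.arg(normalize)
  w <- hcube$wavenumber
  if (shift < min(w) || shift > max(w))
    stop(sprintf("shift %.3g cm^-1 outside the axis range [%.3g, %.3g]",
                 shift, min(w), max(w)), call. = FALSE)
  if (is.null(band)) {
    bin <- which.min(abs(w - shift))
    img <- hcube$values[, , bin]
    used <- w[bin]
  } else {
    sel <- which(w >= band[1L] & w <= band[2L])
    if (!length(sel)) stop("empty band", call. = FALSE)
    img <- apply(hcube$values[, , sel, drop = FALSE], c(1L, 2L), mean)
    used <- mean(w[sel])
  }
  if (isTRUE(smooth)) img <- smooth_2x2(img, sigma)
  img <- switch(normalize,
                "none" = img,
                "image-max" = if (max(img) > 0) img / max(img) else img,
                "cube-max" = {
                  mx <- max(hcube$values)
                  if (mx > 0) img / mx else img
                })
  attr(img, "shift") <- used
  attr(img, "normalize") <- normalize
  img
}

#' ROI-averaged spectrum
#'
#' Per-bin mean of the spectra of all valid pixels inside a region of
#' interest.
#'
#' @param hcube A `raman_hypercube`.
#' @param roi Logical `Ny x Nx` mask.
#' @return A `raman_spectrum` on the cube's shared axis.
#' @export
roi_spectrum <- function(hcube, roi) {
  stopifnot(inherits(hcube, "raman_hypercube"))
  roi <- as.matrix(roi)
  d <- dim(hcube$values)
  if (!all(dim(roi) == d[1:2]))
    stop("`roi` shape must match the cube's spatial grid", call. = FALSE)
  sel <- roi & hcube$pixel_ok
  if (!any(sel)) stop("ROI contains no valid pixel", call. = FALSE)
  m <- matrix(hcube$values, d[1L] * d[2L], d[3L])
  mag <- colMeans(m[as.vector(sel), , drop = FALSE])
  structure(list(wavenumber = hcube$wavenumber, magnitude = mag,
                 metadata = c(hcube$params, list(n_roi_pixels = sum(sel)))),
            class = "raman_spectrum")
}
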