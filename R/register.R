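# Trigger-edge registration: raw 2D records -> co-registered (Ny, Nx, Ntau)
# cubes, tolerant to per-line clock jitter and a truncated final line.

#' Detect rising edges of a trigger row
#'
#' An edge is a sample at or above the threshold whose predecessor is below
#' it; the first sample counts as an edge when already high. The threshold is
#' `threshold_fraction` of the row's dynamic range above its minimum. Edges
#' closer than `min_gap` samples to an accepted edge are discarded
#' (debounce); by default `min_gap` is half the median raw inter-edge
#' spacing.
#'
#' @param trigger_row Numeric vector of trigger samples.
#' @param threshold_fraction Fraction of the dynamic range, in (0, 1)
#'   (default 0.5).
#' @param min_gap Minimum accepted inter-edge gap in samples, or `NULL` for
#'   the default.
#' @param line Optional line number used in error messages.
#' @return Integer vector of 1-based edge sample indices.
#' @export
detect_rising_edges <- function(trigger_row, threshold_fraction = 0.5,
                                min_gap = NULL, line = NULL) {
  if (!length(trigger_row)) stop("empty trigger row", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must lie in (0, 1)", call. = FALSE)
  rng <- range(trigger_row)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("flat trigger row (no edges detectable)",
         if (!is.null(line)) paste0(" on line ", line), call. = FALSE)
  th <- rng[1] + threshold_fraction * diff(rng)
  above <- trigger_row >= th
  edges <- which(above & !c(FALSE, above[-length(above)]))
  if (length(edges) > 1L) {
    if (is.null(min_gap)) min_gap <- floor(stats::median(diff(edges)) / 2)
    if (min_gap > 0L) {
      kept <- edges[1L]
      last <- edges[1L]
      for (e in edges[-1L]) {
        if (e - last >= min_gap) {
          kept <- c(kept, e)
          last <- e
        }
      }
      edges <- kept
    }
  }
  as.integer(edges)
}

#' Build the per-line trigger edge table of a raw acquisition
#'
#' @param raw A `raw_acquisition` (or list with a `trigger` matrix and
#'   `config`).
#' @param threshold_fraction Passed to [detect_rising_edges()].
#' @return An object of class `edge_table`: per-line edge index lists, the
#'   inferred samples-per-window period, and per-line offset estimates.
#' @export
edge_table <- function(raw, threshold_fraction = 0.5) {
  trig <- raw$trigger
  ny <- nrow(trig)
  edges <- vector("list", ny)
  for (y in seq_len(ny)) {
    edges[[y]] <- tryCatch(
      detect_rising_edges(trig[y, ], threshold_fraction, line = y),
      error = function(e) integer(0))
  }
  period <- tryCatch(infer_window_period(edges, config = raw$config),
                     error = function(e) {
                       # single edge per line: fall back to the configured period
                       if (!is.null(raw$config)) raw$config$n_delay_samples
                       else stop(e)
                     })
  offsets <- vapply(edges, function(e)
    if (length(e)) as.integer((e[1L] - 1L) %% period) else NA_integer_,
    integer(1))
  structure(list(edges = edges, period = period, offsets = offsets,
                 n_lines = ny, n_samples = ncol(trig)),
            class = "edge_table")
}

#' Infer the samples-per-window period from trigger edges
#'
#' Median inter-edge spacing across all lines, rounded to the nearest
#' integer. When a config is supplied and the inferred period disagrees with
#' `n_delay_samples`, a warning is recorded (not an error).
#'
#' @param edges An `edge_table`, or a list of per-line edge index vectors.
#' @param config Optional [acquisition_config()] to cross-check against.
#' @return Integer samples per window.
#' @export
infer_window_period <- function(edges, config = NULL) {
  if (inherits(edges, "edge_table")) edges <- edges$edges
  gaps <- unlist(lapply(edges, function(e) if (length(e) > 1L) diff(e)),
                 use.names = FALSE)
  if (!length(gaps))
    stop("fewer than 2 trigger edges on every line; cannot infer period",
         call. = FALSE)
  period <- as.integer(round(stats::median(gaps)))
  if (!is.null(config) && period != config$n_delay_samples)
    warning(sprintf("inferred window period %d differs from configured n_delay_samples %d",
                    period, config$n_delay_samples), call. = FALSE)
  period
}

#' Reshape raw 2D records into co-registered cubes
#'
#' For each scan line, the `n_delay_samples` samples following each trigger
#' edge (plus the configured `trigger_lead`) are assigned to consecutive
#' macro-pixels and windows in acquisition order, for both the Raman and the
#' transmission channel. Per-line jitter appears only as a common shift of
#' that line's edges and is removed exactly. Lines with a full complement of
#' edges are extracted circularly (the simulator's jitter model wraps);
#' truncated lines are flagged, their present windows filled, and missing or
#' incomplete trailing macro-pixels zero-filled and masked invalid.
#'
#' @param raw A `raw_acquisition`.
#' @param threshold_fraction Passed to [detect_rising_edges()].
#' @return An object of class `cube_pair`: `raman_cube` and
#'   `transmission_cube` of shape `(Ny, Nx, n_windows * n_delay_samples)`,
#'   a `pixel_ok` validity mask, per-line quality flags, the inferred period
#'   and the config.
#' @export
reshape_to_cubes <- function(raw, threshold_fraction = 0.5) {
  config <- raw$config
  ny <- config$n_lines_y; nx <- config$n_macro_x
  nt <- config$n_delay_samples; nw <- config$n_windows
  len <- ncol(raw$raman)
  expected <- nx * nw
  et <- edge_table(raw, threshold_fraction)

  raman_cube <- array(0, c(ny, nx, nw * nt))
  trans_cube <- array(0, c(ny, nx, nw * nt))
  pixel_ok <- matrix(TRUE, ny, nx)
  truncated <- logical(ny)

  for (y in seq_len(ny)) {
    edges <- et$edges[[y]]
    n_e <- length(edges)
    if (n_e == 0L) {
      # fully truncated (or dead) line: flag and zero-fill, keep cube shape
      truncated[y] <- TRUE
      pixel_ok[y, ] <- FALSE
      next
    }
    if (n_e > expected)
      stop(sprintf("line %d: %d trigger edges found, expected %d (malformed trigger train)",
                   y, n_e, expected), call. = FALSE)
    full <- n_e == expected
    last_valid <- len
    if (!full) {
      truncated[y] <- TRUE
      if (any(diff(edges) > 1.5 * et$period))
        stop(sprintf("line %d: %d trigger edges with a gap exceeding the window period (malformed trigger train, expected %d edges)",
                     y, n_e, expected), call. = FALSE)
      # truncation zeroes all channels; data beyond the trailing zero run of
      # the combined channels is unusable
      combined <- abs(raw$raman[y, ]) + abs(raw$trigger[y, ]) +
        abs(raw$transmission[y, ])
      nz <- which(combined > 0)
      if (length(nz)) last_valid <- max(nz)
    }
    # data-valid start of each segment; acquisition order = ascending start
    # (modulo the row length, since jitter is circular and the lead-shifted
    # first pulse may wrap to the row end)
    starts <- sort(((edges + config$trigger_lead - 1L) %% len) + 1L)
    for (j in seq_len(n_e)) {
      x <- (j - 1L) %/% nw + 1L
      w <- (j - 1L) %% nw + 1L
      start <- starts[j]
      if (full) {
        idx <- ((start - 1L + 0L:(nt - 1L)) %% len) + 1L   # circular (jitter wrap)
      } else {
        if (start + nt - 1L > last_valid) {   # incomplete trailing window
          pixel_ok[y, x] <- FALSE
          next
        }
        idx <- start:(start + nt - 1L)
      }
      sl <- ((w - 1L) * nt + 1L):(w * nt)
      raman_cube[y, x, sl] <- raw$raman[y, idx]
      trans_cube[y, x, sl] <- raw$transmission[y, idx]
    }
    if (!full) {
      # macro-pixels with no edge at all
      seen <- unique((seq_len(n_e) - 1L) %/% nw + 1L)
      pixel_ok[y, setdiff(seq_len(nx), seen)] <- FALSE
    }
  }

  structure(list(raman_cube = raman_cube, transmission_cube = trans_cube,
                 pixel_ok = pixel_ok,
                 line_flags = data.frame(line = seq_len(ny),
                                         n_edges = lengths(et$edges),
                                         truncated = truncated),
                 period = et$period, offsets = et$offsets, config = config),
            class = "cube_pair")
}

#' @export
print.cube_pair <- function(x, ...) {
  d <- dim(x$raman_cube)
  cat(sprintf("<cube_pair> %d lines x %d macro-pixels x %d delay samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  inferred period %d samples; %d truncated line(s); %d invalid pixel(s)\n",
              x$period, sum(x$line_flags$truncated), sum(!x$pixel_ok)))
  invisible(x)
}

#' Diagnostic synchronization report
#'
#' Purely diagnostic: per-line edge counts and offsets, the period estimate,
#' truncated lines, and whether the configured trigger lead leaves every
#' window inside the record. Never throws.
#'
#' @param raw A `raw_acquisition` (or list with `trigger` and `config`).
#' @param threshold_fraction Passed to [detect_rising_edges()].
#' @return An object of class `sync_report`.
#' @export
validate_sync <- function(raw, threshold_fraction = 0.5) {
  config <- raw$config
  fatal <- NULL
  if (is.null(raw$trigger)) {
    return(structure(list(fatal = "missing trigger channel", lines = NULL,
                          period = NA_integer_, period_matches_config = NA,
                          lead_consistent = NA),
                     class = "sync_report"))
  }
  et <- tryCatch(edge_table(raw, threshold_fraction), error = function(e) e)
  if (inherits(et, "error")) {
    return(structure(list(fatal = conditionMessage(et), lines = NULL,
                          period = NA_integer_, period_matches_config = NA,
                          lead_consistent = NA),
                     class = "sync_report"))
  }
  expected <- config$n_macro_x * config$n_windows
  n_edges <- lengths(et$edges)
  if (all(n_edges == 0L)) {
    return(structure(list(fatal = "no trigger edges detectable on any line",
                          lines = NULL, period = NA_integer_,
                          period_matches_config = NA, lead_consistent = NA),
                     class = "sync_report"))
  }
  lines <- data.frame(line = seq_len(et$n_lines), n_edges = n_edges,
                      offset = et$offsets,
                      truncated = n_edges < expected,
                      malformed = n_edges > expected)
  last_ok <- vapply(et$edges, function(e)
    !length(e) || max(e) + config$trigger_lead + config$n_delay_samples - 1L <=
      et$n_samples + max(et$offsets, 0, na.rm = TRUE), logical(1))
  structure(list(
    fatal = fatal, lines = lines, period = et$period,
    period_matches_config = et$period == config$n_delay_samples,
    expected_edges = expected,
    lead_consistent = all(last_ok),
    all_ok = is.null(fatal) && all(!lines$truncated) && all(!lines$malformed) &&
      et$period == config$n_delay_samples
  ), class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  if (!is.null(x$fatal)) {
    cat("<sync_report> FATAL:", x$fatal, "\n")
    return(invisible(x))
  }
  cat(sprintf("<sync_report> period %d (matches config: %s)\n",
              x$period, x$period_matches_config))
  cat(sprintf("  lines: %d total, %d truncated, %d malformed; all OK: %s\n",
              nrow(x$lines), sum(x$lines$truncated), sum(x$lines$malformed),
              isTRUE(x$all_ok)))
  invisible(x)
}
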