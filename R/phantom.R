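# Phantom description: per-macro-pixel species maps and vibrational lines.

#' A single vibrational line
#'
#' @param center Raman shift of the line, cm^-1 (>= 0).
#' @param amplitude Dimensionless modulation depth (>= 0).
#' @param dephasing_time T2 exponential decay constant, ps (> 0).
#' @param phase Initial phase, rad.
#' @return An object of class `vibrational_line`.
#' @export
vibrational_line <- function(center, amplitude = 1, dephasing_time = 5,
                             phase = 0) {
  if (center < 0) stop("`center` must be >= 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (!is.finite(dephasing_time) || dephasing_time <= 0)
    stop("`dephasing_time` must be > 0", call. = FALSE)
  structure(list(center = center, amplitude = amplitude,
                 dephasing_time = dephasing_time, phase = phase),
            class = "vibrational_line")
}

#' Synthetic sample phantom
#'
#' A phantom states, for every macro-pixel of the scan grid, which chemical
#' species sits there and how transparent it is. Each species is a list of
#' [vibrational_line()]s; a species with no lines is inert ("void").
#'
#' @param label_map `n_lines_y x n_macro_x` matrix of species labels
#'   (character).
#' @param species_table Named list mapping every label occurring in
#'   `label_map` to a list of [vibrational_line()]s (possibly empty).
#' @param transmission_map Matrix of static per-pixel transmission factors in
#'   (0, 1], same shape as `label_map`; defaults to all ones.
#' @return An object of class `phantom`.
#' @export
phantom <- function(label_map, species_table, transmission_map = NULL) {
  label_map <- as.matrix(label_map)
  if (is.null(transmission_map))
    transmission_map <- matrix(1, nrow(label_map), ncol(label_map))
  transmission_map <- as.matrix(transmission_map)
  if (!all(dim(transmission_map) == dim(label_map)))
    stop("`transmission_map` shape must match `label_map`", call. = FALSE)
  if (any(transmission_map <= 0) || any(transmission_map > 1))
    stop("`transmission_map` values must lie in (0, 1]", call. = FALSE)
  labs <- unique(as.vector(label_map))
  missing <- setdiff(labs, names(species_table))
  if (length(missing))
    stop("labels without species_table entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (s in names(species_table)) {
    for (ln in species_table[[s]]) {
      if (!inherits(ln, "vibrational_line"))
        stop("species `", s, "` contains a non-vibrational_line entry",
             call. = FALSE)
    }
  }
  structure(list(label_map = label_map, species_table = species_table,
                 transmission_map = transmission_map),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d pixels, %d species\n",
              nrow(x$label_map), ncol(x$label_map), length(x$species_table)))
  for (s in names(x$species_table)) {
    lines <- x$species_table[[s]]
    ctr <- vapply(lines, function(l) l$center, numeric(1))
    cat(sprintf("  %-14s %5d px  lines: %s cm^-1\n", s,
                sum(x$label_map == s),
                if (length(ctr)) paste(ctr, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Logical mask of the pixels occupied by one species
#'
#' @param ph A [phantom()].
#' @param species A label present in the phantom's species table.
#' @return Logical `n_lines_y x n_macro_x` matrix.
#' @export
phantom_roi <- function(ph, species) {
  stopifnot(inherits(ph, "phantom"))
  if (!species %in% names(ph$species_table))
    stop("unknown species: ", species, call. = FALSE)
  ph$label_map == species
}

#' Calibration-crystal phantom (single low-frequency phonon)
#'
#' A transparent crystal occupying one corner of the field of view, carrying a
#' single narrow resonance at 90 cm^-1 as exhibited by bismuth germanate
#' calibration crystals; the rest of the field is void.
#'
#' @param config An [acquisition_config()]; defaults to a 64 macro-pixel by 63
#'   line frame (the last scan line of a 64-line frame being truncated in
#'   practice).
#' @param center Resonance position, cm^-1.
#' @param dephasing_time T2 of the resonance, ps.
#' @return A [phantom()] with species `"crystal"` and `"void"`.
#' @export
phantom_bgo <- function(config = acquisition_config(n_macro_x = 64L,
                                                    n_lines_y = 63L,
                                                    fov = 300),
                        center = 90, dephasing_time = 10) {
  ny <- config$n_lines_y; nx <- config$n_macro_x
  lab <- matrix("void", ny, nx)
  lab[seq_len(ceiling(ny * 0.65)), seq_len(ceiling(nx * 0.65))] <- "crystal"
  trans <- matrix(1, ny, nx)
  trans[lab == "crystal"] <- 0.8
  phantom(lab, list(
    crystal = list(vibrational_line(center, amplitude = 1,
                                    dephasing_time = dephasing_time)),
    void = list()
  ), trans)
}

#' Two-species chemical-contrast phantom
#'
#' Two transparent crystals that cannot be told apart in transmission but have
#' distinct low-frequency Raman signatures: an acetaminophen-like species with
#' its strongest line at 56 cm^-1 and an anthracene-like species with its
#' strongest line at 37 cm^-1. The remaining area is void. Synthetic stand-in
#' geometry; no measured data enter the package.
#'
#' @param config An [acquisition_config()]; defaults to the 64 x 64, 500 um
#'   field of view.
#' @param dephasing_time T2 shared by all lines, ps.
#' @return A [phantom()] with species `"acetaminophen"`, `"anthracene"`,
#'   `"void"`.
#' @export
phantom_two_species <- function(config = acquisition_config(n_macro_x = 64L,
                                                            n_lines_y = 64L,
                                                            fov = 500),
                                dephasing_time = 5) {
  ny <- config$n_lines_y; nx <- config$n_macro_x
  lab <- matrix("void", ny, nx)
  # big anthracene crystal, smaller acetaminophen pieces (disjoint blocks)
  r1 <- seq(max(1L, round(ny * 0.30)), min(ny, round(ny * 0.92)))
  c1 <- seq(max(1L, round(nx * 0.06)), min(nx, round(nx * 0.45)))
  lab[r1, c1] <- "anthracene"
  r2 <- seq(max(1L, round(ny * 0.10)), min(ny, round(ny * 0.42)))
  c2 <- seq(max(1L, round(nx * 0.55)), min(nx, round(nx * 0.88)))
  lab[r2, c2] <- "acetaminophen"
  trans <- matrix(1, ny, nx)
  trans[lab != "void"] <- 0.85
  phantom(lab, list(
    acetaminophen = list(vibrational_line(56, amplitude = 1,
                                          dephasing_time = dephasing_time)),
    anthracene = list(vibrational_line(37, amplitude = 1,
                                       dephasing_time = dephasing_time)),
    void = list()
  ), trans)
}

#' Acquisition noise model
#'
#' @param raman_sigma Additive Gaussian sigma on the Raman channel (>= 0).
#' @param transmission_sigma Same for the transmission channel (>= 0).
#' @param jitter_max Per-line trigger offset bound, samples (integer >= 0).
#' @param seed RNG seed; a fixed seed makes the simulator bit-reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(raman_sigma = 5e-4, transmission_sigma = 1e-3,
                        jitter_max = 5L, seed = 1L) {
  if (raman_sigma < 0 || transmission_sigma < 0)
    stop("noise sigmas must be >= 0", call. = FALSE)
  jitter_max <- as.integer(jitter_max)
  if (is.na(jitter_max) || jitter_max < 0L)
    stop("`jitter_max` must be an integer >= 0", call. = FALSE)
  structure(list(raman_sigma = raman_sigma,
                 transmission_sigma = transmission_sigma,
                 jitter_max = jitter_max, seed = as.integer(seed)),
            class = "noise_model")
}
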