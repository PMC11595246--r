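# Plain-text persistence: lossless TSV matrices + JSON metadata.
# Doubles are formatted with %.17g so write -> read is bit-exact.

write_matrix_tsv <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  m <- as.matrix(data.table::fread(path, header = FALSE, sep = "\t"))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# 3D array <-> matrix (rows = first dim, cols = flattened rest, row-major in
# the trailing dims so each row reads naturally as one scan line)
flatten_cube <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(3L, 2L, 1L)), nrow = d[1L], byrow = TRUE)
}
unflatten_cube <- function(m, d) {
  aperm(array(t(m), d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
}

#' Write / read a raw acquisition fixture
#'
#' Persists the three channel records as lossless TSV, the configuration and
#' simulation parameters as JSON, and (when present) the simulator ground
#' truth, into a directory. `read_raw_acquisition` restores an object equal
#' to the one written.
#'
#' @param raw A `raw_acquisition` (see [simulate_acquisition()]), or any list
#'   with `raman`, `trigger`, `transmission` matrices and a `config`.
#' @param dir Directory to create/fill.
#' @param ground_truth Persist the simulator ground truth too (default TRUE
#'   when present).
#' @return `write_raw_acquisition` returns `dir` invisibly;
#'   `read_raw_acquisition` returns a `raw_acquisition`.
#' @export
write_raw_acquisition <- function(raw, dir, ground_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(name, m) write_matrix_tsv(m, file.path(dir, name))
  tryCatch({
    wr("raman.tsv", raw$raman)
    wr("trigger.tsv", raw$trigger)
    wr("transmission.tsv", raw$transmission)
    write_config(raw$config, file.path(dir, "config.json"))
    meta <- list(kind = "raw_acquisition")
    if (!is.null(raw$params)) {
      p <- raw$params
      p$noise <- unclass(p$noise)
      meta$params <- p
    }
    has_gt <- isTRUE(ground_truth) && !is.null(raw$ground_truth)
    meta$has_ground_truth <- has_gt
    if (has_gt) {
      gt <- raw$ground_truth
      meta$gt_dim <- dim(gt$raman_cube)
      meta$jitter <- gt$jitter
      wr("gt_raman.tsv", flatten_cube(gt$raman_cube))
      wr("gt_transmission.tsv", flatten_cube(gt$transmission_cube))
      wr("gt_transient.tsv", flatten_cube(gt$transient))
    }
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    stop("failed writing raw acquisition to `", dir, "`: ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(dir)
}

#' @rdname write_raw_acquisition
#' @export
read_raw_acquisition <- function(dir) {
  if (!dir.exists(dir)) stop("no such fixture directory: ", dir, call. = FALSE)
  config <- read_config(file.path(dir, "config.json"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  out <- list(raman = read_matrix_tsv(file.path(dir, "raman.tsv")),
              trigger = read_matrix_tsv(file.path(dir, "trigger.tsv")),
              transmission = read_matrix_tsv(file.path(dir, "transmission.tsv")),
              config = config)
  if (!is.null(meta$params)) {
    p <- meta$params
    p$noise <- do.call(noise_model, p$noise)
    p$truncate_samples <- as.integer(p$truncate_samples)
    out$params <- p
  }
  if (isTRUE(meta$has_ground_truth)) {
    d <- as.integer(meta$gt_dim)
    axes <- lapply(seq_len(config$n_windows) - 1L, build_delay_axis,
                   config = config)
    out$ground_truth <- list(
      raman_cube = unflatten_cube(read_matrix_tsv(file.path(dir, "gt_raman.tsv")), d),
      transmission_cube = unflatten_cube(read_matrix_tsv(file.path(dir, "gt_transmission.tsv")), d),
      transient = unflatten_cube(read_matrix_tsv(file.path(dir, "gt_transient.tsv")), d),
      axes = axes,
      envelope = transmission_envelope(config$n_delay_samples,
                                       out$params$edge_fraction %||% 0.2),
      jitter = as.integer(meta$jitter))
  }
  structure(out, class = "raw_acquisition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a registered cube pair
#'
#' @param cubes A `cube_pair` (see [reshape_to_cubes()]).
#' @param dir Directory to create/fill.
#' @return `write_cube_pair` returns `dir` invisibly; `read_cube_pair`
#'   returns a `cube_pair`.
#' @export
write_cube_pair <- function(cubes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(flatten_cube(cubes$raman_cube), file.path(dir, "raman_cube.tsv"))
  write_matrix_tsv(flatten_cube(cubes$transmission_cube),
                   file.path(dir, "transmission_cube.tsv"))
  write_config(cubes$config, file.path(dir, "config.json"))
  jsonlite::write_json(list(
    kind = "cube_pair", dim = dim(cubes$raman_cube),
    pixel_ok = cubes$pixel_ok, line_flags = cubes$line_flags,
    period = cubes$period
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cube_pair
#' @export
read_cube_pair <- function(dir) {
  if (!dir.exists(dir)) stop("no such cube directory: ", dir, call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  structure(list(
    raman_cube = unflatten_cube(read_matrix_tsv(file.path(dir, "raman_cube.tsv")), d),
    transmission_cube = unflatten_cube(read_matrix_tsv(file.path(dir, "transmission_cube.tsv")), d),
    pixel_ok = matrix(as.logical(meta$pixel_ok), d[1L], d[2L]),
    line_flags = as.data.frame(meta$line_flags),
    period = as.integer(meta$period),
    config = read_config(file.path(dir, "config.json"))
  ), class = "cube_pair")
}

#' Write / read a hyperspectral cube
#'
#' @param hcube A `raman_hypercube` (see [process_cube()]).
#' @param dir Directory to create/fill.
#' @return `write_hypercube` returns `dir` invisibly; `read_hypercube`
#'   returns a `raman_hypercube`.
#' @export
write_hypercube <- function(hcube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(flatten_cube(hcube$values), file.path(dir, "hypercube.tsv"))
  write_matrix_tsv(matrix(hcube$wavenumber, nrow = 1L),
                   file.path(dir, "wavenumber_axis.tsv"))
  write_config(hcube$config, file.path(dir, "config.json"))
  jsonlite::write_json(list(
    kind = "raman_hypercube", dim = dim(hcube$values),
    pixel_ok = hcube$pixel_ok, params = hcube$params,
    n_flagged = hcube$n_flagged
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_hypercube
#' @export
read_hypercube <- function(dir) {
  if (!dir.exists(dir)) stop("no such hypercube directory: ", dir, call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  structure(list(
    values = unflatten_cube(read_matrix_tsv(file.path(dir, "hypercube.tsv")), d),
    wavenumber = as.numeric(read_matrix_tsv(file.path(dir, "wavenumber_axis.tsv"))),
    pixel_ok = matrix(as.logical(meta$pixel_ok), d[1L], d[2L]),
    params = meta$params, n_flagged = meta$n_flagged,
    config = read_config(file.path(dir, "config.json"))
  ), class = "raman_hypercube")
}

#' Export a spectrum as CSV
#'
#' Two columns: `wavenumber` (cm^-1) and `magnitude`.
#'
#' @param spectrum A `raman_spectrum` (see [compute_spectrum()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  data.table::fwrite(data.table::data.table(wavenumber = spectrum$wavenumber,
                                            magnitude = spectrum$magnitude),
                     path)
  invisible(path)
}
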