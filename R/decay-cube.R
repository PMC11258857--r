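#' TCSPC decay cube container
#'
#' A decay cube holds one photon-count histogram per pixel: a 3-D array of
#' non-negative counts with dimensions (rows, cols, time bins) plus the
#' time-axis metadata needed to interpret it. The default time axis is 256
#' bins spanning 12.5 ns, the laser repetition period of an 80 MHz source.
#'
#' @param counts 3-D numeric array (rows, cols, n_bins) of non-negative
#'   counts.
#' @param bin_width Time-bin width in picoseconds.
#' @param truth Optional ground-truth record attached by the simulator.
#' @return An object of class `decay_cube`.
#' @export
decay_cube <- function(counts, bin_width, truth = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("decay_cube: 'counts' must be a 3-D array (rows, cols, bins)")
  if (any(counts < 0)) stop("decay_cube: counts must be non-negative")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("decay_cube: 'bin_width' must be positive (ps)")
  structure(
    list(counts = counts, bin_width = bin_width,
         n_bins = dim(counts)[3L], truth = truth),
    class = "decay_cube"
  )
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "Decay cube: %d x %d pixels, %d bins x %.2f ps (%.2f ns window), %.0f total photons\n",
    d[1L], d[2L], d[3L], x$bin_width, d[3L] * x$bin_width / 1000,
    sum(x$counts)))
  invisible(x)
}

#' Per-pixel photon totals of a decay cube
#'
#' @param cube A `decay_cube`.
#' @return Matrix (rows x cols) of summed counts.
#' @export
photon_image <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  rowSums(cube$counts, dims = 2L)
}

#' Write/read a decay cube as a multi-page TIFF plus a JSON sidecar
#'
#' One 16-bit grayscale page per time bin; the sidecar records
#' `bin_width_ps` and `n_bins` so the time axis survives the round trip.
#'
#' @param cube A `decay_cube`.
#' @param tiff_path Path for the multi-page TIFF.
#' @param json_path Path for the sidecar; defaults to `tiff_path` with a
#'   `.json` extension appended.
#' @return Invisibly, the TIFF path.
#' @export
write_decay_cube <- function(cube, tiff_path, json_path = NULL) {
  stopifnot(inherits(cube, "decay_cube"))
  if (is.null(json_path)) json_path <- paste0(tiff_path, ".json")
  if (max(cube$counts) > 65535)
    stop("write_decay_cube: counts exceed the 16-bit range")
  pages <- lapply(seq_len(cube$n_bins), function(k) cube$counts[, , k] / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(bin_width_ps = cube$bin_width, n_bins = cube$n_bins),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(tiff_path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(tiff_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(tiff_path, ".json")
  meta <- jsonlite::read_json(json_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  counts <- round(array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages))) * 65535)
  decay_cube(counts, bin_width = meta$bin_width_ps)
}
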