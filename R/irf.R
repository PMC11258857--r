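#' Construct a Gaussian instrument response function (IRF)
#'
#' Builds a discretized Gaussian IRF histogram for use in decay simulation
#' and fitting. TCSPC systems convolve every fluorescence decay with the
#' temporal response of the instrument; a measured IRF (e.g., second-harmonic
#' generation from urea crystals) is typically close to Gaussian, so a
#' parametric Gaussian specified by its full width at half maximum (FWHM)
#' is used for synthesis and testing.
#'
#' @param fwhm Full width at half maximum in picoseconds (e.g., 240 ps for
#'   a typical multiphoton TCSPC system).
#' @param n_bins Number of time bins (>= 64).
#' @param bin_width Width of one time bin in picoseconds.
#' @param peak_bin Bin index (1-based) at which the IRF peaks; must be
#'   strictly inside the time window.
#' @return An object of class `irf`: a list with elements `counts`
#'   (non-negative, summing to 1), `bin_width`, `n_bins` and `peak_bin`.
#' @examples
#' irf <- make_irf(fwhm = 240, n_bins = 256, bin_width = 12500 / 256,
#'                 peak_bin = 25)
#' irf_fwhm(irf)  # close to 240
#' @export
make_irf <- function(fwhm, n_bins = 256L, bin_width = 12500 / 256,
                     peak_bin = 25L) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("make_irf: 'fwhm' must be a single positive number (ps)")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("make_irf: 'bin_width' must be positive (ps)")
  n_bins <- as.integer(n_bins)
  peak_bin <- as.integer(peak_bin)
  if (n_bins < 64L)
    stop("make_irf: 'n_bins' must be >= 64")
  if (peak_bin <= 1L || peak_bin >= n_bins)
    stop("make_irf: 'peak_bin' must lie strictly inside the time window")
  # bin centers; sigma from FWHM = 2*sqrt(2*log(2))*sigma
  t <- (seq_len(n_bins) - 0.5) * bin_width
  mu <- (peak_bin - 0.5) * bin_width
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  counts <- exp(-((t - mu)^2) / (2 * sigma^2))
  counts <- counts / sum(counts)
  structure(
    list(counts = counts, bin_width = bin_width, n_bins = n_bins,
         peak_bin = peak_bin),
    class = "irf"
  )
}

#' Measure the FWHM of an IRF histogram
#'
#' Interpolates linearly across the half-maximum crossings of the histogram.
#'
#' @param irf An `irf` object (or a bare numeric histogram plus `bin_width`).
#' @param bin_width Bin width in ps, only needed when `irf` is a bare vector.
#' @return FWHM in picoseconds.
#' @export
irf_fwhm <- function(irf, bin_width = NULL) {
  if (inherits(irf, "irf")) {
    counts <- irf$counts
    bin_width <- irf$bin_width
  } else {
    counts <- as.numeric(irf)
    if (is.null(bin_width)) stop("irf_fwhm: 'bin_width' required for a bare vector")
  }
  t <- (seq_along(counts) - 0.5) * bin_width
  half <- max(counts) / 2
  above <- which(counts >= half)
  if (length(above) == 0L) return(NA_real_)
  i1 <- above[1L]; i2 <- above[length(above)]
  # left crossing
  left <- if (i1 == 1L) t[1L] else {
    f <- (half - counts[i1 - 1L]) / (counts[i1] - counts[i1 - 1L])
    t[i1 - 1L] + f * bin_width
  }
  right <- if (i2 == length(counts)) t[i2] else {
    f <- (counts[i2] - half) / (counts[i2] - counts[i2 + 1L])
    t[i2] + f * bin_width
  }
  right - left
}

#' Read/write an IRF as a two-column CSV (bin, counts)
#'
#' @param path File path.
#' @param bin_width Bin width in picoseconds for the returned object.
#' @return `read_irf_csv` returns an `irf` object (counts renormalized to
#'   unit sum).
#' @export
read_irf_csv <- function(path, bin_width) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("read_irf_csv: expected columns (bin, counts)")
  counts <- as.numeric(df[[2L]])
  if (any(counts < 0) || sum(counts) <= 0)
    stop("read_irf_csv: counts must be non-negative with positive sum")
  counts <- counts / sum(counts)
  structure(
    list(counts = counts, bin_width = bin_width, n_bins = length(counts),
         peak_bin = which.max(counts)),
    class = "irf"
  )
}

#' @rdname read_irf_csv
#' @param irf An `irf` object to write.
#' @export
write_irf_csv <- function(irf, path) {
  stopifnot(inherits(irf, "irf"))
  utils::write.csv(
    data.frame(bin = seq_len(irf$n_bins), counts = irf$counts),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf(
    "IRF: %d bins x %.2f ps, peak at bin %d, measured FWHM %.1f ps\n",
    x$n_bins, x$bin_width, x$peak_bin, irf_fwhm(x)))
  invisible(x)
}
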