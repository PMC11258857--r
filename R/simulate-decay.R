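#' Ground truth for a simulated biexponential decay
#'
#' Bundles the parameters of a two-component NAD(P)H-style decay: a short
#' (free) lifetime, a long (protein-bound) lifetime, their fractional
#' contributions, a constant background rate and the expected photon yield
#' per pixel.
#'
#' @param tau1,tau2 Short and long lifetimes (ps); requires
#'   `0 < tau1 < tau2`.
#' @param a1 Fraction of the short component in \[0, 1\]; `a2 = 1 - a1`.
#' @param offset_rate Background counts per bin.
#' @param photons_target Expected decay photons per pixel (> 0), excluding
#'   the background offset.
#' @return An object of class `decay_ground_truth`.
#' @export
decay_ground_truth <- function(tau1, tau2, a1, offset_rate = 0,
                               photons_target = 5000) {
  if (!(tau1 > 0 && tau2 > tau1))
    stop("decay_ground_truth: need 0 < tau1 < tau2")
  if (a1 < 0 || a1 > 1) stop("decay_ground_truth: 'a1' must lie in [0, 1]")
  if (offset_rate < 0) stop("decay_ground_truth: 'offset_rate' must be >= 0")
  if (photons_target <= 0)
    stop("decay_ground_truth: 'photons_target' must be > 0")
  structure(
    list(tau1 = tau1, tau2 = tau2, a1 = a1, a2 = 1 - a1,
         offset_rate = offset_rate, photons_target = photons_target),
    class = "decay_ground_truth"
  )
}

#' Simulate a TCSPC decay cube with known ground truth
#'
#' Per-pixel counts are Poisson draws around the expected decay
#' `photons_target * s + offset_rate`, where `s` is the IRF-convolved
#' biexponential shape normalized to unit sum over the window. The
#' generating parameters are stored on the returned cube so downstream
#' fits can be scored against truth. Reproducible for a fixed seed.
#'
#' @param truth A `decay_ground_truth`.
#' @param irf An `irf` object with matching bin structure.
#' @param shape Integer vector (rows, cols); both must be >= 8.
#' @param seed Integer random seed.
#' @return A `decay_cube` with the truth attached.
#' @export
simulate_decay_cube <- function(truth, irf, shape = c(32L, 32L), seed = 1L) {
  stopifnot(inherits(truth, "decay_ground_truth"), inherits(irf, "irf"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop("simulate_decay_cube: 'shape' must be (rows, cols) with both >= 8")
  mu <- expected_decay(truth, irf)
  n_px <- prod(shape)
  counts <- withr::with_seed(seed, {
    array(stats::rpois(n_px * irf$n_bins,
                       lambda = rep(mu, each = n_px)),
          dim = c(shape, irf$n_bins))
  })
  decay_cube(counts, bin_width = irf$bin_width, truth = truth)
}

# expected per-bin counts for one pixel under the ground truth
expected_decay <- function(truth, irf) {
  s <- model_decay(truth$tau1, truth$tau2, truth$a1, amplitude = 1,
                   offset = 0, irf = irf)
  s <- s / sum(s)
  truth$photons_target * s + truth$offset_rate
}
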