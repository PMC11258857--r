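#' Ground truth for a simulated widefield autofluorescence field of view
#'
#' Describes one field of view (FOV): mean cell and gel-background
#' intensities in each channel (arbitrary units), the vignetting strength
#' and the implied true normalized optical redox ratio
#' \deqn{ORR = \frac{I_{cell,N}/I_{bg,N}}
#'                 {I_{cell,N}/I_{bg,N} + I_{cell,F}/I_{bg,F}}.}
#' The gel background is nonzero in both channels: hydrogel substrates are
#' weakly autofluorescent, which is exactly why the pipeline normalizes to
#' background.
#'
#' @param nadh_cell,fad_cell Mean cell intensities per channel (a.u., > 0).
#' @param nadh_bg,fad_bg Gel background intensities per channel (a.u., > 0).
#' @param vignette_strength Fractional falloff of illumination at the field
#'   corner, in \[0, 1).
#' @return An object of class `field_ground_truth` with the derived
#'   `orr_true`.
#' @export
field_ground_truth <- function(nadh_cell, fad_cell, nadh_bg, fad_bg,
                               vignette_strength = 0.15) {
  vals <- c(nadh_cell, fad_cell, nadh_bg, fad_bg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("field_ground_truth: all intensities must be positive")
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("field_ground_truth: 'vignette_strength' must lie in [0, 1)")
  rn <- nadh_cell / nadh_bg
  rf <- fad_cell / fad_bg
  structure(
    list(nadh_cell = nadh_cell, fad_cell = fad_cell,
         nadh_bg = nadh_bg, fad_bg = fad_bg,
         vignette_strength = vignette_strength,
         orr_true = rn / (rn + rf)),
    class = "field_ground_truth"
  )
}

#' Radial cosine-fourth illumination falloff
#'
#' Classic cos^4 vignetting: the off-axis angle grows linearly with the
#' normalized distance from the field center (45 degrees at the corner)
#' and the relative illumination is blended toward 1 by
#' `1 - strength * (1 - cos^4)`, so `strength = 0` yields flat
#' illumination.
#'
#' @param shape Integer (rows, cols).
#' @param strength Fraction in \[0, 1).
#' @return Matrix of relative illumination in (0, 1].
#' @export
vignette_field <- function(shape, strength) {
  nr <- shape[1L]; nc <- shape[2L]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
  r <- r / max(r)
  falloff <- cos(r * pi / 4)^4
  1 - strength * (1 - falloff)
}

# random non-overlapping ellipses; returns a binary matrix
make_ellipse_mask <- function(shape, n_cells = 25L, semi_axes = c(5, 12),
                              max_attempts = 40L * n_cells) {
  nr <- shape[1L]; nc <- shape[2L]
  mask <- matrix(0L, nr, nc)
  placed <- 0L; attempts <- 0L
  while (placed < n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    a <- stats::runif(1, semi_axes[1L], semi_axes[2L])
    b <- stats::runif(1, semi_axes[1L], semi_axes[2L])
    th <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, a + 2, nr - a - 2)
    cx <- stats::runif(1, a + 2, nc - a - 2)
    r0 <- max(1L, floor(cy - a - 1)); r1 <- min(nr, ceiling(cy + a + 1))
    c0 <- max(1L, floor(cx - a - 1)); c1 <- min(nc, ceiling(cx + a + 1))
    ys <- r0:r1; xs <- c0:c1
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    u <- dy * cos(th) + dx * sin(th)
    v <- -dy * sin(th) + dx * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (any(mask[ys, xs][inside] > 0L)) next  # keep cells disjoint
    sub <- mask[ys, xs]; sub[inside] <- 1L; mask[ys, xs] <- sub
    placed <- placed + 1L
  }
  mask
}

#' Simulate a registered NAD(P)H / FAD widefield image pair
#'
#' The expected image in each channel is
#' `vignette * (background + mask * (cell - background))`; the noise model
#' adds Poisson shot noise on the expected intensity plus Gaussian read
#' noise (a CMOS camera model). Both channels share the same cell geometry
#' and vignette, as in sequential imaging of one FOV. The true mask and
#' ground truth are attached for downstream scoring.
#'
#' @param truth A `field_ground_truth`.
#' @param shape Integer (rows, cols).
#' @param noise_model `"poisson-gaussian"` (default) or `"none"`.
#' @param seed Integer seed; the pair is a pure function of
#'   (arguments, seed).
#' @param n_cells Number of elliptical cells to place.
#' @param semi_axes Range of ellipse semi-axes in pixels.
#' @param read_noise_sd Gaussian read-noise SD; default 1% of the NAD(P)H
#'   background.
#' @param cell_mask Optional pre-made binary mask overriding the random
#'   ellipse geometry.
#' @return An object of class `widefield_pair`: matrices `nadh` and `fad`,
#'   the `truth` (with `cell_mask_true`), and a `saturated` flag.
#' @export
simulate_widefield_pair <- function(truth, shape = c(192L, 192L),
                                    noise_model = c("poisson-gaussian", "none"),
                                    seed = 1L, n_cells = 25L,
                                    semi_axes = c(5, 12),
                                    read_noise_sd = NULL,
                                    cell_mask = NULL) {
  stopifnot(inherits(truth, "field_ground_truth"))
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  if (is.null(read_noise_sd)) read_noise_sd <- 0.01 * truth$nadh_bg

  withr::with_seed(seed, {
    if (is.null(cell_mask)) cell_mask <- make_ellipse_mask(shape, n_cells,
                                                           semi_axes)
    if (mean(cell_mask) > 0.6)
      stop("simulate_widefield_pair: mask covers too much area to leave cell-free background regions")
    vig <- vignette_field(shape, truth$vignette_strength)
    expected <- function(cell, bg) vig * (bg + cell_mask * (cell - bg))
    noisy <- function(mu, sd) {
      if (noise_model == "none") return(mu)
      img <- stats::rpois(length(mu), lambda = mu) +
        stats::rnorm(length(mu), sd = sd)
      matrix(pmax(img, 0), nrow(mu), ncol(mu))
    }
    nadh <- noisy(expected(truth$nadh_cell, truth$nadh_bg), read_noise_sd)
    fad <- noisy(expected(truth$fad_cell, truth$fad_bg),
                 read_noise_sd * truth$fad_bg / truth$nadh_bg)
    saturated <- max(nadh, fad) >= 65535
    nadh <- pmin(nadh, 65535)
    fad <- pmin(fad, 65535)
    truth$cell_mask_true <- cell_mask
    structure(
      list(nadh = nadh, fad = fad, truth = truth, saturated = saturated,
           metadata = list()),
      class = "widefield_pair"
    )
  })
}

#' @export
print.widefield_pair <- function(x, ...) {
  cat(sprintf(
    "Widefield pair: %d x %d px, true ORR %.3f, cell area %.1f%%%s\n",
    nrow(x$nadh), ncol(x$nadh), x$truth$orr_true,
    100 * mean(x$truth$cell_mask_true),
    if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}
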