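#' Rolling-ball background subtraction
#'
#' Removes smooth background (vignetting, substrate autofluorescence
#' gradients) from a widefield image by subtracting its morphological
#' background estimate: a grayscale opening with a disc structuring
#' element of the given radius, the classic rolling-ball construction.
#' Structures smaller than the ball survive the subtraction; smooth
#' large-scale illumination does not. The output is clipped at zero and is
#' everywhere `<=` the input.
#'
#' The opening is computed in compiled code via a disc row decomposition
#' with sliding-window minima, so large radii stay fast; windows are
#' clamped at the image border (in-bounds neighborhood), which makes a
#' constant image a fixed point of the opening.
#'
#' @param image Numeric matrix of intensities.
#' @param radius Ball radius in pixels (>= 1 and smaller than the image).
#' @return Corrected image matrix.
#' @export
rolling_ball_subtract <- function(image, radius = 50) {
  if (!is.matrix(image)) stop("rolling_ball_subtract: 'image' must be a matrix")
  radius <- as.integer(radius)
  if (radius < 1L) stop("rolling_ball_subtract: 'radius' must be >= 1")
  if (2L * radius + 1L > min(dim(image)))
    stop("rolling_ball_subtract: radius too large for the image")
  bg <- gray_open_disc(image, radius)
  pmax(image - bg, 0)
}

#' Grayscale opening with a disc structuring element
#'
#' Erosion followed by dilation with the disc
#' \eqn{\{(dy, dx): dy^2 + dx^2 \le r^2\}}; the morphological background
#' estimate underlying [rolling_ball_subtract()].
#'
#' @param image Numeric matrix.
#' @param radius Disc radius in pixels.
#' @return Opened image matrix.
#' @export
gray_open_disc <- function(image, radius) {
  storage.mode(image) <- "double"
  .gray_dilate_disc(.gray_erode_disc(image, radius), radius)
}

#' Threshold a corrected image into a binary cell mask
#'
#' Pixels above the threshold become foreground; connected components
#' smaller than `min_object_px` are removed as noise specks. The threshold
#' method and value are recorded as provenance on the mask.
#'
#' @param image Corrected (background-subtracted) NAD(P)H image.
#' @param method `"otsu"` (default), `"fixed"` (uses `value`) or
#'   `"percentile"` (threshold at the `value` quantile, e.g. 0.9).
#' @param min_object_px Minimum connected-component area kept.
#' @param value Threshold value for `"fixed"`, or quantile for
#'   `"percentile"`.
#' @return An object of class `cell_mask`: a 0/1 integer matrix with a
#'   `provenance` attribute.
#' @export
make_cell_mask <- function(image, method = c("otsu", "fixed", "percentile"),
                           min_object_px = 64L, value = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("make_cell_mask: 'image' must be a matrix")
  lo <- min(image); hi <- max(image)
  if (hi == lo)
    stop("make_cell_mask: constant image, no foreground separable")
  thr <- switch(method,
    otsu = {
      x <- (image - lo) / (hi - lo)
      EBImage::otsu(EBImage::Image(x), range = c(0, 1)) * (hi - lo) + lo
    },
    fixed = {
      if (is.null(value)) stop("make_cell_mask: 'fixed' needs a value")
      value
    },
    percentile = {
      if (is.null(value)) stop("make_cell_mask: 'percentile' needs a value")
      stats::quantile(image, probs = value, names = FALSE)
    }
  )
  mask <- (image > thr) * 1L
  if (min_object_px > 0L && any(mask > 0L)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(as.integer(lab %in% keep), nrow(image))
  }
  structure(mask, class = c("cell_mask", "matrix"),
            provenance = list(method = method, threshold = thr,
                              min_object_px = min_object_px))
}

#' Mean intensity over a binary mask
#'
#' Masks are derived from the corrected NAD(P)H image but applied to the
#' raw images of both channels; saturated pixels (at the 16-bit maximum)
#' are excluded from the mean.
#'
#' @param image Raw intensity matrix.
#' @param mask Binary matrix (`cell_mask` or 0/1 matrix) of the same
#'   shape.
#' @param saturation Intensity treated as saturated (default 65535).
#' @return Mean intensity (scalar).
#' @export
measure_masked_mean <- function(image, mask, saturation = 65535) {
  if (!all(dim(image) == dim(mask)))
    stop("measure_masked_mean: shape mismatch")
  sel <- mask > 0 & image < saturation
  if (!any(sel)) stop("measure_masked_mean: empty mask")
  mean(image[sel])
}

#' Select cell-free background ROIs
#'
#' Deterministically chooses `n_rois` disjoint square regions fully
#' outside the dilated cell mask: candidate ROIs lie on a half-ROI-stride
#' grid, are ranked by (mask overlap, row, column), and only zero-overlap
#' candidates qualify; candidates overlapping an already-selected ROI are
#' skipped. Used to estimate gel background intensity per channel.
#'
#' @param mask Binary cell mask.
#' @param n_rois Number of ROIs (default 3).
#' @param roi_size Side of each square ROI in pixels.
#' @param margin Mask dilation radius (safety margin) in pixels.
#' @return A data.frame with columns `row`, `col`, `size` (top-left
#'   corners), one row per ROI.
#' @export
select_background_rois <- function(mask, n_rois = 3L, roi_size = 24L,
                                   margin = 3L) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (roi_size > min(nr, nc))
    stop("select_background_rois: ROI larger than the image")
  dil <- if (margin > 0L)
    EBImage::dilate(mask + 0, EBImage::makeBrush(2L * margin + 1L, "disc"))
  else mask
  stride <- max(1L, roi_size %/% 2L)
  rows <- unique(c(seq(1L, nr - roi_size + 1L, by = stride),
                   nr - roi_size + 1L))
  cols <- unique(c(seq(1L, nc - roi_size + 1L, by = stride),
                   nc - roi_size + 1L))
  cand <- expand.grid(row = rows, col = cols)
  cand$overlap <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand$row[i]; c <- cand$col[i]
    sum(dil[r:(r + roi_size - 1L), c:(c + roi_size - 1L)])
  }, numeric(1L))
  cand <- cand[cand$overlap == 0, , drop = FALSE]
  cand <- cand[order(cand$row, cand$col), , drop = FALSE]
  picked <- data.frame(row = integer(0), col = integer(0))
  for (i in seq_len(nrow(cand))) {
    if (nrow(picked) >= n_rois) break
    r <- cand$row[i]; c <- cand$col[i]
    clash <- any(abs(picked$row - r) < roi_size &
                 abs(picked$col - c) < roi_size)
    if (!clash) picked <- rbind(picked, data.frame(row = r, col = c))
  }
  if (nrow(picked) < n_rois)
    stop("select_background_rois: insufficient cell-free area; ",
         "supply manual ROIs")
  picked$size <- roi_size
  rownames(picked) <- NULL
  picked
}

#' Mean gel background intensity from cell-free ROIs
#'
#' Averages the image over `n_rois` automatically selected (or manually
#' supplied) disjoint cell-free square regions. This per-gel background
#' estimate absorbs day-to-day illumination drift, exposure differences
#' and substrate autofluorescence, and is the denominator of the
#' normalized ORR.
#'
#' @param image Raw intensity matrix.
#' @param mask Binary cell mask used to exclude cells.
#' @param n_rois Number of background ROIs (default 3).
#' @param roi_size ROI side length in pixels.
#' @param margin Mask dilation safety margin.
#' @param rois Optional manual ROI data.frame (`row`, `col`, `size`),
#'   overriding automatic selection.
#' @return Mean background intensity with the ROI table attached as
#'   attribute `rois`.
#' @export
measure_background <- function(image, mask, n_rois = 3L, roi_size = 24L,
                               margin = 3L, rois = NULL) {
  if (is.null(rois))
    rois <- select_background_rois(mask, n_rois, roi_size, margin)
  means <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois$row[i]; c <- rois$col[i]; s <- rois$size[i]
    mean(image[r:(r + s - 1L), c:(c + s - 1L)])
  }, numeric(1L))
  structure(mean(means), rois = rois, roi_means = means)
}

#' Background-normalized optical redox ratio
#'
#' Each channel's cell intensity is normalized to its own gel background,
#' \deqn{I_{N} = I_{cell,N}/I_{bg,N}, \quad I_{F} = I_{cell,F}/I_{bg,F},}
#' and the normalized ORR is \eqn{I_N / (I_N + I_F)}. Because each channel
#' is divided by its own background, any global gain applied to one
#' channel (lamp drift, exposure change, substrate autofluorescence
#' level) cancels out.
#'
#' @param i_cell_nadh,i_bg_nadh Mean cell and background NAD(P)H
#'   intensities (> 0).
#' @param i_cell_fad,i_bg_fad Mean cell and background FAD intensities
#'   (> 0).
#' @return A list with `i_norm_nadh`, `i_norm_fad` and `orr` (in (0, 1)).
#' @export
normalized_orr <- function(i_cell_nadh, i_bg_nadh, i_cell_fad, i_bg_fad) {
  vals <- c(i_cell_nadh, i_bg_nadh, i_cell_fad, i_bg_fad)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("normalized_orr: all intensities must be positive and finite")
  i_norm_nadh <- i_cell_nadh / i_bg_nadh
  i_norm_fad <- i_cell_fad / i_bg_fad
  list(i_norm_nadh = i_norm_nadh, i_norm_fad = i_norm_fad,
       orr = i_norm_nadh / (i_norm_nadh + i_norm_fad))
}

#' Configuration of the widefield ORR workflow
#'
#' @param rolling_ball_radius Rolling-ball radius in pixels.
#' @param threshold_method Cell-mask threshold method (see
#'   [make_cell_mask()]).
#' @param threshold_value Value/quantile for non-Otsu methods.
#' @param min_object_px Minimum kept object size in pixels.
#' @param n_background_rois Number of cell-free background ROIs.
#' @param roi_size Background ROI side length in pixels.
#' @param roi_margin Mask dilation margin around cells.
#' @param manual_rois Optional manual ROI data.frame overriding automatic
#'   background selection.
#' @return A list of class `ori_config`.
#' @export
ori_config <- function(rolling_ball_radius = 50L,
                       threshold_method = "otsu",
                       threshold_value = NULL,
                       min_object_px = 64L,
                       n_background_rois = 3L,
                       roi_size = 24L,
                       roi_margin = 3L,
                       manual_rois = NULL) {
  structure(
    list(rolling_ball_radius = rolling_ball_radius,
         threshold_method = threshold_method,
         threshold_value = threshold_value,
         min_object_px = min_object_px,
         n_background_rois = n_background_rois,
         roi_size = roi_size, roi_margin = roi_margin,
         manual_rois = manual_rois),
    class = "ori_config"
  )
}

#' Process one field of view into a gel record
#'
#' Runs the full widefield workflow on a registered image pair:
#' rolling-ball subtraction of the NAD(P)H image, thresholding into a cell
#' mask, mean cell intensity of both *raw* channels under that mask, mean
#' background from cell-free ROIs in both raw channels, and the
#' background-normalized ORR. Failures are reported with the name of the
#' failing stage.
#'
#' @param pair A `widefield_pair` (simulated or read from TIFFs).
#' @param config An [ori_config()].
#' @return A one-row data.frame (`gel_record`) with intensity, normalized
#'   intensity, `orr`, QC fields (`mask_area_fraction`, `n_bg_rois`,
#'   `saturated`) and any metadata/ground truth carried by the pair.
#' @export
process_fov <- function(pair, config = ori_config()) {
  stopifnot(inherits(pair, "widefield_pair"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("process_fov failed at %s: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  corrected <- stage("rolling_ball_subtract",
    rolling_ball_subtract(pair$nadh, config$rolling_ball_radius))
  mask <- stage("make_cell_mask",
    make_cell_mask(corrected, method = config$threshold_method,
                   min_object_px = config$min_object_px,
                   value = config$threshold_value))
  if (!any(mask > 0))
    stop("process_fov failed at make_cell_mask: empty mask", call. = FALSE)
  i_cell_nadh <- stage("measure_masked_mean",
                       measure_masked_mean(pair$nadh, mask))
  i_cell_fad <- stage("measure_masked_mean",
                      measure_masked_mean(pair$fad, mask))
  rois <- config$manual_rois
  if (is.null(rois))
    rois <- stage("select_background_rois",
      select_background_rois(mask, config$n_background_rois,
                             config$roi_size, config$roi_margin))
  i_bg_nadh <- as.numeric(stage("measure_background",
                                measure_background(pair$nadh, mask, rois = rois)))
  i_bg_fad <- as.numeric(stage("measure_background",
                               measure_background(pair$fad, mask, rois = rois)))
  orr <- stage("normalized_orr",
               normalized_orr(i_cell_nadh, i_bg_nadh, i_cell_fad, i_bg_fad))
  rec <- data.frame(
    i_cell_nadh = i_cell_nadh, i_bg_nadh = i_bg_nadh,
    i_cell_fad = i_cell_fad, i_bg_fad = i_bg_fad,
    i_norm_nadh = orr$i_norm_nadh, i_norm_fad = orr$i_norm_fad,
    orr = orr$orr,
    mask_area_fraction = mean(mask > 0),
    n_bg_rois = nrow(rois),
    saturated = isTRUE(pair$saturated)
  )
  for (nm in names(pair$metadata)) rec[[nm]] <- pair$metadata[[nm]]
  if (!is.null(pair$truth)) rec$orr_true <- pair$truth$orr_true
  class(rec) <- c("gel_record", class(rec))
  rec
}

#' Process every FOV of a simulated or on-disk plate
#'
#' @param plate A `simulated_plate` (in-memory pairs or an `out_dir` with
#'   TIFFs + manifest).
#' @param config An [ori_config()].
#' @return A data.frame of gel records, one row per FOV, joined with the
#'   manifest metadata (including `orr_true`).
#' @export
process_plate <- function(plate, config = ori_config()) {
  stopifnot(inherits(plate, "simulated_plate"))
  if (!is.null(plate$pairs)) {
    recs <- lapply(plate$pairs, process_fov, config = config)
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    return(out)
  }
  process_manifest(file.path(plate$out_dir, "manifest.csv"),
                   dir = plate$out_dir, config = config)
}

#' Process a manifest of TIFF image pairs on disk
#'
#' @param manifest Path to a manifest CSV (or a data.frame) with columns
#'   `file_nadh`, `file_fad` and metadata (`formulation`, `day`,
#'   `replicate`, `group`, optionally `orr_true`).
#' @param dir Directory containing the TIFFs.
#' @param config An [ori_config()].
#' @return A data.frame of gel records joined with the manifest metadata.
#' @export
process_manifest <- function(manifest, dir = ".", config = ori_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    nadh <- tiff::readTIFF(file.path(dir, manifest$file_nadh[i])) * 65535
    fad <- tiff::readTIFF(file.path(dir, manifest$file_fad[i])) * 65535
    pair <- structure(
      list(nadh = nadh, fad = fad, truth = NULL, saturated = FALSE,
           metadata = as.list(manifest[i, setdiff(names(manifest),
                                                  c("file_nadh", "file_fad"))])),
      class = "widefield_pair"
    )
    process_fov(pair, config)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
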