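# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately written as plain loops so they share no code path with the
# package implementation they check.

std_irf <- function() make_irf(fwhm = 240, n_bins = 256,
                               bin_width = 12500 / 256, peak_bin = 25)

# truncated linear convolution of an IRF with a biexponential, as an
# explicit double loop
oracle_model_decay <- function(tau1, tau2, a1, amplitude, offset, irf) {
  n <- irf$n_bins
  t <- (seq_len(n) - 1) * irf$bin_width
  d <- a1 * exp(-t / tau1) + (1 - a1) * exp(-t / tau2)
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(k)) s <- s + irf$counts[j] * d[k - j + 1]
    out[k] <- amplitude * s + offset
  }
  out
}

# 3x3 neighborhood sum by explicit looping
oracle_box_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    ys <- max(1, y - 1):min(nr, y + 1)
    xs <- max(1, x - 1):min(nc, x + 1)
    out[y, x] <- sum(m[ys, xs])
  }
  out
}

# grayscale erosion/dilation with the disc {dy^2+dx^2 <= r^2}, in-bounds
# neighborhood, explicit loops
oracle_disc_morph <- function(img, r, f) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    vals <- numeric(0)
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > r^2) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc)
        vals <- c(vals, img[yy, xx])
    }
    out[y, x] <- f(vals)
  }
  out
}

oracle_rolling_ball <- function(img, r) {
  bg <- oracle_disc_morph(oracle_disc_morph(img, r, min), r, max)
  pmax(img - bg, 0)
}

# Welch's t from first principles (independent of the package formulas)
oracle_welch <- function(x, y) {
  sx2 <- sum((x - mean(x))^2) / (length(x) - 1)
  sy2 <- sum((y - mean(y))^2) / (length(y) - 1)
  ax <- sx2 / length(x); ay <- sy2 / length(y)
  t <- (mean(x) - mean(y)) / sqrt(ax + ay)
  df <- (ax + ay)^2 / (ax^2 / (length(x) - 1) + ay^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small two-group plate design used in several tests
small_design <- function(seed = 1L, replicate_sd = 0.01,
                         days = c(6L, 8L, 10L, 16L)) {
  forms <- data.frame(
    formulation = c("7C-3I 2", "10C 4"),
    stiffness_kpa = c(10, 4),
    group = c("high", "low")
  )
  traj_hi <- default_orr_trajectory(days)
  traj_lo <- pmax(traj_hi - 0.05, 0.05)
  plate_design(forms, days = days,
               groups = list(high = traj_hi, low = traj_lo),
               replicates = 3L, replicate_sd = replicate_sd, seed = seed)
}
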