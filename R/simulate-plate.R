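#' Declarative design of a synthetic longitudinal screen
#'
#' A plate design maps gel formulations to efficiency groups and assigns
#' each group an ORR trajectory over imaging days. Typical screens image
#' on days 6, 8, 10 and 16 after differentiation, then every 3 days
#' through day 30 (early maturation) or every 10 days thereafter (late
#' maturation), with three replicate gels per formulation.
#'
#' @param formulations A data.frame with columns `formulation`,
#'   `stiffness_kpa` and `group`, or a character vector of labels (all
#'   assigned to the first group, stiffness `NA`).
#' @param days Strictly increasing integer vector of imaging days.
#' @param groups Named list: one ORR trajectory per group, each a numeric
#'   vector of per-day true ORR values in (0, 1) named by day. Defaults to
#'   a single `"high"` group following [default_orr_trajectory()].
#' @param replicates Replicate gels per formulation (>= 1; default 3).
#' @param replicate_sd SD of per-FOV Gaussian jitter on the trajectory ORR
#'   (default 0.01, matching typical gel-to-gel spread).
#' @param seed Integer seed controlling the whole plate.
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(formulations, days, groups = NULL, replicates = 3L,
                         replicate_sd = 0.01, seed = 1L) {
  if (is.character(formulations))
    formulations <- data.frame(formulation = formulations,
                               stiffness_kpa = NA_real_,
                               group = NA_character_)
  need <- c("formulation", "stiffness_kpa", "group")
  if (!all(need %in% names(formulations)))
    stop("plate_design: formulations need columns ",
         paste(need, collapse = ", "))
  days <- as.integer(days)
  if (any(diff(days) <= 0)) stop("plate_design: days must be strictly increasing")
  if (is.null(groups))
    groups <- list(high = default_orr_trajectory(days))
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("plate_design: groups must be a named list of trajectories")
  formulations$group[is.na(formulations$group)] <- names(groups)[1L]
  if (!all(formulations$group %in% names(groups)))
    stop("plate_design: formulation groups missing from 'groups'")
  for (g in names(groups)) {
    tr <- groups[[g]]
    if (!all(as.character(days) %in% names(tr)))
      stop("plate_design: trajectory for group '", g,
           "' must cover every day")
    if (any(tr <= 0 | tr >= 1))
      stop("plate_design: trajectory ORR values must lie in (0, 1)")
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("plate_design: replicates must be >= 1")
  if (anyDuplicated(formulations$formulation))
    stop("plate_design: duplicate formulation labels")
  structure(
    list(formulations = formulations, days = days, groups = groups,
         replicates = replicates, replicate_sd = replicate_sd,
         seed = as.integer(seed)),
    class = "plate_design"
  )
}

#' Reference ORR trajectory over differentiation and maturation
#'
#' The qualitative pattern seen in cardiomyocyte differentiation screens:
#' ORR rises from the cardiac-progenitor stage (day 6) to day 10 as cells
#' remain glycolytic, falls by the differentiation timepoint (day 16) as
#' oxidative metabolism ramps up, and keeps declining through early
#' (day 30) and late (day 100) maturation. Values at the anchor days
#' (6, 8, 10, 16, 30, 100) are linearly interpolated to the requested
#' days.
#'
#' @param days Integer vector of days (within \[6, 100\]).
#' @param anchors Named numeric vector of anchor ORR values.
#' @return Named numeric vector of ORR values, one per requested day.
#' @export
default_orr_trajectory <- function(days,
                                   anchors = c(`6` = 0.55, `8` = 0.58,
                                               `10` = 0.60, `16` = 0.52,
                                               `30` = 0.45, `100` = 0.35)) {
  ad <- as.numeric(names(anchors))
  out <- stats::approx(ad, anchors, xout = days, rule = 2)$y
  names(out) <- as.character(days)
  out
}

#' Simulate a whole longitudinal plate with known per-FOV ground truth
#'
#' Generates one widefield image pair per (formulation, replicate, day).
#' Each FOV's true ORR is its group trajectory value plus Gaussian
#' replicate jitter; intensities are derived so the NAD(P)H cell/background
#' contrast stays fixed while the FAD contrast encodes the target ORR.
#' Fully reproducible from the design seed. When `out_dir` is given, 16-bit
#' TIFFs and a `manifest.csv` are written; otherwise pairs are kept in
#' memory.
#'
#' @param design A `plate_design`.
#' @param out_dir Optional output directory for TIFFs + manifest.
#' @param shape FOV shape in pixels.
#' @param noise_model Passed to [simulate_widefield_pair()].
#' @param nadh_bg,fad_bg Gel background intensities (a.u.).
#' @param nadh_contrast Cell/background ratio in the NAD(P)H channel.
#' @param vignette_strength Illumination falloff fraction.
#' @param n_cells Cells per FOV.
#' @return An object of class `simulated_plate`: `manifest` (data.frame,
#'   one row per FOV), `pairs` (named list of `widefield_pair`, `NULL`
#'   when written to disk), `design`, `out_dir`.
#' @export
simulate_plate <- function(design, out_dir = NULL, shape = c(192L, 192L),
                           noise_model = "poisson-gaussian",
                           nadh_bg = 400, fad_bg = 300,
                           nadh_contrast = 2.5, vignette_strength = 0.15,
                           n_cells = 25L) {
  stopifnot(inherits(design, "plate_design"))
  grid <- expand.grid(
    replicate = seq_len(design$replicates),
    formulation = design$formulations$formulation,
    day = design$days,
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$formulation, grid$replicate, grid$day), ]
  key <- paste(grid$formulation, grid$replicate, grid$day)
  if (anyDuplicated(key))
    stop("simulate_plate: duplicate (formulation, replicate, day) keys")
  meta <- design$formulations[match(grid$formulation,
                                    design$formulations$formulation), ]
  n <- nrow(grid)
  draws <- withr::with_seed(design$seed, list(
    jitter = stats::rnorm(n, 0, design$replicate_sd),
    seeds = sample.int(2147483646L, n)
  ))
  traj <- mapply(function(g, d) design$groups[[g]][[as.character(d)]],
                 meta$group, grid$day)
  orr_true <- pmin(pmax(traj + draws$jitter, 0.05), 0.95)

  slug <- gsub("[^A-Za-z0-9._-]+", "-", grid$formulation)
  base <- sprintf("%s_r%d_d%02d", slug, grid$replicate, grid$day)
  manifest <- data.frame(
    file_nadh = paste0(base, "_nadh.tif"),
    file_fad = paste0(base, "_fad.tif"),
    formulation = grid$formulation,
    stiffness_kpa = meta$stiffness_kpa,
    day = grid$day,
    replicate = grid$replicate,
    group = meta$group,
    orr_true = orr_true,
    row.names = NULL
  )

  pairs <- vector("list", n)
  names(pairs) <- base
  for (i in seq_len(n)) {
    # fixed NAD(P)H contrast; FAD contrast carries the ORR signal
    rf <- nadh_contrast * (1 - orr_true[i]) / orr_true[i]
    tr <- field_ground_truth(
      nadh_cell = nadh_bg * nadh_contrast, fad_cell = fad_bg * rf,
      nadh_bg = nadh_bg, fad_bg = fad_bg,
      vignette_strength = vignette_strength
    )
    pairs[[i]] <- simulate_widefield_pair(
      tr, shape = shape, noise_model = noise_model, seed = draws$seeds[i],
      n_cells = n_cells
    )
    pairs[[i]]$metadata <- as.list(manifest[i, c("formulation", "day",
                                                 "replicate", "group")])
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_len(n)) {
      tiff::writeTIFF(pairs[[i]]$nadh / 65535,
                      file.path(out_dir, manifest$file_nadh[i]),
                      bits.per.sample = 16L, compression = "none")
      tiff::writeTIFF(pairs[[i]]$fad / 65535,
                      file.path(out_dir, manifest$file_fad[i]),
                      bits.per.sample = 16L, compression = "none")
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    pairs <- NULL
  }
  structure(
    list(manifest = manifest, pairs = pairs, design = design,
         out_dir = out_dir),
    class = "simulated_plate"
  )
}

#' @export
print.simulated_plate <- function(x, ...) {
  cat(sprintf(
    "Simulated plate: %d formulations x %d replicates x %d days = %d FOVs%s\n",
    nrow(x$design$formulations), x$design$replicates,
    length(x$design$days), nrow(x$manifest),
    if (is.null(x$out_dir)) " (in memory)" else paste0(" in ", x$out_dir)))
  invisible(x)
}
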