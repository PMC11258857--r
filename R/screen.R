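#' Join per-FOV gel records with a screen design
#'
#' Validates that every record resolves to a known (formulation, day) in
#' the design, rejects duplicate (formulation, replicate, day, group)
#' keys, and returns a deterministically sorted screen table. Records that
#' failed processing can be passed through `failures` and are reported,
#' never silently dropped.
#'
#' @param records Data.frame of gel records (from [process_plate()] or
#'   [process_manifest()]), with columns `formulation`, `day`,
#'   `replicate`, `group`, `orr`.
#' @param design Optional `plate_design` to validate against.
#' @param failures Optional data.frame of failed FOVs (carried in the
#'   `failures` attribute).
#' @return A `screen_table` data.frame sorted by (group, formulation,
#'   replicate, day).
#' @export
aggregate_screen <- function(records, design = NULL, failures = NULL) {
  need <- c("formulation", "day", "replicate", "group", "orr")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("aggregate_screen: records missing columns ",
         paste(miss, collapse = ", "))
  if (!is.null(design)) {
    stopifnot(inherits(design, "plate_design"))
    bad_f <- setdiff(records$formulation, design$formulations$formulation)
    if (length(bad_f) > 0)
      stop("aggregate_screen: unknown formulation label(s): ",
           paste(bad_f, collapse = ", "))
    bad_d <- setdiff(records$day, design$days)
    if (length(bad_d) > 0)
      stop("aggregate_screen: unknown day(s): ",
           paste(bad_d, collapse = ", "))
  }
  key <- paste(records$formulation, records$replicate, records$day,
               records$group)
  if (anyDuplicated(key))
    stop("aggregate_screen: duplicate (formulation, replicate, day, group) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- records[order(records$group, records$formulation,
                       records$replicate, records$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  class(out) <- c("screen_table", class(out))
  out
}

#' Percent change in group-mean ORR between two days
#'
#' Reports `100 * (mean_b - mean_a) / mean_a`. Two conventions are
#' offered: `"group_means"` (default) differences the per-day group means;
#' `"per_gel"` averages the per-gel percent changes after pairing gels by
#' (formulation, replicate) across the two days. Longitudinal screens are
#' typically summarized this way, e.g. the ORR drop from the progenitor
#' stage (day 6) to early maturation (day 30).
#'
#' @param table A `screen_table` (or compatible data.frame).
#' @param group Group label; `NULL` uses all rows.
#' @param day_a,day_b The two days compared (change reported a -> b).
#' @param value Column summarized (default `"orr"`).
#' @param method `"group_means"` or `"per_gel"`.
#' @return A one-row data.frame (`comparison_result`) with means, mean
#'   difference, `percent_change` and per-side n.
#' @export
percent_change <- function(table, group = NULL, day_a, day_b,
                           value = "orr",
                           method = c("group_means", "per_gel")) {
  method <- match.arg(method)
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  a <- table[table$day == day_a, , drop = FALSE]
  b <- table[table$day == day_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("percent_change: day ", if (nrow(a) == 0) day_a else day_b,
         " not present", if (!is.null(group)) paste0(" for group ", group))
  mean_a <- mean(a[[value]]); mean_b <- mean(b[[value]])
  pc <- if (method == "group_means") {
    100 * (mean_b - mean_a) / mean_a
  } else {
    ka <- paste(a$formulation, a$replicate)
    kb <- paste(b$formulation, b$replicate)
    common <- intersect(ka, kb)
    if (length(common) == 0)
      stop("percent_change: no gels present on both days")
    va <- a[[value]][match(common, ka)]
    vb <- b[[value]][match(common, kb)]
    mean(100 * (vb - va) / va)
  }
  out <- data.frame(
    group = if (is.null(group)) NA_character_ else group,
    day_a = day_a, day_b = day_b,
    mean_a = mean_a, mean_b = mean_b,
    mean_difference = mean_b - mean_a,
    percent_change = pc, method = method,
    n_a = nrow(a), n_b = nrow(b)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Implemented from the standard formulas: the statistic
#' \deqn{t = \frac{\bar x_a - \bar x_b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_a^2/n_a + s_b^2/n_b)^2}
#'   {(s_a^2/n_a)^2/(n_a-1) + (s_b^2/n_b)^2/(n_b-1)}}
#' and a two-sided p-value from the t distribution.
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @return A list with `t`, `df`, `p_value`, means and n per side.
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t_test: need at least 2 observations per side")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  se2 <- vx + vy
  if (se2 == 0) {
    t <- 0; df <- nx + ny - 2; p <- 1
  } else {
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p_value = p, mean_x = mean(x), mean_y = mean(y),
       n_x = nx, n_y = ny)
}

#' Compare two groups' ORR at one day (Welch's t-test)
#'
#' Used to test efficiency-group separation, e.g. whether
#' low-differentiation-efficiency cultures show a different ORR than
#' high-efficiency cultures at the cardiac-progenitor stage.
#'
#' @param table A `screen_table` (or compatible data.frame).
#' @param day Day at which to compare.
#' @param group_a,group_b Group labels.
#' @param value Column compared (default `"orr"`).
#' @return A one-row `comparison_result` data.frame with group means,
#'   difference, percent difference, `t`, `df`, `p_value` and per-side n.
#' @export
compare_groups <- function(table, day, group_a, group_b, value = "orr") {
  x <- table[[value]][table$day == day & table$group == group_a]
  y <- table[[value]][table$day == day & table$group == group_b]
  if (length(x) < 2L || length(y) < 2L)
    stop("compare_groups: need >= 2 replicates per group on day ", day)
  w <- welch_t_test(x, y)
  out <- data.frame(
    group_a = group_a, group_b = group_b, day = day,
    mean_a = w$mean_x, mean_b = w$mean_y,
    mean_difference = w$mean_y - w$mean_x,
    percent_change = 100 * (w$mean_y - w$mean_x) / w$mean_x,
    t = w$t, df = w$df, p_value = w$p_value,
    n_a = w$n_x, n_b = w$n_y
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Per-group, per-formulation day-series summary
#'
#' Descriptive trajectory report: mean, SD and n of ORR per (group,
#' formulation, day), plus per-group day means and day-over-day changes.
#' Optionally writes a CSV and a trajectory figure. Purely descriptive;
#' no inferential claims.
#'
#' @param table A `screen_table` (or compatible data.frame).
#' @param value Column summarized (default `"orr"`).
#' @param out_dir Optional directory; writes `trajectory_summary.csv`,
#'   `group_day_means.csv` and `trajectories.png`.
#' @return A list with `summary` (per formulation/day), `group_means`
#'   (per group/day, with `change` from the previous day) — both
#'   data.frames sorted deterministically.
#' @export
trajectory_report <- function(table, value = "orr", out_dir = NULL) {
  if (nrow(table) == 0) stop("trajectory_report: empty table")
  sd_or_na <- function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_
  smry <- do.call(rbind, lapply(
    split(table, list(table$group, table$formulation, table$day),
          drop = TRUE),
    function(d) data.frame(
      group = d$group[1L], formulation = d$formulation[1L], day = d$day[1L],
      mean = mean(d[[value]]), sd = sd_or_na(d[[value]]), n = nrow(d))
  ))
  smry <- smry[order(smry$group, smry$formulation, smry$day), ]
  rownames(smry) <- NULL

  gm <- do.call(rbind, lapply(split(table, list(table$group, table$day),
                                    drop = TRUE),
    function(d) data.frame(group = d$group[1L], day = d$day[1L],
                           mean = mean(d[[value]]),
                           sd = sd_or_na(d[[value]]), n = nrow(d))))
  gm <- gm[order(gm$group, gm$day), ]
  rownames(gm) <- NULL
  gm$change <- stats::ave(gm$mean, gm$group,
                          FUN = function(v) c(NA, diff(v)))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(smry, file.path(out_dir, "trajectory_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(gm, file.path(out_dir, "group_day_means.csv"),
                     row.names = FALSE)
    p <- ggplot2::ggplot(
      smry, ggplot2::aes(x = day, y = mean, group = formulation,
                         colour = group)) +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "Day post-differentiation", y = "Normalized ORR",
                    colour = "Group") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, "trajectories.png"), p,
                    width = 6, height = 4, dpi = 150)
  }
  list(summary = smry, group_means = gm)
}
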