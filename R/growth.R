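#' Sliding-window regression slopes of a growth curve
#'
#' Ordinary least-squares slopes of (log) OD against time in hours, fitted
#' in overlapping sliding windows of `window` consecutive timepoints
#' (step 1). With the default log transform the slope of a window in
#' exponential phase is the per-hour growth rate.
#'
#' @param curve Data frame with `time_min` (strictly increasing) and `od`.
#' @param window Window width in timepoints (default 10).
#' @param transform `"log"` (natural log of OD, default) or `"linear"`.
#' @param blank Optional blank OD subtracted before the transform; values
#'   driven non-positive are floored at `1e-6` with a warning.
#' @return A tibble with `window_index` (1-based start of the window),
#'   `t_start` (hours) and `slope` (per hour). Under the log transform,
#'   windows containing non-positive OD are skipped with a warning.
#' @export
#' @examples
#' gc <- sim_growth_curve(0.3, carrying_capacity = Inf, noise_sd = 0)
#' range(sliding_slopes(gc)$slope)
sliding_slopes <- function(curve, window = 10L, transform = c("log", "linear"),
                           blank = NULL) {
  transform <- match.arg(transform)
  stopifnot(all(c("time_min", "od") %in% names(curve)))
  if (is.unsorted(curve$time_min, strictly = TRUE))
    abort("sliding_slopes: `time_min` must be strictly increasing")
  n <- nrow(curve)
  if (n < window)
    abort(paste0("sliding_slopes: need at least ", window, " timepoints"))
  od <- curve$od
  if (!is.null(blank)) {
    od <- od - blank
    if (any(od <= 0)) {
      warn("sliding_slopes: blank subtraction produced non-positive OD; floored at 1e-6")
      od <- pmax(od, 1e-6)
    }
  }
  t_h <- curve$time_min / 60
  y <- if (transform == "log") {
    bad <- od <= 0
    if (any(bad))
      warn(paste0("sliding_slopes: ", sum(bad),
                  " non-positive OD value(s); affected windows skipped"))
    suppressWarnings(log(od))
  } else {
    od
  }
  starts <- seq_len(n - window + 1L)
  slopes <- purrr::map_dbl(starts, function(i) {
    idx <- i:(i + window - 1L)
    yy <- y[idx]
    if (any(!is.finite(yy))) return(NA_real_)
    tt <- t_h[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  })
  out <- tibble(window_index = starts, t_start = t_h[starts], slope = slopes)
  filter(out, is.finite(.data$slope))
}

#' Maximum growth rate as the 98th percentile of sliding slopes
#'
#' The maximum growth rate of a curve is the 98th percentile of its
#' sliding-window regression slopes — a robust stand-in for the maximum
#' slope that discounts the very top of the slope distribution. The
#' percentile uses linear interpolation between closest ranks
#' (`stats::quantile` type 7).
#'
#' @param slopes A [sliding_slopes()] result, or a bare numeric vector of
#'   slopes.
#' @param percentile Percentile in (0, 1] (default 0.98).
#' @return A tibble with `rate` (per hour) and `n_windows`.
#' @export
max_growth_rate <- function(slopes, percentile = 0.98) {
  s <- if (is.data.frame(slopes)) slopes$slope else slopes
  s <- s[is.finite(s)]
  if (length(s) == 0) abort("max_growth_rate: no slopes")
  tibble(
    rate = unname(quantile(s, percentile, type = 7)),
    n_windows = length(s)
  )
}

#' Growth rate of one or many curves
#'
#' Convenience wrapper chaining [sliding_slopes()] and [max_growth_rate()],
#' grouped by any of `strain_id`, `replicate_id` present in the input.
#'
#' @param curves Data frame with `time_min`, `od` and optional `strain_id`,
#'   `replicate_id` columns.
#' @inheritParams sliding_slopes
#' @inheritParams max_growth_rate
#' @return A tibble with the grouping columns, `rate` and `n_windows`.
#' @export
#' @examples
#' gc <- sim_growth_curve(0.35, seed = 2)
#' growth_rate(gc)
growth_rate <- function(curves, window = 10L, percentile = 0.98,
                        transform = c("log", "linear"), blank = NULL) {
  transform <- match.arg(transform)
  keys <- intersect(c("strain_id", "replicate_id"), names(curves))
  if (length(keys) == 0) {
    return(max_growth_rate(
      sliding_slopes(curves, window, transform, blank), percentile
    ))
  }
  curves |>
    group_by(across(dplyr::all_of(keys))) |>
    group_split() |>
    purrr::map(function(g) {
      dplyr::bind_cols(
        g[1, keys, drop = FALSE],
        max_growth_rate(sliding_slopes(g, window, transform, blank),
                        percentile)
      )
    }) |>
    bind_rows()
}

#' Summarise replicate growth rates per strain
#'
#' @param rates A [growth_rate()] result with `strain_id`.
#' @return A tibble per strain: `mean_rate`, `se_rate`, `n_replicates`.
#' @export
summarise_rates <- function(rates) {
  stopifnot("strain_id" %in% names(rates))
  rates |>
    group_by(.data$strain_id) |>
    summarise(
      mean_rate = mean(.data$rate),
      se_rate = sd(.data$rate) / sqrt(n()),
      n_replicates = n(),
      .groups = "drop"
    )
}

#' Fitness change between two growth-rate measurements
#'
#' The change in fitness by WGD is the difference between the maximum growth
#' rate after and before the event; the post-WGD change per generation
#' additionally divides by the number of generations evolved after the
#' event.
#'
#' @param before,after Growth rates (per hour): numbers or single-row
#'   [max_growth_rate()] tibbles.
#' @param generations Optional generation count for the per-generation
#'   convention; must be nonzero when supplied.
#' @return A tibble with `kind` (`"delta"` or `"delta_per_generation"`),
#'   `delta`, and `generations`.
#' @export
#' @examples
#' fitness_change(0.30, 0.33)
#' fitness_change(0.30, 0.34, generations = 400)
fitness_change <- function(before, after, generations = NULL) {
  b <- if (is.data.frame(before)) before$rate else before
  a <- if (is.data.frame(after)) after$rate else after
  d <- a - b
  if (is.null(generations)) {
    tibble(kind = "delta", delta = d, generations = NA_real_)
  } else {
    if (any(generations == 0))
      abort("fitness_change: `generations` must be nonzero")
    tibble(kind = "delta_per_generation", delta = d / generations,
           generations = generations)
  }
}
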