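#' Find density peaks in a fluorescence distribution
#'
#' Local maxima of a Gaussian kernel density estimate of per-cell
#' fluorescence, used to locate the G1 and G2 cell populations. Peaks with
#' height below `min_prominence` of the maximum density (debris shoulders)
#' are discarded. The two highest remaining peaks are the main peaks.
#'
#' @param values Numeric vector of per-cell fluorescence (>= 100 finite
#'   values required).
#' @param bandwidth KDE bandwidth: `"auto"` for Silverman's rule-of-thumb
#'   (`stats::bw.nrd0`), or a positive number.
#' @param min_prominence Minimum peak density as a fraction of the maximum
#'   density (default 0.05).
#' @param n_main If not `NULL`, require at least this many peaks and return
#'   only the top `n_main`; fewer detectable peaks is an error.
#' @param sample_id Label used in error messages.
#' @return A tibble with `position` and `density`, sorted by density
#'   (highest first).
#' @export
#' @examples
#' x <- c(rnorm(600, 200, 10), rnorm(400, 400, 20))
#' density_peaks(x)
density_peaks <- function(values, bandwidth = "auto", min_prominence = 0.05,
                          n_main = NULL, sample_id = "sample") {
  values <- values[is.finite(values)]
  if (length(values) < 100)
    abort(paste0("density_peaks: fewer than 100 finite values in ", sample_id))
  if (diff(range(values)) == 0) {
    # degenerate distribution: a single peak at the common value
    pk <- tibble(position = values[1], density = Inf)
  } else {
    bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values) else bandwidth
    d <- density(values, bw = bw, n = 1024)
    y <- d$y
    is_max <- y > dplyr::lag(y, default = -Inf) &
      y >= dplyr::lead(y, default = -Inf)
    keep <- is_max & y >= min_prominence * max(y)
    pk <- tibble(position = d$x[keep], density = y[keep])
    pk <- arrange(pk, dplyr::desc(.data$density))
  }
  if (nrow(pk) < 1)
    abort(paste0("density_peaks: no detectable peak in ", sample_id))
  if (!is.null(n_main)) {
    if (nrow(pk) < n_main)
      abort(paste0(
        "density_peaks: ", n_main, " main peaks requested but only ",
        nrow(pk), " found in ", sample_id
      ))
    pk <- pk[seq_len(n_main), ]
  }
  pk
}

#' Calibrate the fluorescence-per-genome unit from control strains
#'
#' Fits the fluorescence per haploid genome equivalent as the least-squares
#' slope through the origin of G1 peak position against known control ploidy,
#' \eqn{u = \sum p g / \sum p^2}. Controls are the parental strains measured
#' in haploid and diploid state. A control whose own G2/G1 peak ratio falls
#' outside [1.6, 2.4] is excluded as unreliable.
#'
#' @param controls Long-format data frame with columns `control_id`,
#'   `known_ploidy` and `fluorescence` (one row per cell).
#' @param bandwidth,min_prominence Passed to [density_peaks()].
#' @return An object of class `"ploidy_calibration"`: a list with `unit`
#'   (fluorescence per haploid genome) and `control_peaks` (per-control G1/G2
#'   peak positions and inclusion flag).
#' @export
#' @examples
#' ctl <- dplyr::bind_rows(
#'   dplyr::tibble(control_id = "hap", known_ploidy = 1,
#'                 fluorescence = sim_fluorescence(1, 2000, seed = 1)$fluorescence),
#'   dplyr::tibble(control_id = "dip", known_ploidy = 2,
#'                 fluorescence = sim_fluorescence(2, 2000, seed = 2)$fluorescence))
#' calibrate_ploidy(ctl)$unit
calibrate_ploidy <- function(controls, bandwidth = "auto",
                             min_prominence = 0.05) {
  stopifnot(all(c("control_id", "known_ploidy", "fluorescence") %in%
                  names(controls)))
  per <- controls |>
    group_by(.data$control_id, .data$known_ploidy) |>
    summarise(peaks = list(density_peaks(
      .data$fluorescence, bandwidth = bandwidth,
      min_prominence = min_prominence,
      sample_id = dplyr::cur_group()$control_id
    )), .groups = "drop") |>
    mutate(
      g1_peak = purrr::map_dbl(.data$peaks, ~ min(.x$position[1:min(2, nrow(.x))])),
      g2_peak = purrr::map_dbl(.data$peaks, ~ {
        if (nrow(.x) < 2) NA_real_ else max(.x$position[1:2])
      }),
      ratio = .data$g2_peak / .data$g1_peak,
      usable = !is.na(.data$ratio) & .data$ratio >= 1.6 & .data$ratio <= 2.4
    ) |>
    select(-"peaks")
  ok <- filter(per, .data$usable)
  if (nrow(ok) == 0)
    abort("calibrate_ploidy: no usable control (all failed the G2/G1 ratio check)")
  unit <- sum(ok$known_ploidy * ok$g1_peak) / sum(ok$known_ploidy^2)
  structure(
    list(unit = unit, control_peaks = per),
    class = "ploidy_calibration"
  )
}

#' @export
print.ploidy_calibration <- function(x, ...) {
  cat("Ploidy calibration: unit =", format(x$unit, digits = 5),
      "a.u. per haploid genome,", sum(x$control_peaks$usable),
      "of", nrow(x$control_peaks), "controls used\n")
  invisible(x)
}

#' Call ploidy per line and timepoint from fluorescence distributions
#'
#' For each line x timepoint group, locates the two main density peaks of the
#' per-cell fluorescence distribution (the G1 and G2 cell populations), takes
#' the lower-position peak as G1, and converts it to a continuous ploidy
#' estimate via the calibration unit. The ploidy class is the nearest integer
#' when the estimate lies within `class_tolerance` of it, and `"fractional"`
#' otherwise (the fractional call is what reveals progressive ploidy
#' reduction, e.g. ~2.8n intermediates). If the G2/G1 ratio falls outside
#' [1.6, 2.4] or only one peak is found, ploidy is called from the dominant
#' peak alone and the call is flagged `"warn"`.
#'
#' @param samples Long-format data frame with columns `line_id`,
#'   `generations` and `fluorescence` (optionally `cross_id`), one row per
#'   cell.
#' @param calibration A [calibrate_ploidy()] result, or a single number
#'   taken as the unit directly.
#' @param bandwidth,min_prominence Passed to [density_peaks()].
#' @param class_tolerance Half-width of the integer rounding band on the
#'   continuous ploidy (default 0.15; an estimate further than this from
#'   every integer — like the ~2.8n decaying tetraploids — is `"fractional"`).
#' @return A tibble with one row per line x timepoint: `line_id`
#'   (`cross_id` if supplied), `generations`, `g1_peak`, `g2_peak`,
#'   `ploidy` (continuous), `ploidy_class` (integer, `NA` when fractional),
#'   `fractional`, `qc_flag`.
#' @export
#' @examples
#' smp <- sim_fluorescence(4, 2000, seed = 5)
#' calls <- call_ploidy(
#'   dplyr::tibble(line_id = "l1", generations = 770,
#'                 fluorescence = smp$fluorescence), calibration = 100)
#' calls$ploidy_class
call_ploidy <- function(samples, calibration, bandwidth = "auto",
                        min_prominence = 0.05, class_tolerance = 0.15) {
  unit <- if (inherits(calibration, "ploidy_calibration")) {
    calibration$unit
  } else if (is.numeric(calibration) && length(calibration) == 1) {
    calibration
  } else {
    abort("`calibration` must be a ploidy_calibration or a single number")
  }
  if (unit <= 0) abort("calibration unit must be > 0")
  keys <- intersect(c("line_id", "cross_id", "generations"), names(samples))
  if (!all(c("line_id", "generations", "fluorescence") %in% names(samples)))
    abort("`samples` needs columns line_id, generations, fluorescence")
  samples |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(call = list({
      id <- paste(dplyr::cur_group(), collapse = "/")
      pk <- density_peaks(.data$fluorescence, bandwidth = bandwidth,
                          min_prominence = min_prominence, sample_id = id)
      if (nrow(pk) >= 2) {
        two <- pk[1:2, ]
        g1 <- min(two$position)
        g2 <- max(two$position)
        ratio <- g2 / g1
        if (ratio >= 1.6 && ratio <= 2.4) {
          tibble(g1_peak = g1, g2_peak = g2, qc_flag = "pass")
        } else {
          # ratio check failed: fall back to the dominant peak
          tibble(g1_peak = pk$position[1], g2_peak = NA_real_,
                 qc_flag = "warn")
        }
      } else {
        tibble(g1_peak = pk$position[1], g2_peak = NA_real_, qc_flag = "warn")
      }
    }), .groups = "drop") |>
    tidyr::unnest("call") |>
    mutate(
      ploidy = .data$g1_peak / unit,
      fractional = abs(.data$ploidy - round(.data$ploidy)) > class_tolerance |
        round(.data$ploidy) < 1,
      ploidy_class = if_else(.data$fractional, NA_integer_,
                             as.integer(round(.data$ploidy)))
    ) |>
    arrange(across(dplyr::all_of(keys)))
}

#' Detect whole-genome duplication events in ploidy trajectories
#'
#' Scans each line's time-ordered ploidy calls for the first timepoint whose
#' ploidy class is at least twice the line's baseline (its class at the first
#' observed timepoint, so triploid-start lines are judged against 3n). A
#' single tetraploid observation records an event; if a later call returns
#' below twice the baseline the event is annotated `reverted = TRUE`, not
#' erased.
#'
#' @param calls A [call_ploidy()] result covering one or more lines.
#' @param baseline_ploidy Integer baseline to use for every line; default
#'   `NULL` uses each line's own first-timepoint class.
#' @param end_generations If given, `extinct_before_end` flags lines whose
#'   last observation precedes this generation count.
#' @return A tibble with one row per line that duplicated: `line_id`
#'   (`cross_id` if present), `first_tetraploid_timepoint` (generations),
#'   `baseline_ploidy`, `reverted`, `extinct_before_end`. Zero rows when no
#'   line duplicated.
#' @export
#' @examples
#' calls <- dplyr::tibble(line_id = "l1", generations = c(0, 90, 385, 770),
#'   ploidy_class = c(2L, 2L, 4L, 4L))
#' detect_wgd(calls)
detect_wgd <- function(calls, baseline_ploidy = NULL, end_generations = NULL) {
  stopifnot(all(c("line_id", "generations", "ploidy_class") %in% names(calls)))
  keys <- intersect(c("line_id", "cross_id"), names(calls))
  calls |>
    group_by(across(dplyr::all_of(keys))) |>
    arrange(.data$generations, .by_group = TRUE) |>
    group_split() |>
    purrr::map(function(tr) {
      if (is.unsorted(tr$generations, strictly = TRUE))
        abort("detect_wgd: timepoints must be strictly increasing within a line")
      base <- baseline_ploidy %||% tr$ploidy_class[1]
      if (is.na(base)) return(NULL)
      hit <- which(!is.na(tr$ploidy_class) & tr$ploidy_class >= 2L * base)
      if (length(hit) == 0) return(NULL)
      i <- hit[1]
      later <- tr$ploidy_class[seq_len(nrow(tr)) > i]
      # fractional intermediates below 2x baseline (e.g. 4n -> ~2.8n) also
      # count as reversion when the continuous estimate is available
      later_cont <- if ("ploidy" %in% names(tr)) {
        tr$ploidy[seq_len(nrow(tr)) > i]
      } else {
        later
      }
      dplyr::bind_cols(
        tr[i, keys, drop = FALSE],
        tibble(
          first_tetraploid_timepoint = tr$generations[i],
          baseline_ploidy = as.integer(base),
          reverted = any(!is.na(later) & later < 2L * base) ||
            any(!is.na(later_cont) & later_cont < 2 * base - 0.25),
          extinct_before_end = if (is.null(end_generations)) NA else
            max(tr$generations) < end_generations
        )
      )
    }) |>
    purrr::compact() |>
    bind_rows()
}

#' Per-cross WGD rate
#'
#' The WGD rate of a cross is the number of lines with a recorded WGD event
#' divided by the number of lines in the denominator set. With the default
#' `"founding"` policy the denominator is every line present at the initial
#' timepoint (extinct lines stay in); `"surviving"` restricts it to lines
#' still observed at the final timepoint.
#'
#' @param events A [detect_wgd()] result.
#' @param calls The [call_ploidy()] table the events came from (defines the
#'   line/cross universe and observation span).
#' @param denominator `"founding"` (default) or `"surviving"`.
#' @return A tibble per cross: `cross_id`, `n_events`, `n_lines`, `rate`
#'   (proportion in [0, 1]).
#' @export
wgd_rate <- function(events, calls, denominator = c("founding", "surviving")) {
  denominator <- match.arg(denominator)
  if (!"cross_id" %in% names(calls)) calls$cross_id <- "all"
  if (nrow(calls) == 0) abort("wgd_rate: empty cross")
  lines <- calls |>
    group_by(.data$cross_id, .data$line_id) |>
    summarise(
      first_gen = min(.data$generations),
      last_gen = max(.data$generations), .groups = "drop"
    )
  if (denominator == "surviving") {
    end_gen <- max(calls$generations)
    lines <- filter(lines, .data$last_gen == end_gen)
  }
  denom <- count(lines, .data$cross_id, name = "n_lines")
  ev <- if (nrow(events) == 0) {
    tibble(cross_id = character(), n_events = integer())
  } else {
    if (!"cross_id" %in% names(events)) events$cross_id <- "all"
    count(events, .data$cross_id, name = "n_events")
  }
  denom |>
    left_join(ev, by = "cross_id") |>
    mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      rate = .data$n_events / .data$n_lines
    ) |>
    select("cross_id", "n_events", "n_lines", "rate")
}

#' Cumulative WGD counts along the experiment
#'
#' Counts, at each observed timepoint, the lines whose first tetraploid
#' observation is at or before that timepoint — the cumulative-curve view of
#' WGD emergence.
#'
#' @param events A [detect_wgd()] result.
#' @param timepoints Numeric vector of observation timepoints (generations);
#'   defaults to the event timepoints themselves.
#' @return A tibble per cross: `cross_id`, `generations`,
#'   `cumulative_count` (non-decreasing).
#' @export
wgd_cumulative <- function(events, timepoints = NULL) {
  if (nrow(events) == 0) {
    return(tibble(cross_id = character(), generations = double(),
                  cumulative_count = integer()))
  }
  if (!"cross_id" %in% names(events)) events$cross_id <- "all"
  tp <- sort(unique(timepoints %||% events$first_tetraploid_timepoint))
  events |>
    group_by(.data$cross_id) |>
    reframe_cumulative(tp)
}

reframe_cumulative <- function(grouped, tp) {
  dplyr::reframe(
    grouped,
    generations = tp,
    cumulative_count = purrr::map_int(
      tp, ~ sum(.data$first_tetraploid_timepoint <= .x)
    )
  )
}
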