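#' Bin per-base read depth into fixed windows
#'
#' Averages a samtools-depth-style per-base depth table over tiling windows
#' (10 kb by default; the final window of a chromosome may be shorter). When
#' `chrom_lengths` is supplied, positions absent from the input count as
#' depth 0 and windows tile the full chromosome; otherwise windows are
#' averaged over observed positions only and the result is flagged.
#'
#' @param depth Data frame with columns `chrom`, `pos` (1-based), `depth`,
#'   sorted by position within chromosome.
#' @param window Window width in bp (default 10000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A tibble with `chrom`, `start` (0-based half-open), `end`,
#'   `mean_depth` and `partial` (`TRUE` when averaged over observed
#'   positions only).
#' @export
#' @examples
#' d <- dplyr::tibble(chrom = "chrA", pos = 1:25000, depth = 90)
#' bin_depth(d, chrom_lengths = c(chrA = 25000))
bin_depth <- function(depth, window = 10000L, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  unsorted <- depth |>
    group_by(.data$chrom) |>
    summarise(bad = is.unsorted(.data$pos), .groups = "drop")
  if (any(unsorted$bad))
    abort(paste0("bin_depth: positions not sorted within ",
                 paste(unsorted$chrom[unsorted$bad], collapse = ", ")))
  have_len <- !is.null(chrom_lengths)
  binned <- depth |>
    mutate(start = ((.data$pos - 1L) %/% window) * window) |>
    group_by(.data$chrom, .data$start) |>
    summarise(total = sum(.data$depth), n_obs = n(), .groups = "drop")
  if (have_len) {
    full <- purrr::imap(
      chrom_lengths[names(chrom_lengths) %in% unique(depth$chrom)],
      function(len, chr) {
        starts <- seq(0L, len - 1L, by = window)
        tibble(chrom = chr, start = starts, end = pmin(starts + window, len))
      }
    ) |> bind_rows()
    full |>
      left_join(binned, by = c("chrom", "start")) |>
      mutate(
        mean_depth = dplyr::coalesce(.data$total, 0) /
          (.data$end - .data$start),
        partial = FALSE
      ) |>
      select("chrom", "start", "end", "mean_depth", "partial") |>
      arrange(.data$chrom, .data$start)
  } else {
    binned |>
      mutate(
        end = .data$start + window,
        mean_depth = .data$total / .data$n_obs,
        partial = TRUE
      ) |>
      select("chrom", "start", "end", "mean_depth", "partial") |>
      arrange(.data$chrom, .data$start)
  }
}

#' Normalize window depths by genome-wide coverage
#'
#' Divides each window's mean depth by the genome-wide coverage, defined as
#' the mean of all window mean depths across the genome, yielding unitless
#' depth ratios (1.0 = euploid baseline).
#'
#' @param windows A [bin_depth()]-style tibble (`chrom`, `start`, `end`,
#'   `mean_depth`).
#' @param genome_coverage Overriding genome-wide coverage; default is the
#'   mean of `mean_depth` over all windows.
#' @return The input tibble with an added `ratio` column.
#' @export
normalize_depth <- function(windows, genome_coverage = NULL) {
  stopifnot("mean_depth" %in% names(windows))
  gc <- genome_coverage %||% mean(windows$mean_depth)
  if (!is.finite(gc) || gc <= 0)
    abort("normalize_depth: genome-wide coverage must be > 0")
  mutate(windows, ratio = .data$mean_depth / gc)
}

#' Chromosome copy number from the median window depth ratio
#'
#' The per-chromosome copy number is the median of the chromosome's
#' normalized window ratios multiplied by the baseline ploidy and rounded to
#' the nearest integer. Calls whose scaled median has a fractional part in
#' the no-call band (default \[0.35, 0.65\]) are flagged `"warn"` rather than
#' trusted. Windows overlapping an optional mask (e.g. the rDNA array on
#' chromosome XII, one of the most unstable regions of the genome) are
#' excluded from the median.
#'
#' @param windows A [normalize_depth()] result (needs `chrom`, `start`,
#'   `end`, `ratio`).
#' @param baseline_ploidy Euploid baseline (default 2).
#' @param mask Optional data frame of 0-based half-open intervals (`chrom`,
#'   `start`, `end`) to exclude.
#' @param no_call_band Fractional-part interval flagged as ambiguous.
#' @return A tibble per chromosome: `chrom`, `n_windows`,
#'   `normalized_median`, `copy_number`, `baseline_ploidy`, `aneuploid`,
#'   `qc_flag`.
#' @export
#' @examples
#' w <- sim_depth_track(c(chrA = 3, chrB = 2), c(chrA = 2e5, chrB = 2e5),
#'                      seed = 1) |> normalize_depth()
#' chromosome_copy_number(w)
chromosome_copy_number <- function(windows, baseline_ploidy = 2L,
                                   mask = NULL, no_call_band = c(0.35, 0.65)) {
  stopifnot(all(c("chrom", "ratio") %in% names(windows)))
  if (!is.null(mask) && nrow(mask) > 0) {
    masked <- purrr::pmap(
      list(mask$chrom, mask$start, mask$end),
      function(mc, ms, me) {
        windows$chrom == mc & windows$start < me & windows$end > ms
      }
    ) |> purrr::reduce(`|`)
    windows <- windows[!masked, ]
  }
  out <- windows |>
    group_by(.data$chrom) |>
    summarise(
      n_windows = n(),
      normalized_median = median(.data$ratio),
      .groups = "drop"
    )
  if (any(out$n_windows < 3))
    abort(paste0("chromosome_copy_number: fewer than 3 windows on ",
                 paste(out$chrom[out$n_windows < 3], collapse = ", ")))
  out |>
    mutate(
      scaled = .data$normalized_median * baseline_ploidy,
      copy_number = as.integer(round(.data$scaled)),
      baseline_ploidy = as.integer(baseline_ploidy),
      aneuploid = .data$copy_number != baseline_ploidy,
      qc_flag = if_else(
        .data$scaled %% 1 >= no_call_band[1] &
          .data$scaled %% 1 <= no_call_band[2],
        "warn", "pass"
      )
    ) |>
    select(-"scaled")
}

#' Consensus copy number across window calls
#'
#' The consensus chromosome copy number is the most common value across
#' per-window integer calls; ties are broken toward the value closest to the
#' baseline ploidy, then toward the smaller value.
#'
#' @param window_calls Integer vector of per-window copy-number calls.
#' @param baseline_ploidy Euploid baseline used for tie-breaking.
#' @return A single integer.
#' @export
#' @examples
#' consensus_copy_number(c(2L, 2L, 2L, 3L))
#' consensus_copy_number(c(2L, 3L), baseline_ploidy = 2)
consensus_copy_number <- function(window_calls, baseline_ploidy = 2L) {
  if (length(window_calls) == 0)
    abort("consensus_copy_number: empty call list")
  tab <- table(window_calls)
  vals <- as.integer(names(tab))
  cand <- vals[tab == max(tab)]
  cand <- cand[order(abs(cand - baseline_ploidy), cand)]
  cand[1]
}

#' Chromosome gains and losses between two timepoints
#'
#' Joins per-chromosome copy numbers at the initial and final sequenced
#' timepoints and reports the delta (gained > 0, lost < 0) per chromosome.
#'
#' @param cn_ini,cn_end [chromosome_copy_number()]-style tibbles for the
#'   same chromosome set (optionally carrying a shared `line_id` column).
#' @return A tibble: (`line_id`,) `chrom`, `cn_initial`, `cn_end`, `delta`.
#' @export
aneuploidy_delta <- function(cn_ini, cn_end) {
  keys <- intersect(c("line_id", "chrom"), intersect(names(cn_ini),
                                                     names(cn_end)))
  if (!"chrom" %in% keys) abort("aneuploidy_delta: `chrom` column required")
  a <- select(cn_ini, dplyr::all_of(keys), cn_initial = "copy_number")
  b <- select(cn_end, dplyr::all_of(keys), cn_end = "copy_number")
  if (!setequal(
    do.call(paste, a[keys]), do.call(paste, b[keys])
  ))
    abort("aneuploidy_delta: chromosome sets differ between timepoints")
  a |>
    left_join(b, by = keys) |>
    mutate(delta = .data$cn_end - .data$cn_initial)
}

#' Count aneuploid chromosomes per line at the final timepoint
#'
#' A line's aneuploidy count is the number of chromosomes whose final copy
#' number differs from the line's baseline ploidy at that timepoint (so a 4n
#' line with one chromosome at 3 copies counts one aneuploidy).
#'
#' @param calls An [aneuploidy_delta()] result with a `line_id` column.
#' @param baseline_end Integer baseline ploidy at the final timepoint, either
#'   a single value or a data frame (`line_id`, `baseline_end`).
#' @return A tibble: `line_id`, `n_aneuploid`.
#' @export
aneuploidy_count <- function(calls, baseline_end = 2L) {
  stopifnot("line_id" %in% names(calls))
  if (is.data.frame(baseline_end)) {
    calls <- left_join(calls, baseline_end, by = "line_id")
  } else {
    calls$baseline_end <- as.integer(baseline_end)
  }
  calls |>
    group_by(.data$line_id) |>
    summarise(
      n_aneuploid = sum(.data$cn_end != .data$baseline_end),
      .groups = "drop"
    )
}

#' Per-chromosome gain and loss frequencies
#'
#' For each chromosome, the fraction of lines gaining (`delta > 0`) and
#' losing (`delta < 0`) copies — the gain/loss spectrum contrasted between
#' ploidy classes and crosses.
#'
#' @param calls An [aneuploidy_delta()] result with `line_id`.
#' @param group Optional extra grouping column name (e.g. `"cross_id"` or a
#'   ploidy-class column) present in `calls`.
#' @return A tibble: (`group`,) `chrom`, `n_lines`, `n_gain`, `n_loss`,
#'   `gain_freq`, `loss_freq`.
#' @export
gain_loss_spectrum <- function(calls, group = NULL) {
  if (nrow(calls) == 0) abort("gain_loss_spectrum: no calls")
  keys <- c(group, "chrom")
  calls |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      n_lines = dplyr::n_distinct(.data$line_id),
      n_gain = sum(.data$delta > 0),
      n_loss = sum(.data$delta < 0),
      .groups = "drop"
    ) |>
    mutate(
      gain_freq = .data$n_gain / .data$n_lines,
      loss_freq = .data$n_loss / .data$n_lines
    )
}
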