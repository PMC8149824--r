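#' Filter Freebayes SNP records to reliable parent-informative markers
#'
#' Applies the marker selection rules used for allele-frequency analysis:
#' keep biallelic SNPs with `QUAL > 1`, `QUAL/AO > 10`, alternate
#' observations on both strands (`SAF > 0`, `SAR > 0`), reads centred on
#' both sides of the allele (`RPR > 1`, `RPL > 1`) and balanced mapping
#' quality (`0.9 < MQM/MQMR < 1.05`). Indels, multiallelic records and
#' records overlapping a supplied repeat mask are excluded. Records missing
#' a required field are skipped and counted.
#'
#' @param records Data frame of VCF records with columns `chrom`, `pos`,
#'   `qual`, `ao`, `saf`, `sar`, `rpr`, `rpl`, `mqm`, `mqmr` and logical
#'   `is_indel`, `is_multiallelic` (see [read_freebayes_vcf()]).
#' @param repeats Optional repeat mask: data frame of 0-based half-open
#'   intervals (`chrom`, `start`, `end`).
#' @return The retained records, with the number of records skipped for
#'   missing fields in attribute `"n_skipped"` (also reported via a
#'   message when nonzero).
#' @export
filter_snps <- function(records, repeats = NULL) {
  need <- c("chrom", "pos", "qual", "ao", "saf", "sar", "rpr", "rpl",
            "mqm", "mqmr")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    abort(paste0("filter_snps: missing columns ",
                 paste(missing_cols, collapse = ", ")))
  if (!"is_indel" %in% names(records)) records$is_indel <- FALSE
  if (!"is_multiallelic" %in% names(records)) records$is_multiallelic <- FALSE
  incomplete <- !stats::complete.cases(records[need])
  n_skipped <- sum(incomplete)
  if (n_skipped > 0)
    inform(paste0("filter_snps: skipped ", n_skipped,
                  " record(s) with missing required fields"))
  rec <- records[!incomplete, ]
  keep <- rec$qual > 1 &
    rec$qual / rec$ao > 10 &
    rec$saf > 0 &
    rec$sar > 0 &
    rec$rpr > 1 &
    rec$rpl > 1 &
    rec$mqm / rec$mqmr > 0.9 &
    rec$mqm / rec$mqmr < 1.05 &
    !rec$is_indel &
    !rec$is_multiallelic
  keep[is.na(keep)] <- FALSE
  out <- rec[keep, ]
  if (!is.null(repeats) && nrow(repeats) > 0 && nrow(out) > 0) {
    in_rep <- purrr::pmap(
      list(repeats$chrom, repeats$start, repeats$end),
      function(rc, rs, re) out$chrom == rc & out$pos > rs & out$pos <= re
    ) |> purrr::reduce(`|`)
    out <- out[!in_rep, ]
  }
  attr(out, "n_skipped") <- n_skipped
  as_tibble(out)
}

#' Compute parental allele frequencies on a marker track
#'
#' The allele frequency of a heterozygous marker is the read depth of the
#' parent-A allele divided by the total read depth. Markers with total depth
#' of `min_depth` reads or fewer are dropped (the rule is strict: depth must
#' be *higher than* `min_depth`). The chromosome baseline is the arithmetic
#' mean allele frequency over all retained markers of the chromosome,
#' computed before any candidate exclusion.
#'
#' @param markers Data frame with `chrom`, `pos`, `depth_a`, `total_depth`
#'   (an `af` column, if present, is recomputed).
#' @param min_depth Depth threshold; markers with `total_depth > min_depth`
#'   are kept (default 20).
#' @return A tibble sorted by position within chromosome with `af` and a
#'   chromosome-wide `baseline_af` column. Empty input after filtering gives
#'   an empty tibble with a warning.
#' @export
#' @examples
#' m <- dplyr::tibble(chrom = "chrI", pos = c(100, 200), depth_a = c(11, 30),
#'                    total_depth = c(22, 60))
#' compute_af(m)
compute_af <- function(markers, min_depth = 20) {
  stopifnot(all(c("chrom", "pos", "depth_a", "total_depth") %in%
                  names(markers)))
  out <- markers |>
    filter(.data$total_depth > min_depth) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(af = .data$depth_a / .data$total_depth) |>
    group_by(.data$chrom) |>
    mutate(baseline_af = mean(.data$af)) |>
    ungroup()
  if (nrow(out) == 0)
    warn("compute_af: no markers left after depth filtering")
  out
}

#' Segment loss-of-heterozygosity tracts from allele frequencies
#'
#' Implements the three-rule segmentation: (1) markers whose allele
#' frequency deviates from the chromosome-average baseline by more than
#' `deviation` are LOH candidates; (2) segments are runs of at least
#' `min_markers` successive candidate markers sharing the same allele
#' frequency, i.e. each within `af_tolerance` of the running mean of the
#' current run; (3) consecutive member markers must be no further apart than
#' `max_gap` (300 bp for hybrid crosses, 1 kb for low-heterozygosity
#' intra-lineage crosses). A non-candidate marker, an over-long gap or an
#' allele-frequency break closes the current run. Segment size is the
#' distance between the first and last member SNP. A segment containing the
#' chromosome's first or last retained marker is `terminal`, otherwise
#' `interstitial`.
#'
#' @param track A [compute_af()] result (needs `chrom`, `pos`, `af`,
#'   `baseline_af`).
#' @param deviation Minimum absolute deviation from the chromosome baseline
#'   for a candidate marker (default 0.15, strict).
#' @param af_tolerance Allowed departure of a member from the running mean
#'   allele frequency of its run (default 0.1).
#' @param max_gap Maximum spacing in bp between consecutive member SNPs
#'   (default 300).
#' @param min_markers Minimum run length (default 3).
#' @param min_marker_density Refuse segmentation (with an informative error)
#'   when the chromosome's marker density falls below this floor in markers
#'   per bp (default 1/10000); very low heterozygosity prevents accurate LOH
#'   measurement. Set to 0 to disable.
#' @return A tibble of segments: `chrom`, `start`, `end` (positions of first
#'   and last member SNP), `size`, `n_markers`, `segment_af`,
#'   `retained_parent` (`"a"` if the segment allele frequency exceeds the
#'   baseline, else `"b"`), `kind` (`"terminal"`/`"interstitial"`).
#' @export
#' @examples
#' trk <- dplyr::tibble(chrom = "chrI", pos = c(500, 1000, 1100, 1200, 2000),
#'   af = c(0.5, 1, 1, 1, 0.5), baseline_af = 0.5)
#' detect_loh(trk)
detect_loh <- function(track, deviation = 0.15, af_tolerance = 0.1,
                       max_gap = 300, min_markers = 3L,
                       min_marker_density = 1e-4) {
  stopifnot(all(c("chrom", "pos", "af") %in% names(track)))
  if (!"baseline_af" %in% names(track)) {
    track <- track |>
      group_by(.data$chrom) |>
      mutate(baseline_af = mean(.data$af)) |>
      ungroup()
  }
  track |>
    group_by(.data$chrom) |>
    group_split() |>
    purrr::map(function(tr) {
      tr <- arrange(tr, .data$pos)
      if (is.unsorted(tr$pos, strictly = TRUE))
        abort("detect_loh: duplicated marker positions")
      if (min_marker_density > 0 && nrow(tr) > 1) {
        dens <- nrow(tr) / diff(range(tr$pos))
        if (dens < min_marker_density)
          abort(paste0(
            "detect_loh: marker density on ", tr$chrom[1], " (",
            signif(dens, 3), "/bp) is below the floor of ",
            signif(min_marker_density, 3),
            "/bp; heterozygosity too low for reliable LOH calls"
          ))
      }
      segment_markers(tr, deviation, af_tolerance, max_gap, min_markers)
    }) |>
    bind_rows()
}

# Greedy left-to-right run construction over one chromosome's markers.
segment_markers <- function(tr, deviation, af_tolerance, max_gap,
                            min_markers) {
  n <- nrow(tr)
  base <- tr$baseline_af[1]
  candidate <- abs(tr$af - base) > deviation
  segs <- list()
  run <- integer(0)
  run_sum <- 0
  close_run <- function() {
    if (length(run) >= min_markers) {
      segs[[length(segs) + 1L]] <<- run
    }
    run <<- integer(0)
    run_sum <<- 0
  }
  for (i in seq_len(n)) {
    if (!candidate[i]) {
      close_run()
      next
    }
    if (length(run) == 0) {
      run <- i
      run_sum <- tr$af[i]
      next
    }
    gap_ok <- tr$pos[i] - tr$pos[run[length(run)]] <= max_gap
    af_ok <- abs(tr$af[i] - run_sum / length(run)) <= af_tolerance
    if (gap_ok && af_ok) {
      run <- c(run, i)
      run_sum <- run_sum + tr$af[i]
    } else {
      close_run()
      run <- i
      run_sum <- tr$af[i]
    }
  }
  close_run()
  if (length(segs) == 0) {
    return(tibble(
      chrom = character(), start = double(), end = double(), size = double(),
      n_markers = integer(), segment_af = double(),
      retained_parent = character(), kind = character()
    ))
  }
  purrr::map(segs, function(idx) {
    tibble(
      chrom = tr$chrom[1],
      start = tr$pos[idx[1]],
      end = tr$pos[idx[length(idx)]],
      size = tr$pos[idx[length(idx)]] - tr$pos[idx[1]],
      n_markers = length(idx),
      segment_af = mean(tr$af[idx]),
      retained_parent = if (mean(tr$af[idx]) > base) "a" else "b",
      kind = if (1L %in% idx || nrow(tr) %in% idx) "terminal"
             else "interstitial"
    )
  }) |> bind_rows()
}

#' Summarise LOH segments per line and kind
#'
#' Counts segments and summarises sizes separately for interstitial and
#' terminal tracts. Cross-comparison statistics use only segments strictly
#' larger than `min_size` (1 kb by default), because the minimum detectable
#' size differs between cross classes; the full table retains all segments.
#'
#' @param segments A [detect_loh()] result, optionally with `line_id` and/or
#'   `cross_id` columns.
#' @param min_size Size threshold (bp) for the comparison subset
#'   (default 1000, strict).
#' @return A tibble grouped by any of `cross_id`, `line_id`, `kind` present:
#'   `n_segments` (all), `n_comparison` (size > `min_size`), `total_bp`,
#'   `median_size`.
#' @export
loh_summary <- function(segments, min_size = 1000) {
  keys <- intersect(c("cross_id", "line_id", "kind"), names(segments))
  if (nrow(segments) == 0) {
    return(tibble(n_segments = 0L, n_comparison = 0L,
                  total_bp = 0, median_size = NA_real_))
  }
  segments |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      n_segments = n(),
      n_comparison = sum(.data$size > min_size),
      total_bp = sum(.data$size),
      median_size = median(.data$size),
      .groups = "drop"
    )
}

#' Annotate triploid LOH segments with the lost parental allele class
#'
#' In a triploid hybrid one parent contributes two chromosome copies and the
#' other one, so the baseline parent-A allele frequency sits near 1/3 or
#' 2/3. Segmentation is unchanged; each segment is annotated with which
#' parental allele class was lost and how many copies, from the shift of the
#' segment allele frequency relative to the baseline in units of 1/3.
#'
#' @param track A [compute_af()] result whose `baseline_af` is near 1/3 or
#'   2/3 (a warning is raised otherwise).
#' @param ... Passed to [detect_loh()] (e.g. `max_gap`).
#' @return The [detect_loh()] segments with extra columns `lost_parent`
#'   (`"a"`/`"b"`) and `copies_lost`.
#' @export
triploid_allele_loss <- function(track, ...) {
  base <- unique(round(track$baseline_af, 2))
  if (!any(abs(track$baseline_af - 1 / 3) < 0.1 |
             abs(track$baseline_af - 2 / 3) < 0.1))
    warn(paste0(
      "triploid_allele_loss: baseline allele frequency (",
      paste(base, collapse = ", "),
      ") is not near 1/3 or 2/3; not a 2:1 triploid context?"
    ))
  segs <- detect_loh(track, ...)
  if (nrow(segs) == 0) {
    segs$lost_parent <- character(0)
    segs$copies_lost <- integer(0)
    return(segs)
  }
  base_by_chrom <- distinct(track, .data$chrom, .data$baseline_af)
  segs |>
    left_join(base_by_chrom, by = "chrom") |>
    mutate(
      # allele frequency moving down means parent-a copies were lost
      lost_parent = if_else(.data$segment_af < .data$baseline_af, "a", "b"),
      copies_lost = pmax(1L, as.integer(round(
        abs(.data$segment_af - .data$baseline_af) * 3
      )))
    ) |>
    select(-"baseline_af")
}
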