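#' Spore viability from tetrad dissection counts
#'
#' Viability is the proportion of dissected spores that form a visible
#' colony — the standard fertility proxy in yeast.
#'
#' @param records Data frame with `line_id`, `stage`
#'   (e.g. `"diploid_before_wgd"` / `"tetraploid_after_wgd"`),
#'   `spores_dissected`, `colonies`.
#' @return The input with an added `viability` column (proportion in
#'   \[0, 1\]).
#' @export
#' @examples
#' spore_viability(dplyr::tibble(line_id = "l1", stage = "diploid_before_wgd",
#'                               spores_dissected = 40, colonies = 30))
spore_viability <- function(records) {
  stopifnot(all(c("line_id", "stage", "spores_dissected", "colonies") %in%
                  names(records)))
  if (any(records$colonies > records$spores_dissected |
            records$colonies < 0))
    abort("spore_viability: `colonies` must be in [0, spores_dissected]")
  mutate(records, viability = .data$colonies / .data$spores_dissected)
}

#' Compare viability before and after WGD within lines
#'
#' Pairs each line's viability before and after the WGD event and runs a
#' two-sided paired t-test on the difference. Lines lacking either stage are
#' excluded with a warning. When every within-line difference is zero the
#' t statistic is undefined and the comparison is reported explicitly as
#' no-change (`p = NA`).
#'
#' @param viability A [spore_viability()] result with both stages.
#' @param before,after The `stage` labels to pair.
#' @return A list of class `"paired_viability"` with `pairs` (tibble of
#'   per-line before/after values and deltas) and `test` (one-row tibble:
#'   `estimate`, `statistic`, `p.value`, `n`).
#' @export
viability_change <- function(viability,
                             before = "diploid_before_wgd",
                             after = "tetraploid_after_wgd") {
  wide <- viability |>
    filter(.data$stage %in% c(before, after)) |>
    select("line_id", "stage", "viability") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "viability")
  if (!all(c(before, after) %in% names(wide)))
    abort("viability_change: one of the stages has no records")
  unpaired <- !stats::complete.cases(wide[c(before, after)])
  if (any(unpaired))
    warn(paste0("viability_change: excluded ", sum(unpaired),
                " unpaired line(s)"))
  wide <- wide[!unpaired, ]
  delta <- wide[[after]] - wide[[before]]
  test <- if (length(delta) < 2 || sd(delta) == 0) {
    tibble(estimate = mean(delta), statistic = NA_real_,
           p.value = NA_real_, n = length(delta))
  } else {
    tt <- t.test(wide[[after]], wide[[before]], paired = TRUE)
    tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
           p.value = tt$p.value, n = length(delta))
  }
  structure(
    list(pairs = mutate(wide, delta = delta), test = test),
    class = "paired_viability"
  )
}

#' Nonparametric group comparison with omnibus and pairwise tests
#'
#' The standard statistical battery for per-cross rate comparisons: a
#' Kruskal-Wallis omnibus test across all groups plus unadjusted pairwise
#' two-sided Mann-Whitney-Wilcoxon tests (reported regardless of the omnibus
#' outcome, matching how the figures annotate every pair). For paired
#' designs a two-sided paired t-test is run instead. Small samples without
#' ties use the exact Wilcoxon distribution; larger samples or ties use the
#' midrank normal approximation (the `stats::wilcox.test` switch).
#'
#' @param data Data frame with a value column and a grouping column.
#' @param value,group Column names (strings) of the measurement and the
#'   group label.
#' @param design `"independent"` (default) or `"paired"`; paired data must
#'   have exactly two groups with equal length and aligned order.
#' @return An object of class `"group_comparison"` with elements `omnibus`,
#'   `pairwise`, `design`, `data`. Use [tidy()] for the pairwise table and
#'   [glance()] for the omnibus row.
#' @export
#' @examples
#' d <- dplyr::tibble(rate = c(1, 2, 3, 4, 5, 6),
#'                    cross = rep(c("A", "B"), each = 3))
#' cmp <- compare_groups(d, "rate", "cross")
#' glance(cmp)
#' tidy(cmp)
compare_groups <- function(data, value, group,
                           design = c("independent", "paired")) {
  design <- match.arg(design)
  stopifnot(all(c(value, group) %in% names(data)))
  v <- data[[value]]
  g <- factor(data[[group]])
  sizes <- table(g)
  if (any(sizes == 0) || nlevels(g) < 2)
    abort("compare_groups: need >= 2 non-empty groups")
  if (design == "paired") {
    if (nlevels(g) != 2 || length(unique(sizes)) != 1)
      abort("compare_groups: paired design needs two groups of equal size")
    x <- v[g == levels(g)[1]]
    y <- v[g == levels(g)[2]]
    d <- y - x
    omnibus <- if (sd(d) == 0) {
      tibble(method = "Paired t-test", statistic = NA_real_,
             parameter = NA_real_, p.value = NA_real_)
    } else {
      tt <- t.test(y, x, paired = TRUE)
      tibble(method = "Paired t-test", statistic = unname(tt$statistic),
             parameter = unname(tt$parameter), p.value = tt$p.value)
    }
    pairwise <- tibble(
      group1 = levels(g)[1], group2 = levels(g)[2],
      statistic = omnibus$statistic, p.value = omnibus$p.value,
      method = "Paired t-test"
    )
  } else {
    kw <- kruskal.test(v, g)
    omnibus <- tibble(
      method = "Kruskal-Wallis", statistic = unname(kw$statistic),
      parameter = unname(kw$parameter), p.value = kw$p.value
    )
    combos <- utils::combn(levels(g), 2, simplify = FALSE)
    pairwise <- purrr::map(combos, function(pr) {
      wt <- suppressWarnings(
        wilcox.test(v[g == pr[1]], v[g == pr[2]], alternative = "two.sided")
      )
      tibble(group1 = pr[1], group2 = pr[2],
             statistic = unname(wt$statistic), p.value = wt$p.value,
             method = "Mann-Whitney-Wilcoxon")
    }) |> bind_rows()
  }
  structure(
    list(omnibus = omnibus, pairwise = pairwise, design = design,
         data = tibble(value = v, group = g)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$design, " design)\n", sep = "")
  cat("  omnibus:", x$omnibus$method, "p =",
      format.pval(x$omnibus$p.value, digits = 3), "\n")
  cat("  pairwise tests:", nrow(x$pairwise), "\n")
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname compare_groups
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  mutate(x$omnibus, n_groups = nlevels(x$data$group),
         n = nrow(x$data))
}

#' Assemble the cohort-level report
#'
#' Collects the per-cross summary tables produced by the upstream modules —
#' WGD rates and cumulative curves, aneuploidy counts and gain/loss spectra,
#' LOH summaries and size distributions, fitness changes and fertility — into
#' one structured, JSON-serialisable report. Missing tables leave explicit
#' `NULL` gaps rather than failing.
#'
#' @param wgd_rates,wgd_cumulative,aneuploidy,spectrum,loh,fitness,fertility
#'   Tibbles from the respective modules (any may be omitted).
#' @return A list of class `"ma_report"`.
#' @export
build_report <- function(wgd_rates = NULL, wgd_cumulative = NULL,
                         aneuploidy = NULL, spectrum = NULL, loh = NULL,
                         fitness = NULL, fertility = NULL) {
  parts <- list(
    wgd_rates = wgd_rates, wgd_cumulative = wgd_cumulative,
    aneuploidy = aneuploidy, spectrum = spectrum, loh = loh,
    fitness = fitness, fertility = fertility
  )
  if (all(purrr::map_lgl(parts, is.null)))
    abort("build_report: at least one upstream table is required")
  structure(parts, class = "ma_report")
}

#' @export
print.ma_report <- function(x, ...) {
  cat("MA cohort report\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %s\n", nm,
                if (is.null(x[[nm]])) "(absent)"
                else paste0(nrow(x[[nm]]), " rows")))
  }
  invisible(x)
}

#' Write / read a report as JSON
#'
#' The JSON serialisation is canonical (data frames as row-wise records,
#' fixed precision), so write -> read -> write round-trips byte-identically.
#'
#' @param report An [build_report()] result (or any list of tibbles).
#' @param path Output path.
#' @return `path` invisibly for `write_report_json()`; a named list of
#'   tibbles for `read_report_json()`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    purrr::map(unclass(report), function(tb) tb %||% list()),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null"
  )
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(x, function(el) {
    if (is.data.frame(el)) as_tibble(el) else el
  })
}
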