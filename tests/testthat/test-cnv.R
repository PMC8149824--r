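test_that("depth binning tiles chromosomes with a short final window", {
  d <- tibble::tibble(chrom = "chrA", pos = 1:25000, depth = 90)
  w <- bin_depth(d, chrom_lengths = c(chrA = 25000))
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(10000, 20000, 25000))
  expect_equal(w$mean_depth, c(90, 90, 90))

  z <- bin_depth(dplyr::mutate(d, depth = 0), chrom_lengths = c(chrA = 25000))
  expect_true(all(z$mean_depth == 0))

  # absent positions count as zero when lengths are known, and are flagged
  # partial otherwise
  sparse <- tibble::tibble(chrom = "chrA", pos = c(1, 2), depth = c(10, 30))
  expect_equal(bin_depth(sparse, chrom_lengths = c(chrA = 10000))$mean_depth,
               40 / 10000)
  part <- bin_depth(sparse)
  expect_equal(part$mean_depth, 20)
  expect_true(all(part$partial))

  expect_error(
    bin_depth(tibble::tibble(chrom = "c", pos = c(5, 1), depth = 1)),
    "sorted"
  )
})

test_that("binned means match a brute-force per-window oracle", {
  withr::local_seed(42)
  d <- tibble::tibble(
    chrom = rep(c("c1", "c2"), c(3000, 2000)),
    pos = c(sort(sample.int(35000, 3000)), sort(sample.int(22000, 2000))),
    depth = rpois(5000, 60)
  )
  got <- bin_depth(d, window = 5000)
  for (k in sample(nrow(got), 10)) {
    sub <- d[d$chrom == got$chrom[k] &
               (d$pos - 1) %/% 5000 == got$start[k] / 5000, ]
    expect_equal(got$mean_depth[k], sum(sub$depth) / nrow(sub),
                 tolerance = 1e-12)
  }
})

test_that("normalization and copy-number rounding follow the median rule", {
  w <- sim_depth_track(c(a = 2L, b = 2L), c(a = 1e5, b = 1e5),
                       dispersion = 0, seed = 1)
  expect_true(all(normalize_depth(w)$ratio == 1))
  expect_error(normalize_depth(dplyr::mutate(w, mean_depth = 0)), "coverage")

  ratios <- tibble::tibble(
    chrom = rep(c("tri", "eu4"), each = 4), start = 0, end = 1,
    ratio = rep(c(1.5, 1.0), each = 4)
  )
  cn <- chromosome_copy_number(ratios, baseline_ploidy = 2)
  expect_equal(cn$copy_number[cn$chrom == "tri"], 3L)
  cn4 <- chromosome_copy_number(ratios, baseline_ploidy = 4)
  expect_equal(cn4$copy_number[cn4$chrom == "eu4"], 4L)
  expect_true(all(cn4$copy_number[cn4$chrom == "tri"] == 6L))

  expect_error(
    chromosome_copy_number(ratios[1:2, ], baseline_ploidy = 2),
    "fewer than 3"
  )

  # ambiguous medians fall in the no-call band
  amb <- tibble::tibble(chrom = "x", start = 0, end = 1, ratio = rep(1.25, 5))
  expect_equal(chromosome_copy_number(amb, 2)$qc_flag, "warn")
})

test_that("copy-number calls are invariant under depth scaling", {
  trk <- sim_depth_track(c(a = 3L, b = 2L, c = 1L, d = 2L),
                         c(a = 2e5, b = 2e5, c = 2e5, d = 2e5),
                         dispersion = 0.08, seed = 5)
  cn1 <- chromosome_copy_number(normalize_depth(trk), 2)
  for (c_scale in c(0.1, 4.2)) {
    scaled <- dplyr::mutate(trk, mean_depth = mean_depth * c_scale)
    cn2 <- chromosome_copy_number(normalize_depth(scaled), 2)
    expect_identical(cn1$copy_number, cn2$copy_number)
  }
})

test_that("full pipeline equals the naive copy-number oracle on random genomes", {
  withr::local_seed(99)
  for (rep in 1:5) {
    cns <- sample(0:4, 4, replace = TRUE)
    names(cns) <- paste0("chr", 1:4)
    lens <- setNames(sample(c(30000, 50000, 80000), 4, replace = TRUE),
                     names(cns))
    base <- purrr::imap(lens, function(len, chr) {
      tibble::tibble(chrom = chr, pos = 1:len,
                     depth = rpois(len, 45 * cns[[chr]] / 2 + 0.001))
    }) |> dplyr::bind_rows()
    got <- bin_depth(base, window = 10000, chrom_lengths = lens) |>
      normalize_depth() |>
      chromosome_copy_number(baseline_ploidy = 2)
    ora <- oracle_copy_number(base, window = 10000, baseline_ploidy = 2)
    expect_equal(got$copy_number[match(ora$chrom, got$chrom)],
                 ora$copy_number)
  }
})

test_that("masked windows are excluded from the chromosome median", {
  w <- tibble::tibble(
    chrom = "chrXII", start = seq(0, 9e4, 1e4), end = seq(1e4, 1e5, 1e4),
    ratio = c(rep(1, 5), rep(8, 5)) # rDNA-like pileup in the last 50 kb
  )
  no_mask <- chromosome_copy_number(w, 2)
  masked <- chromosome_copy_number(
    w, 2, mask = tibble::tibble(chrom = "chrXII", start = 5e4, end = 1e5)
  )
  expect_equal(masked$copy_number, 2L)
  expect_equal(masked$n_windows, 5L)
  expect_gt(no_mask$normalized_median, masked$normalized_median)
})

test_that("consensus copy number uses modal value with baseline tie-breaks", {
  expect_equal(consensus_copy_number(c(2L, 2L, 2L, 3L)), 2L)
  expect_equal(consensus_copy_number(c(2L, 3L), baseline_ploidy = 2), 2L)
  expect_equal(consensus_copy_number(c(1L, 3L), baseline_ploidy = 2), 1L)
  expect_error(consensus_copy_number(integer(0)), "empty")
  withr::local_seed(7)
  for (i in 1:200) {
    calls <- sample(0:5, sample(1:12, 1), replace = TRUE)
    base <- sample(1:4, 1)
    expect_identical(consensus_copy_number(calls, base),
                     oracle_consensus(calls, base))
  }
})

test_that("aneuploidy deltas, counts and spectra are conserved", {
  ini <- tibble::tibble(line_id = "l1", chrom = c("c1", "c2", "c3"),
                        copy_number = c(2L, 2L, 4L))
  fin <- tibble::tibble(line_id = "l1", chrom = c("c1", "c2", "c3"),
                        copy_number = c(3L, 2L, 3L))
  d <- aneuploidy_delta(ini, fin)
  expect_equal(d$delta, c(1L, 0L, -1L))
  expect_equal(aneuploidy_delta(ini, ini)$delta, c(0L, 0L, 0L))
  expect_error(aneuploidy_delta(ini, fin[1:2, ]), "differ")

  expect_equal(aneuploidy_count(d, baseline_end = 2L)$n_aneuploid, 2L)
  # a 4n line with one chromosome at 3 copies counts one aneuploidy
  expect_equal(aneuploidy_count(d, baseline_end = 3L)$n_aneuploid, 1L)

  many <- tidyr::expand_grid(line_id = sprintf("l%02d", 1:10),
                             chrom = c("chrI", "chrII")) |>
    dplyr::mutate(cn_initial = 2L, cn_end = 2L,
                  delta = dplyr::if_else(line_id == "l01" & chrom == "chrI",
                                         -1L, 0L))
  sp <- gain_loss_spectrum(many)
  expect_equal(sp$loss_freq[sp$chrom == "chrI"], 0.1)
  expect_equal(sp$loss_freq[sp$chrom == "chrII"], 0)
  expect_equal(sum(sp$n_gain) + sum(sp$n_loss), sum(many$delta != 0))
})
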