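fixture <- function(name) system.file("extdata", name, package = "wgdma")

test_that("marker filtering applies every selection rule", {
  rec <- read_freebayes_vcf(fixture("example_markers.vcf"))
  expect_equal(nrow(rec), 12)

  expect_message(kept <- filter_snps(rec), "skipped 1")
  # chrI:500 passes (QUAL/AO = 12.5); chrII:300 passes; everything else
  # fails exactly one rule each
  expect_setequal(paste0(kept$chrom, ":", kept$pos),
                  c("chrI:500", "chrI:1950", "chrII:300"))
  expect_equal(attr(kept, "n_skipped"), 1)

  reps <- read_bed(fixture("example_repeats.bed"))
  masked <- suppressMessages(filter_snps(rec, repeats = reps))
  expect_setequal(paste0(masked$chrom, ":", masked$pos),
                  c("chrI:500", "chrII:300"))
})

test_that("random record sets match the predicate-by-predicate oracle", {
  withr::local_seed(13)
  n <- 500
  rec <- tibble::tibble(
    chrom = "chrI", pos = seq_len(n),
    qual = runif(n, 0, 40), ao = sample(1:8, n, TRUE),
    saf = sample(0:5, n, TRUE), sar = sample(0:5, n, TRUE),
    rpr = sample(0:4, n, TRUE), rpl = sample(0:4, n, TRUE),
    mqm = runif(n, 50, 70), mqmr = runif(n, 50, 70),
    is_indel = runif(n) < 0.1, is_multiallelic = runif(n) < 0.1
  )
  kept <- filter_snps(rec)
  expect_identical(kept$pos, rec$pos[oracle_filter_keep(rec)])
})

test_that("allele frequencies honour the strict depth threshold", {
  m <- tibble::tibble(
    chrom = "chrI", pos = c(100, 200, 300),
    depth_a = c(10, 11, 20), total_depth = c(20, 22, 30)
  )
  af <- compute_af(m)
  expect_equal(af$pos, c(200, 300)) # depth 20 is excluded, not > 20
  expect_equal(af$af, c(0.5, 2 / 3))
  expect_equal(af$baseline_af, rep(mean(c(0.5, 2 / 3)), 2))
  expect_warning(compute_af(m[1, ]), "no markers")
})

test_that("the three-SNP rule is traced by hand on a minimal track", {
  trk <- tibble::tibble(
    chrom = "chrI", pos = c(500, 1000, 1100, 1200, 2000),
    af = c(0.5, 1, 1, 1, 0.5), baseline_af = 0.5
  )
  seg <- detect_loh(trk, max_gap = 300)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1000)
  expect_equal(seg$end, 1200)
  expect_equal(seg$size, 200)
  expect_equal(seg$n_markers, 3L)
  expect_equal(seg$retained_parent, "a")
  expect_equal(seg$kind, "interstitial")

  # two deviating SNPs are not enough
  two <- trk[c(1, 2, 3, 5), ]
  expect_equal(nrow(detect_loh(two, max_gap = 300)), 0)

  # an inter-SNP gap above the window breaks the run
  gapped <- tibble::tibble(
    chrom = "chrI", pos = c(1000, 1100, 1600),
    af = 1, baseline_af = 0.5
  )
  expect_equal(nrow(detect_loh(gapped, max_gap = 300)), 0)
  expect_equal(nrow(detect_loh(gapped, max_gap = 1000)), 1)
})

test_that("segmentation equals the brute-force oracle on random tracks", {
  withr::local_seed(202)
  for (i in 1:200) {
    trk <- random_track(sample(5:50, 1))
    base <- mean(trk$af)
    got <- detect_loh(dplyr::mutate(trk, baseline_af = base),
                      max_gap = 300, min_marker_density = 0)
    ora <- oracle_segment_loh(trk$pos, trk$af, base, max_gap = 300)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(ora) > 0) {
      expect_equal(got$start, ora$start)
      expect_equal(got$end, ora$end)
      expect_equal(got$n_markers, ora$n_markers)
      expect_equal(got$segment_af, ora$segment_af)
    }
  }
})

test_that("segments obey structural invariants", {
  withr::local_seed(303)
  n_checked <- 0L
  for (i in 1:50) {
    trk <- random_track(50, depth = 20)
    # plant a deviating run in half the tracks so the invariants are
    # exercised on real segments, not vacuously
    if (i %% 2 == 0) {
      j <- sample(1:45, 1)
      trk$af[j:(j + 4)] <- 1
      trk$depth_a[j:(j + 4)] <- trk$total_depth[j:(j + 4)]
    }
    segs <- detect_loh(trk, max_gap = 300, min_marker_density = 0)
    if (nrow(segs) == 0) next
    n_checked <- n_checked + nrow(segs)
    expect_true(all(segs$n_markers >= 3))
    expect_true(all(segs$size >= 0))
    expect_true(all(segs$start <= segs$end))
    # ordered and non-overlapping
    expect_true(all(diff(segs$start) > 0))
    expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
    # no member gap exceeds max_gap: segment span is bounded
    expect_true(all(segs$size <= (segs$n_markers - 1) * 300))
  }
  expect_gt(n_checked, 0)
})

test_that("swapping parent labels mirrors AF and flips the retained parent", {
  withr::local_seed(404)
  for (i in 1:20) {
    trk <- random_track(40)
    segs <- detect_loh(trk, max_gap = 300, min_marker_density = 0)
    flipped <- dplyr::mutate(trk, af = 1 - af,
                             depth_a = total_depth - depth_a)
    fsegs <- detect_loh(flipped, max_gap = 300, min_marker_density = 0)
    expect_equal(fsegs$start, segs$start)
    expect_equal(fsegs$end, segs$end)
    expect_equal(fsegs$segment_af, 1 - segs$segment_af)
    if (nrow(segs) > 0) {
      expect_true(all(fsegs$retained_parent != segs$retained_parent))
    }
  }
})

test_that("terminal segments touch a chromosome end marker", {
  trk <- tibble::tibble(
    chrom = "chrI", pos = c(100, 200, 300, 5000, 9000, 9100, 9200),
    af = c(1, 1, 1, 0.5, 0, 0, 0), baseline_af = 0.5
  )
  segs <- detect_loh(trk, max_gap = 300, min_marker_density = 0)
  expect_equal(segs$kind, c("terminal", "terminal"))
  expect_equal(segs$retained_parent, c("a", "b"))
})

test_that("summaries separate kinds and apply the 1-kb comparison rule", {
  segs <- tibble::tibble(
    line_id = c("l1", "l1", "l2"),
    chrom = "chrI", start = c(1, 100, 200), end = c(801, 2100, 1400),
    size = c(800, 2000, 1200), n_markers = c(3L, 8L, 5L),
    segment_af = 1, retained_parent = "a",
    kind = c("interstitial", "terminal", "interstitial")
  )
  s <- loh_summary(segs)
  expect_equal(sum(s$n_segments), 3)
  # the 800 bp segment is in the full count but not the comparison count
  inter_l1 <- dplyr::filter(s, line_id == "l1", kind == "interstitial")
  expect_equal(inter_l1$n_segments, 1L)
  expect_equal(inter_l1$n_comparison, 0L)
  empty <- loh_summary(segs[0, ])
  expect_equal(empty$n_segments, 0)
})

test_that("very sparse marker tracks are refused", {
  sparse <- tibble::tibble(
    chrom = "chrI", pos = seq(1, 1e6, length.out = 20),
    af = 0.5, baseline_af = 0.5
  )
  expect_error(detect_loh(sparse), "density")
})

test_that("triploid tracts report the lost parental allele class", {
  # two SpC-like copies (parent a): baseline 2/3, loss of one a copy -> 1/3
  mk <- function(base, seg_af) tibble::tibble(
    chrom = "chrI",
    pos = c(100, 1000, 1100, 1200, 2000),
    af = c(base, seg_af, seg_af, seg_af, base),
    baseline_af = base
  )
  s1 <- triploid_allele_loss(mk(2 / 3, 1 / 3), max_gap = 300,
                             min_marker_density = 0)
  expect_equal(s1$lost_parent, "a")
  expect_equal(s1$copies_lost, 1L)

  # single-copy parent a fully lost from baseline 1/3
  s2 <- triploid_allele_loss(mk(1 / 3, 0), max_gap = 300,
                             min_marker_density = 0)
  expect_equal(s2$lost_parent, "a")
  expect_equal(s2$copies_lost, 1L)

  expect_warning(
    triploid_allele_loss(mk(0.5, 1), max_gap = 300, min_marker_density = 0),
    "1/3 or 2/3"
  )
})

test_that("planted tracts round-trip through the simulator and segmenter", {
  sim <- sim_marker_track(
    2e5, marker_density = 6, baseline_af = 0.5,
    loh_intervals = data.frame(start = c(5e4, 1.2e5), end = c(5.3e4, 1.4e5),
                               target_af = c(1, 0)),
    mean_depth = 60, seed = 77
  )
  segs <- detect_loh(compute_af(sim$track), max_gap = 1000)
  hits <- purrr::map_lgl(seq_len(nrow(sim$truth)), function(k) {
    any(segs$start >= sim$truth$start[k] - 1000 &
          segs$end <= sim$truth$end[k] + 1000 &
          segs$start <= sim$truth$end[k])
  })
  expect_true(all(hits))
  short <- segs$size < 5000
  long <- segs$size >= 5000
  expect_true(any(short) && any(long))
})

test_that("LOH segments export to BED with 0-based half-open coordinates", {
  segs <- tibble::tibble(chrom = "chrI", start = 1000, end = 1200,
                         size = 200, n_markers = 3L, segment_af = 1,
                         retained_parent = "a", kind = "interstitial")
  path <- withr::local_tempfile(fileext = ".bed")
  write_loh_bed(segs, path)
  bed <- read_bed(path)
  expect_equal(bed$start, 999)
  expect_equal(bed$end, 1200)
})
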