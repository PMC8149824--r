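#' Simulation configuration for a synthetic MA cohort
#'
#' Bundles and validates the parameters of the synthetic mutation-accumulation
#' cohort generator. Defaults describe the experimental design being emulated:
#' 96 lines per cross propagated through 35 single-colony passages
#' (~22 generations each, ~770 generations total), flow-cytometry samples of
#' 5000 cells, and ~90x genome-wide sequencing coverage. The noise models
#' (fluorescence CV, depth overdispersion, OD noise) are stand-ins chosen to
#' resemble typical instrument output; the underlying experiment reports no
#' noise model, so all of them are configurable.
#'
#' @param seed Integer seed controlling all randomness derived from this
#'   config. Identical configs give byte-identical cohorts.
#' @param n_lines Lines per cross (the design uses 48--96).
#' @param n_passages Number of single-colony passages (default 35).
#' @param generations_per_passage Cell generations per passage (default 22,
#'   i.e. ~770 generations over the experiment).
#' @param wgd_hazard Per-passage probability that a line undergoes
#'   whole-genome duplication. The default 0.003 gives a ~10% cumulative WGD
#'   fraction over 35 passages, the upper end of what spontaneous WGD reaches
#'   in the most WGD-prone crosses.
#' @param reversion_hazard Per-passage probability that a tetraploid line
#'   reverts toward its pre-WGD ploidy.
#' @param extinction_hazard Per-passage probability that a line goes extinct
#'   (stops producing samples; it stays in the founding-line denominator).
#' @param triploid_fraction Fraction of lines starting triploid instead of
#'   diploid (emulating low-divergence hybrid crosses in which roughly half
#'   the lines are triploid at the initial timepoint).
#' @param aneuploidy_rate Expected whole-chromosome gain/loss events per line
#'   over the experiment.
#' @param loh_rate Expected LOH tracts per line over the experiment.
#' @param loh_short_fraction Mixture weight of the short (gene-conversion-like,
#'   1e2--1e3 bp) LOH length component; the remainder is the long
#'   (terminal/BIR-like, 1e4--1e5 bp) component.
#' @param coverage_mean Genome-wide mean sequencing depth (default 90).
#' @param coverage_dispersion Coefficient of variation of 10-kb window mean
#'   depths (default 0.1).
#' @param cv_fluorescence Coefficient of variation of fluorescence peaks
#'   (default 0.05).
#' @param g1_fraction Fraction of cells in G1 (default 0.63; with the default
#'   2% debris fraction this leaves 35% in G2).
#' @param debris_fraction Fraction of sub-G1 debris events (default 0.02).
#' @param marker_density Heterozygous markers per kb (default 5, typical of
#'   diverged hybrid crosses).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_lines = 48)
#' cfg$wgd_hazard
sim_config <- function(seed = 1L,
                       n_lines = 96L,
                       n_passages = 35L,
                       generations_per_passage = 22,
                       wgd_hazard = 0.003,
                       reversion_hazard = 0.005,
                       extinction_hazard = 0.001,
                       triploid_fraction = 0,
                       aneuploidy_rate = 0.3,
                       loh_rate = 2,
                       loh_short_fraction = 0.5,
                       coverage_mean = 90,
                       coverage_dispersion = 0.1,
                       cv_fluorescence = 0.05,
                       g1_fraction = 0.63,
                       debris_fraction = 0.02,
                       marker_density = 5,
                       chrom_lengths = yeast_chrom_lengths()) {
  for (nm in c("wgd_hazard", "reversion_hazard", "extinction_hazard",
               "triploid_fraction", "loh_short_fraction",
               "g1_fraction", "debris_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      abort(paste0("`", nm, "` must be a probability in [0, 1]"))
  }
  if (n_passages < 1) abort("`n_passages` must be >= 1")
  if (coverage_mean <= 0) abort("`coverage_mean` must be > 0")
  if (cv_fluorescence < 0) abort("`cv_fluorescence` must be >= 0")
  if (g1_fraction + debris_fraction >= 1)
    abort("`g1_fraction` + `debris_fraction` must leave a nonzero G2 fraction")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    abort("`chrom_lengths` must be a named vector of positive lengths")
  structure(
    list(
      seed = as.integer(seed), n_lines = as.integer(n_lines),
      n_passages = as.integer(n_passages),
      generations_per_passage = generations_per_passage,
      wgd_hazard = wgd_hazard, reversion_hazard = reversion_hazard,
      extinction_hazard = extinction_hazard,
      triploid_fraction = triploid_fraction,
      aneuploidy_rate = aneuploidy_rate, loh_rate = loh_rate,
      loh_short_fraction = loh_short_fraction,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      cv_fluorescence = cv_fluorescence, g1_fraction = g1_fraction,
      debris_fraction = debris_fraction, marker_density = marker_density,
      chrom_lengths = chrom_lengths
    ),
    class = "sim_config"
  )
}

# Fluorescence units per haploid genome equivalent on the simulated
# instrument scale. Arbitrary (flow units are instrument specific); fixed so
# that simulated G1 peaks sit at 100 * ploidy.
FLUOR_UNIT <- 100

#' Simulate a flow-cytometry fluorescence sample
#'
#' Draws per-cell DNA-content fluorescence for one line at one timepoint from
#' a G1/G2 mixture: the G1 component is centred at `true_ploidy` genome
#' equivalents (100 a.u. per haploid genome), the G2 component at twice that,
#' each with relative spread `cv`; a small sub-G1 uniform debris component is
#' included. Component counts are deterministic (rounded fractions of
#' `n_cells`), so the mixture weights are exact.
#'
#' @param true_ploidy True ploidy of the culture (>= 1, need not be integer).
#' @param n_cells Number of cells measured (default 5000, >= 100).
#' @param g1_fraction Fraction of cells in G1 (in (0, 1)).
#' @param cv Coefficient of variation of each fluorescence peak (>= 0).
#' @param debris_fraction Fraction of sub-G1 debris events.
#' @param seed Optional integer seed (scoped; does not touch the global RNG
#'   stream when supplied).
#' @return A tibble with columns `cell`, `fluorescence` and the true `phase`
#'   (`"G1"`, `"G2"` or `"debris"`).
#' @export
#' @examples
#' smp <- sim_fluorescence(2, n_cells = 1000, seed = 1)
#' density_peaks(smp$fluorescence)
sim_fluorescence <- function(true_ploidy, n_cells = 5000L, g1_fraction = 0.63,
                             cv = 0.05, debris_fraction = 0.02, seed = NULL) {
  if (!is.numeric(true_ploidy) || true_ploidy <= 0)
    abort("`true_ploidy` must be positive")
  if (cv < 0) abort("`cv` must be non-negative")
  if (n_cells < 100) abort("`n_cells` must be >= 100")
  if (g1_fraction <= 0 || g1_fraction >= 1)
    abort("`g1_fraction` must be in (0, 1)")
  with_seed_if(seed, {
    n_debris <- round(n_cells * debris_fraction)
    n_g1 <- round((n_cells - n_debris) * g1_fraction)
    n_g2 <- n_cells - n_debris - n_g1
    mu1 <- FLUOR_UNIT * true_ploidy
    vals <- c(
      runif(n_debris, 0.1 * mu1, 0.9 * mu1),
      rnorm(n_g1, mu1, cv * mu1),
      rnorm(n_g2, 2 * mu1, cv * 2 * mu1)
    )
    vals <- pmax(vals, 0)
    tibble(
      cell = seq_len(n_cells),
      fluorescence = vals,
      phase = rep(c("debris", "G1", "G2"), c(n_debris, n_g1, n_g2))
    )
  })
}

#' Simulate an MA cohort with planted WGD, reversion and extinction events
#'
#' Propagates `n_lines` lines through `n_passages` passages. Each line starts
#' diploid (or triploid with probability `triploid_fraction`). At each
#' passage a surviving, not-yet-duplicated line undergoes WGD with probability
#' `wgd_hazard` (ploidy doubles); a duplicated line reverts with probability
#' `reversion_hazard` (ploidy returns to baseline); any line goes extinct
#' with probability `extinction_hazard` and stops producing samples.
#'
#' @param config A [sim_config()].
#' @param cross_id Label for the simulated cross.
#' @return A list of class `"sim_cohort"` with elements
#'   * `truth`: one row per line (`line_id`, `cross_id`, `initial_ploidy`,
#'     `wgd_passage`, `reversion_passage`, `extinct_passage`, all `NA` when
#'     the event did not occur);
#'   * `trajectory`: one row per line x passage while alive (`line_id`,
#'     `passage`, `generations`, `true_ploidy`).
#' @export
#' @examples
#' coh <- sim_cohort(sim_config(seed = 7, n_lines = 24, wgd_hazard = 0.01))
#' sum(!is.na(coh$truth$wgd_passage))
sim_cohort <- function(config, cross_id = "cross1") {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    n <- config$n_lines
    line_id <- sprintf("%s_%02d", cross_id, seq_len(n))
    initial <- ifelse(runif(n) < config$triploid_fraction, 3L, 2L)
    ploidy <- initial
    wgd_p <- rep(NA_integer_, n)
    rev_p <- rep(NA_integer_, n)
    ext_p <- rep(NA_integer_, n)
    traj <- vector("list", config$n_passages + 1L)
    alive <- rep(TRUE, n)
    record <- function(passage) {
      tibble(
        line_id = line_id[alive], passage = passage,
        generations = passage * config$generations_per_passage,
        true_ploidy = ploidy[alive]
      )
    }
    traj[[1L]] <- record(0L)
    for (p in seq_len(config$n_passages)) {
      u_ext <- runif(n)
      u_wgd <- runif(n)
      u_rev <- runif(n)
      dies <- alive & u_ext < config$extinction_hazard
      ext_p[dies] <- p
      alive[dies] <- FALSE
      dup <- alive & is.na(wgd_p) & u_wgd < config$wgd_hazard
      wgd_p[dup] <- p
      ploidy[dup] <- 2L * ploidy[dup]
      revs <- alive & !is.na(wgd_p) & wgd_p < p & is.na(rev_p) &
        u_rev < config$reversion_hazard
      rev_p[revs] <- p
      ploidy[revs] <- initial[revs]
      traj[[p + 1L]] <- record(p)
    }
    structure(
      list(
        truth = tibble(
          line_id = line_id, cross_id = cross_id, initial_ploidy = initial,
          wgd_passage = wgd_p, reversion_passage = rev_p,
          extinct_passage = ext_p
        ),
        trajectory = bind_rows(traj),
        config = config
      ),
      class = "sim_cohort"
    )
  })
}

#' Generate fluorescence samples for a simulated cohort
#'
#' Materialises per-cell fluorescence samples at a grid of observation
#' passages for every line alive at each passage, ready for [call_ploidy()].
#'
#' @param cohort A [sim_cohort()] result.
#' @param passages Integer vector of observation passages (default: every
#'   passage present in the trajectory).
#' @param n_cells Cells per sample.
#' @return A tibble in long format: `line_id`, `cross_id`, `generations`,
#'   `fluorescence` (one row per cell).
#' @export
sim_cohort_fluorescence <- function(cohort, passages = NULL, n_cells = 5000L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  obs <- cohort$trajectory
  if (!is.null(passages)) obs <- filter(obs, .data$passage %in% passages)
  with_seed_if(cfg$seed + 1L, {
    out <- purrr::pmap(
      list(obs$line_id, obs$generations, obs$true_ploidy),
      function(id, gen, pl) {
        smp <- sim_fluorescence(
          pl, n_cells = n_cells, g1_fraction = cfg$g1_fraction,
          cv = cfg$cv_fluorescence, debris_fraction = cfg$debris_fraction
        )
        tibble(line_id = id, generations = gen, fluorescence = smp$fluorescence)
      }
    )
    mutate(bind_rows(out), cross_id = cohort$truth$cross_id[1], .after = "line_id")
  })
}

#' Simulate a windowed read-depth track
#'
#' Draws 10-kb window mean depths for a genome with known per-chromosome copy
#' numbers. Window means are Gamma-distributed with expectation
#' `coverage_mean * copy_number / baseline_ploidy` and coefficient of
#' variation `dispersion` (an overdispersed-count stand-in; `dispersion = 0`
#' gives the expectation exactly).
#'
#' @param copy_numbers Named integer vector (or tibble with `chrom`,
#'   `copy_number`) of true chromosome copy numbers.
#' @param chrom_lengths Named vector of chromosome lengths in bp; names must
#'   cover `copy_numbers`.
#' @param baseline_ploidy Euploid baseline (>= 1).
#' @param coverage_mean Genome-wide mean depth at the baseline.
#' @param dispersion CV of window mean depths.
#' @param window Window width in bp (default 10 kb).
#' @param seed Optional scoped seed.
#' @return A tibble with `chrom`, `start` (0-based), `end`, `mean_depth`.
#' @export
#' @examples
#' trk <- sim_depth_track(c(chrA = 3, chrB = 2), c(chrA = 5e4, chrB = 5e4),
#'                        seed = 1)
#' head(trk)
sim_depth_track <- function(copy_numbers, chrom_lengths, baseline_ploidy = 2L,
                            coverage_mean = 90, dispersion = 0.1,
                            window = 10000L, seed = NULL) {
  if (is.data.frame(copy_numbers))
    copy_numbers <- setNames(copy_numbers$copy_number, copy_numbers$chrom)
  if (any(copy_numbers < 0)) abort("`copy_numbers` must be >= 0")
  if (baseline_ploidy < 1) abort("`baseline_ploidy` must be >= 1")
  if (!all(names(copy_numbers) %in% names(chrom_lengths)))
    abort("every chromosome in `copy_numbers` needs a length")
  with_seed_if(seed, {
    out <- purrr::map(names(copy_numbers), function(chr) {
      len <- chrom_lengths[[chr]]
      starts <- seq(0L, len - 1L, by = window)
      ends <- pmin(starts + window, len)
      mu <- coverage_mean * copy_numbers[[chr]] / baseline_ploidy
      depth <- if (dispersion <= 0 || mu == 0) {
        rep(mu, length(starts))
      } else {
        shape <- 1 / dispersion^2
        rgamma(length(starts), shape = shape, scale = mu / shape)
      }
      tibble(chrom = chr, start = starts, end = ends, mean_depth = depth)
    })
    bind_rows(out)
  })
}

#' Simulate a heterozygous marker track with planted LOH tracts
#'
#' Places markers uniformly along a chromosome and draws per-marker parent-A
#' read counts binomially around `baseline_af` outside planted intervals and
#' around each interval's `target_af` inside it. Marker total depth follows a
#' Poisson law with mean `mean_depth` (`mean_depth = Inf` gives exact allele
#' frequencies, no sampling noise).
#'
#' @param chrom_length Chromosome length in bp.
#' @param marker_density Markers per kb.
#' @param baseline_af Parent-A allele frequency outside LOH tracts (0.5 for
#'   diploids, 1/3 or 2/3 for triploids).
#' @param loh_intervals `NULL`, or a data frame with `start`, `end` (bp,
#'   inclusive) and `target_af`; intervals must lie within the chromosome and
#'   not overlap.
#' @param mean_depth Mean total read depth per marker (default 90).
#' @param min_depth Lower truncation for marker depth (default 1).
#' @param chrom Chromosome name.
#' @param seed Optional scoped seed.
#' @return A list with `track` (tibble: `chrom`, `pos`, `depth_a`,
#'   `total_depth`, `af`) and `truth` (the planted intervals with marker
#'   counts).
#' @export
#' @examples
#' sim <- sim_marker_track(1e5, marker_density = 2, baseline_af = 0.5,
#'   loh_intervals = data.frame(start = 4e4, end = 5e4, target_af = 1),
#'   seed = 3)
#' nrow(sim$track)
sim_marker_track <- function(chrom_length, marker_density = 5,
                             baseline_af = 0.5, loh_intervals = NULL,
                             mean_depth = 90, min_depth = 1L,
                             chrom = "chrI", seed = NULL) {
  if (baseline_af <= 0 || baseline_af >= 1)
    abort("`baseline_af` must be in (0, 1)")
  iv <- loh_intervals
  if (!is.null(iv) && nrow(iv) > 0) {
    iv <- arrange(as_tibble(iv), .data$start)
    if (any(iv$start < 1) || any(iv$end > chrom_length) ||
        any(iv$end < iv$start))
      abort("`loh_intervals` must lie within [1, chrom_length]")
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
      abort("`loh_intervals` must not overlap")
  }
  with_seed_if(seed, {
    n <- max(1L, round(chrom_length * marker_density / 1000))
    pos <- sort(sample.int(chrom_length, n))
    af_target <- rep(baseline_af, n)
    if (!is.null(iv) && nrow(iv) > 0) {
      for (k in seq_len(nrow(iv))) {
        inside <- pos >= iv$start[k] & pos <= iv$end[k]
        af_target[inside] <- iv$target_af[k]
      }
      iv$n_markers <- purrr::map2_int(
        iv$start, iv$end, ~ sum(pos >= .x & pos <= .y)
      )
    }
    if (is.infinite(mean_depth)) {
      depth <- rep(1e6L, n)
      depth_a <- as.integer(round(depth * af_target))
    } else {
      depth <- pmax(rpois(n, mean_depth), min_depth)
      depth_a <- rbinom(n, depth, af_target)
    }
    list(
      track = tibble(
        chrom = chrom, pos = pos, depth_a = depth_a,
        total_depth = as.integer(depth), af = depth_a / depth
      ),
      truth = iv %||% tibble(start = integer(), end = integer(),
                             target_af = double(), n_markers = integer())
    )
  })
}

#' Simulate an OD600 growth curve
#'
#' Samples a logistic growth trajectory
#' \eqn{OD(t) = K od_0 e^{rt} / (K + od_0 (e^{rt} - 1))} on a fixed reading
#' interval and adds Gaussian measurement noise. An infinite carrying
#' capacity gives exact exponential growth.
#'
#' @param rate Intrinsic growth rate per hour (>= 0).
#' @param od0 Initial OD600 (default 0.1, the typical inoculation density).
#' @param carrying_capacity Saturation OD (default 1.5; `Inf` for pure
#'   exponential growth).
#' @param interval Reading interval in minutes (default 15).
#' @param duration Total duration in hours (default 24).
#' @param noise_sd SD of additive OD noise (default 0.003, typical
#'   plate-reader repeatability).
#' @param seed Optional scoped seed.
#' @return A tibble with `time_min` and `od`.
#' @export
#' @examples
#' gc <- sim_growth_curve(0.3, noise_sd = 0, seed = 1)
#' growth_rate(gc)
sim_growth_curve <- function(rate, od0 = 0.1, carrying_capacity = 1.5,
                             interval = 15, duration = 24, noise_sd = 0.003,
                             seed = NULL) {
  if (rate < 0) abort("`rate` must be >= 0")
  if (interval <= 0) abort("`interval` must be > 0")
  with_seed_if(seed, {
    t_min <- seq(0, duration * 60, by = interval)
    t_h <- t_min / 60
    od <- if (is.infinite(carrying_capacity)) {
      od0 * exp(rate * t_h)
    } else {
      K <- carrying_capacity
      K * od0 * exp(rate * t_h) / (K + od0 * (exp(rate * t_h) - 1))
    }
    if (noise_sd > 0) od <- od + rnorm(length(od), 0, noise_sd)
    tibble(time_min = t_min, od = od)
  })
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# a NULL seed uses (and advances) the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
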