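# Independent brute-force reference implementations used to cross-check the
# package's optimised code paths. Each oracle is written in a deliberately
# plain style (explicit loops, recomputation from scratch) so that agreement
# with the package functions is evidence, not tautology.

# LOH segmentation oracle: enumerate maximal runs of candidate markers
# (consecutive in the track) and split each run recursively at the first
# marker that violates the gap rule or the running-mean allele-frequency
# rule, recomputing the mean from scratch at every step.
oracle_segment_loh <- function(pos, af, baseline, deviation = 0.15,
                               af_tolerance = 0.1, max_gap = 300,
                               min_markers = 3L) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  n <- length(pos)
  cand <- abs(af - baseline) > deviation
  # maximal consecutive candidate runs
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- i:j
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  split_run <- function(idx) {
    if (length(idx) == 0) return(list())
    members <- idx[1]
    k <- 2L
    while (k <= length(idx)) {
      cur <- idx[k]
      prev <- members[length(members)]
      ok_gap <- (pos[cur] - pos[prev]) <= max_gap
      ok_af <- abs(af[cur] - mean(af[members])) <= af_tolerance
      if (ok_gap && ok_af) {
        members <- c(members, cur)
        k <- k + 1L
      } else {
        return(c(list(members), split_run(idx[k:length(idx)])))
      }
    }
    list(members)
  }
  pieces <- unlist(lapply(runs, split_run), recursive = FALSE)
  pieces <- Filter(function(m) length(m) >= min_markers, pieces)
  if (length(pieces) == 0) {
    return(data.frame(start = double(), end = double(),
                      n_markers = integer(), segment_af = double()))
  }
  do.call(rbind, lapply(pieces, function(m) {
    data.frame(start = pos[m[1]], end = pos[m[length(m)]],
               n_markers = length(m), segment_af = mean(af[m]))
  }))
}

# naive bin -> normalize -> median -> round chromosome copy-number pipeline
oracle_copy_number <- function(depth_df, window, baseline_ploidy) {
  chroms <- unique(depth_df$chrom)
  win_means <- list()
  for (chr in chroms) {
    sub <- depth_df[depth_df$chrom == chr, ]
    wid <- floor((sub$pos - 1) / window)
    for (w in sort(unique(wid))) {
      vals <- sub$depth[wid == w]
      win_means[[length(win_means) + 1L]] <-
        data.frame(chrom = chr, win = w, m = sum(vals) / length(vals))
    }
  }
  wm <- do.call(rbind, win_means)
  gc <- sum(wm$m) / nrow(wm)
  out <- data.frame(chrom = chroms, copy_number = NA_integer_)
  for (k in seq_along(chroms)) {
    r <- sort(wm$m[wm$chrom == chroms[k]] / gc)
    nn <- length(r)
    med <- if (nn %% 2 == 1) r[(nn + 1) / 2] else (r[nn / 2] + r[nn / 2 + 1]) / 2
    out$copy_number[k] <- as.integer(round(med * baseline_ploidy))
  }
  out
}

# per-window least-squares slope via lm()
oracle_window_slopes <- function(time_h, y, window) {
  n <- length(y)
  sapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    unname(stats::coef(stats::lm(y[idx] ~ time_h[idx]))[2])
  })
}

# type-7 percentile by hand: linear interpolation between closest ranks
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# predicate-by-predicate marker filter
oracle_filter_keep <- function(rec) {
  ok <- rep(TRUE, nrow(rec))
  ok <- ok & rec$qual > 1
  ok <- ok & (rec$qual / rec$ao) > 10
  ok <- ok & rec$saf > 0
  ok <- ok & rec$sar > 0
  ok <- ok & rec$rpr > 1
  ok <- ok & rec$rpl > 1
  ok <- ok & (rec$mqm / rec$mqmr) > 0.9
  ok <- ok & (rec$mqm / rec$mqmr) < 1.05
  ok <- ok & !rec$is_indel
  ok <- ok & !rec$is_multiallelic
  ok
}

# counting-based consensus with the closest-to-baseline-then-smaller tie rule
oracle_consensus <- function(calls, baseline) {
  best <- NULL
  best_count <- -1L
  for (v in sort(unique(calls))) {
    cnt <- sum(calls == v)
    better <- cnt > best_count ||
      (cnt == best_count &&
         (abs(v - baseline) < abs(best - baseline) ||
            (abs(v - baseline) == abs(best - baseline) && v < best)))
    if (better) {
      best <- v
      best_count <- cnt
    }
  }
  as.integer(best)
}

# random marker track generator for segmentation fuzzing
random_track <- function(n_markers, chrom_length = 15000, depth = 30,
                         baseline = 0.5) {
  pos <- sort(sample.int(chrom_length, n_markers))
  da <- rbinom(n_markers, depth, baseline)
  tibble::tibble(
    chrom = "chrZ", pos = pos, depth_a = da,
    total_depth = rep(depth, n_markers), af = da / depth
  )
}
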