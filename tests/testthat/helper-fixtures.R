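# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# a timeline on the period-of-interest clock (-30, 10] built from CC
# episode intervals given as a list of c(start, stop)
poi_timeline <- function(episodes = list(), rate = 110,
                         segments = data.frame(start = -30, stop = 10,
                                               class = "ASYS"),
                         aed = NA_real_) {
  ep <- if (length(episodes)) {
    data.frame(start = vapply(episodes, `[`, 1, 1),
               stop = vapply(episodes, `[`, 1, 2))
  } else {
    data.frame(start = numeric(), stop = numeric())
  }
  cpr_timeline(cc_episodes = ep, aed_analysis_start = aed,
               rhythm_segments = segments, cc_rate = rate,
               coverage = c(-30, 10))
}

# brute-force sHOT oracle: per-sample CC-free mask at resolution `res`,
# counting only samples belonging to interruptions with full length > 1 s
shot_oracle <- function(timeline, t, D, res = 1 / 125) {
  lo <- timeline$coverage[1]
  hi <- timeline$coverage[2]
  grid <- seq(lo + res, hi, by = res)     # sample right-edges
  cc <- rep(FALSE, length(grid))
  ep <- timeline$cc_episodes
  for (i in seq_len(nrow(ep))) {
    cc <- cc | (grid > ep$start[i] & grid <= ep$stop[i])
  }
  free <- !cc
  # qualifying interruptions: maximal runs of free samples longer than 1 s
  r <- rle(free)
  qual <- rep(FALSE, length(grid))
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] * res > 1 + 1e-9) {
      qual[pos[j]:(pos[j + 1] - 1)] <- TRUE
    }
  }
  inwin <- grid > t - D & grid <= t
  sum(qual & inwin) * res
}

# concordance (Mann-Whitney U) AUC oracle with 1/2 for ties
auc_oracle <- function(scores, delta) {
  sh <- scores[delta == 1]
  nsh <- scores[delta == 0]
  tot <- 0
  for (a in sh) for (b in nsh) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sh) * length(nsh))
}

# exhaustive operating-point oracle over all observed candidates
op_oracle <- function(scores, delta) {
  cand <- sort(unique(c(0, scores, 1)))
  best <- -Inf
  best_th <- NA
  for (th in cand) {
    se <- mean(scores[delta == 1] >= th)
    sp <- mean(scores[delta == 0] < th)
    if (se + sp > best + 1e-12) {
      best <- se + sp
      best_th <- th
    }
  }
  list(threshold = best_th, criterion = best)
}

# naive direct 1-D convolution ("same" zero padding, stride 1) for a
# single channel/filter pair; oracle for the compiled conv kernel
conv_oracle <- function(x, w, padL) {
  K <- length(w)
  N <- length(x)
  xp <- c(rep(0, padL), x, rep(0, K - 1 - padL))
  vapply(seq_len(N), function(t) sum(xp[t:(t + K - 1)] * w), numeric(1))
}

# simple beat detector: count prominent R-peak-like maxima
detect_rate_bpm <- function(x, fs) {
  thr <- 0.5 * max(abs(x))
  above <- abs(x) > thr
  # rising edges separated by a 0.25 s refractory period
  idx <- which(above & !c(FALSE, above[-length(above)]))
  if (length(idx) < 2) return(NA_real_)
  keep <- idx[c(TRUE, diff(idx) > 0.25 * fs)]
  (length(keep) - 1) / ((max(keep) - min(keep)) / fs) * 60
}

# max peak-to-peak over sliding windows of `win` seconds
max_pp_in_windows <- function(x, fs, win = 4) {
  n <- length(x)
  w <- round(win * fs)
  starts <- seq(1, n - w + 1, by = round(fs / 4))
  max(vapply(starts, function(s) diff(range(x[s:(s + w - 1)])), numeric(1)))
}

tiny_dataset <- function(n_patients = 12, seed = 5, ...) {
  make_dataset(n_patients, seed = seed, ...)
}

# VF-enriched mix so that tiny training fixtures contain both shock
# categories in every split (6% VF is too rare at n ~ 15)
rich_mix <- c(VF = 0.3, NSR = 0.1, ONR = 0.2, ASYS = 0.4)
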