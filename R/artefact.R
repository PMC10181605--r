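## Chest-compression artefact --------------------------------------------
##
## The artefact added to the defi-lead ECG by compressions is modelled as
## a harmonic series at the compression rate (fundamental 100-120 min^-1,
## i.e. about 1.67-2.0 Hz) with 2-4 harmonics, per-compression log-normal
## amplitude jitter and slow phase noise. It is exactly zero outside CC
## episodes; a short raised-cosine taper at episode edges avoids clicks.

#' Generate a chest-compression ECG artefact
#'
#' @param timeline A [cpr_timeline()] whose `cc_episodes` mark when
#'   compressions are delivered and whose `cc_rate` (min^-1) sets the
#'   fundamental frequency. The rate must lie in 100--120 min^-1.
#' @param duration Trace duration (s); the trace starts at time 0 of the
#'   timeline clock.
#' @param fs Sampling rate (Hz).
#' @param amplitude_scale Peak artefact amplitude (uV). Strong, moderate
#'   and weak artefacts are spanned by roughly 200--3000 uV.
#' @param seed Optional integer seed.
#' @param n_harmonics Number of harmonics (2--4); drawn at random when `NULL`.
#' @return Numeric vector of `round(duration * fs)` samples (uV), zero
#'   outside CC episodes.
#' @examples
#' tl <- cpr_timeline(cc_episodes = data.frame(start = 1, stop = 9),
#'                    cc_rate = 110, coverage = c(0, 10))
#' a <- synth_cc_artefact(tl, 10, 125, 1000, seed = 1)
#' all(a[1:124] == 0)
#' @export
synth_cc_artefact <- function(timeline, duration, fs = 125,
                              amplitude_scale = 1000, seed = NULL,
                              n_harmonics = NULL) {
  stopifnot(inherits(timeline, "cpr_timeline"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(fs, "fs")
  if (amplitude_scale < 0) {
    abort("`amplitude_scale` must be non-negative",
          class = "cprshock_error_bad_input")
  }
  rate <- timeline$cc_rate
  if (nrow(timeline$cc_episodes) > 0 &&
      (!is.finite(rate) || rate < 100 || rate > 120)) {
    abort("timeline `cc_rate` must lie in 100-120 min^-1",
          class = "cprshock_error_bad_input")
  }
  local_seed_if(seed)
  n <- round(duration * fs)
  x <- numeric(n)
  if (amplitude_scale == 0 || nrow(timeline$cc_episodes) == 0) return(x)

  f0 <- rate / 60                       # fundamental (Hz)
  nh <- if (is.null(n_harmonics)) sample(2:4, 1) else as.integer(n_harmonics)
  stopifnot(nh >= 1)
  h_amp <- c(1, 0.45, 0.22, 0.12)[seq_len(nh)]
  t <- seq_len(n) / fs                  # sample timestamps (right edges)

  for (i in seq_len(nrow(timeline$cc_episodes))) {
    s0 <- timeline$cc_episodes$start[i]
    s1 <- timeline$cc_episodes$stop[i]
    idx <- which(t > s0 & t <= s1)
    if (!length(idx)) next
    tt <- t[idx] - s0
    # per-compression log-normal amplitude jitter
    n_comp <- max(1L, ceiling((s1 - s0) * f0))
    comp_amp <- exp(rnorm(n_comp, 0, 0.25))
    env <- comp_amp[pmin(n_comp, floor(tt * f0) + 1L)]
    # slow phase noise: compressions are quasi-periodic, not clock-locked
    ph_noise <- cumsum(rnorm(length(tt), 0, 0.015))
    phase <- 2 * pi * f0 * tt + runif(1, 0, 2 * pi) + ph_noise
    w <- numeric(length(tt))
    for (h in seq_len(nh)) {
      w <- w + h_amp[h] * sin(h * phase + runif(1, 0, 2 * pi))
    }
    # raised-cosine taper over 0.15 s at both episode edges
    taper <- pmin(1, pmin(tt, (s1 - s0) - tt + 1 / fs) / 0.15)
    taper <- 0.5 - 0.5 * cos(pi * pmax(0, pmin(1, taper)))
    x[idx] <- amplitude_scale * env * w * taper / sum(h_amp)
  }
  x
}
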