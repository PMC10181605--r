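## Synthetic rhythm traces ----------------------------------------------
##
## Each generator emits a defi-lead ECG trace (microvolt) that satisfies
## the machine-checkable annotation criterion of its class:
##   VF   coarse ventricular fibrillation, peak-to-peak > 200 uV, no
##        discernible QRS periodicity (drifting dominant frequency 3-8 Hz)
##   NSR  template P-QRS-T beats at 40-100 bpm
##   ONR  other organized non-shockable morphologies (atrial
##        fibrillation-like irregular RR, wide-QRS idioventricular,
##        bradycardia < 40 bpm, sinus with ectopic beats)
##   ASYS peak-to-peak <= 100 uV in every 4 s sub-interval
## All traces are band-limited to the defi-pad acquisition bandwidth.

#' Band-limit a trace to the defi-pad acquisition band
#'
#' Zero-phase 4th-order Butterworth bandpass (applied forward and
#' backward, so no group delay distorts wave positions).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param band Passband edges (Hz), default `c(1, 30)`.
#' @return Filtered numeric trace of the same length.
#' @export
bandpass_ecg <- function(x, fs = 125, band = c(1, 30)) {
  check_positive_scalar(fs, "fs")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Generate a synthetic rhythm trace
#'
#' Dispatches to one of four class-specific generators and band-limits
#' the result. The returned trace satisfies the annotation criterion of
#' its class (see Details) so that class membership is machine-checkable
#' on every synthetic signal.
#'
#' @details
#' Amplitude criteria are enforced after band-limiting: VF traces are
#' rescaled to a peak-to-peak amplitude drawn in 400--1200 uV (criterion:
#' > 200 uV); ASYS traces to a global peak-to-peak in 30--80 uV
#' (criterion: <= 100 uV over any 4 s). NSR beat rate is drawn uniformly
#' in 40--100 bpm. ONR picks one of four organized non-sinus variants at
#' random.
#'
#' @param class Rhythm class, one of `"VF"`, `"NSR"`, `"ONR"`, `"ASYS"`.
#' @param duration Trace duration (s), at least 5.
#' @param fs Sampling rate (Hz), default 125.
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @param band Passband (Hz) of the acquisition chain.
#' @return Numeric vector of `round(duration * fs)` amplitude samples (uV).
#' @examples
#' vf <- synth_rhythm("VF", 10, seed = 1)
#' diff(range(vf)) > 200
#' @export
synth_rhythm <- function(class, duration, fs = 125, seed = NULL, band = c(1, 30)) {
  if (length(class) != 1L) {
    abort("`class` must be a single rhythm class", class = "cprshock_error_bad_class")
  }
  check_rhythm_class(class)
  check_positive_scalar(duration, "duration")
  check_positive_scalar(fs, "fs")
  if (duration < 5) {
    abort("`duration` must be at least 5 s", class = "cprshock_error_bad_input")
  }
  local_seed_if(seed)
  n <- round(duration * fs)
  x <- switch(class,
    VF = synth_vf(n, fs),
    NSR = synth_nsr(n, fs),
    ONR = synth_onr(n, fs),
    ASYS = synth_asys(n, fs)
  )
  x <- bandpass_ecg(x, fs, band)
  # rescale after filtering so amplitude criteria hold on the output
  switch(class,
    VF = rescale_pp(x, runif(1, 400, 1200)),
    ASYS = rescale_pp(x, runif(1, 30, 80)),
    x
  )
}

rescale_pp <- function(x, target_pp) {
  pp <- diff(range(x))
  if (pp < 1e-9) return(x)
  x * (target_pp / pp)
}

## class generators (internal, pre-filter) -------------------------------

# VF: stochastic oscillator whose dominant frequency drifts in 3-8 Hz,
# plus a weak second harmonic and coloured noise; no beat periodicity.
synth_vf <- function(n, fs) {
  f0 <- runif(1, 4, 7)
  drift <- cumsum(rnorm(n, 0, 0.02))
  f_inst <- pmin(8, pmax(3, f0 + drift))
  phase <- cumsum(2 * pi * f_inst / fs)
  amp_mod <- 1 + 0.4 * sin(2 * pi * runif(1, 0.1, 0.4) * seq_len(n) / fs +
                             runif(1, 0, 2 * pi))
  x <- amp_mod * (sin(phase) + 0.35 * sin(2 * phase + runif(1, 0, 2 * pi)))
  nse <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
  nse[is.na(nse)] <- 0
  x + 0.25 * nse
}

# Gaussian wave bump helper: adds amp * exp(-(t-mu)^2 / (2 sd^2))
gauss_wave <- function(t, mu, sd, amp) amp * exp(-((t - mu)^2) / (2 * sd^2))

# one P-QRS-T complex sampled on times `t` (s) relative to the R peak
pqrst <- function(t, r_amp = 1000, qrs_w = 0.012, with_p = TRUE,
                  t_amp = 250, t_mu = 0.25) {
  y <- gauss_wave(t, 0, qrs_w, r_amp) +
    gauss_wave(t, -0.035, 0.011, -0.15 * r_amp) +
    gauss_wave(t, 0.040, 0.012, -0.22 * r_amp) +
    gauss_wave(t, t_mu, 0.07, t_amp)
  if (with_p) y <- y + gauss_wave(t, -0.18, 0.035, 0.12 * r_amp)
  y
}

# lay beats with given RR sequence onto a trace of n samples
beat_train <- function(n, fs, rr, r_amp = 1000, qrs_w = 0.012,
                       with_p = TRUE, t_amp = 250) {
  t <- seq_len(n) / fs
  beat_times <- cumsum(rr)
  beat_times <- beat_times[beat_times < n / fs + 0.5]
  x <- numeric(n)
  for (bt in beat_times) {
    idx <- which(abs(t - bt) < 0.45)
    if (length(idx)) {
      x[idx] <- x[idx] + pqrst(t[idx] - bt, r_amp = r_amp, qrs_w = qrs_w,
                               with_p = with_p, t_amp = t_amp)
    }
  }
  x
}

# NSR: regular beats at 40-100 bpm with small RR jitter
synth_nsr <- function(n, fs) {
  rate <- runif(1, 45, 95)         # bpm; jitter keeps detected rate in 40-100
  nb <- ceiling(n / fs / (60 / rate)) + 2
  rr <- (60 / rate) * exp(rnorm(nb, 0, 0.02))
  r_amp <- runif(1, 800, 1500)
  beat_train(n, fs, rr, r_amp = r_amp, t_amp = 0.25 * r_amp)
}

# ONR: one of several organized non-sinus variants
synth_onr <- function(n, fs) {
  variant <- sample(c("afib", "wide_qrs", "brady", "ectopic"), 1)
  r_amp <- runif(1, 700, 1400)
  switch(variant,
    afib = {
      # irregularly irregular RR, no P waves, fibrillatory baseline
      rate <- runif(1, 70, 130)
      nb <- ceiling(n / fs / (60 / rate)) + 4
      rr <- pmax(0.25, (60 / rate) * exp(rnorm(nb, 0, 0.25)))
      x <- beat_train(n, fs, rr, r_amp = r_amp, with_p = FALSE,
                      t_amp = 0.2 * r_amp)
      fwave <- 60 * sin(2 * pi * runif(1, 5, 7) * seq_len(n) / fs +
                          cumsum(rnorm(n, 0, 0.05)))
      x + fwave
    },
    wide_qrs = {
      # idioventricular: wide QRS, slow-ish, no P
      rate <- runif(1, 30, 55)
      nb <- ceiling(n / fs / (60 / rate)) + 2
      rr <- (60 / rate) * exp(rnorm(nb, 0, 0.04))
      beat_train(n, fs, rr, r_amp = r_amp, qrs_w = 0.045, with_p = FALSE,
                 t_amp = 0.35 * r_amp)
    },
    brady = {
      rate <- runif(1, 25, 38)
      nb <- ceiling(n / fs / (60 / rate)) + 2
      rr <- (60 / rate) * exp(rnorm(nb, 0, 0.03))
      beat_train(n, fs, rr, r_amp = r_amp, t_amp = 0.25 * r_amp)
    },
    ectopic = {
      # sinus beats with premature ventricular contractions
      rate <- runif(1, 60, 100)
      nb <- ceiling(n / fs / (60 / rate)) + 4
      rr <- (60 / rate) * exp(rnorm(nb, 0, 0.03))
      prem <- runif(nb) < 0.25
      rr[prem] <- rr[prem] * 0.6
      beat_train(n, fs, rr, r_amp = r_amp,
                 qrs_w = ifelse(stats::runif(1) < 0.5, 0.012, 0.03),
                 t_amp = 0.25 * r_amp)
    }
  )
}

# ASYS: low-amplitude baseline wander / noise, no organized activity
synth_asys <- function(n, fs) {
  x <- as.numeric(stats::filter(rnorm(n), rep(1 / 8, 8), sides = 2))
  x[is.na(x)] <- 0
  x + 0.5 * sin(2 * pi * runif(1, 0.3, 1.2) * seq_len(n) / fs)
}
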