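## Synthetic OHCA interventions ------------------------------------------

#' Construct a signal record
#'
#' A `cpr_record` bundles the sampled defi-lead ECG (uV), an optional
#' thoracic impedance channel (Ohm, illustration only -- it never enters
#' the classifier), the sampling rate and the acquisition band.
#'
#' @param record_id Opaque identifier.
#' @param ecg Numeric vector of ECG samples (uV).
#' @param fs Sampling rate (Hz), default 125.
#' @param impedance Optional numeric vector, same length and clock as `ecg`.
#' @param band Acquisition passband (Hz).
#' @return An object of class `cpr_record`.
#' @export
cpr_record <- function(record_id, ecg, fs = 125, impedance = NULL,
                       band = c(1, 30)) {
  check_positive_scalar(fs, "fs")
  if (!is.null(impedance) && length(impedance) != length(ecg)) {
    abort("`impedance` must have the same length as `ecg`",
          class = "cprshock_error_length_mismatch")
  }
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         ecg = as.numeric(ecg), impedance = impedance,
         band = as.numeric(band)),
    class = "cpr_record"
  )
}

#' @export
print.cpr_record <- function(x, ...) {
  cat(sprintf("<cpr_record> %s: %d samples @ %g Hz (%.1f s), band %g-%g Hz%s\n",
              x$record_id, length(x$ecg), x$fs, length(x$ecg) / x$fs,
              x$band[1], x$band[2],
              if (is.null(x$impedance)) "" else ", impedance present"))
  invisible(x)
}

#' Simulate one OHCA intervention under a 30:2 CPR protocol
#'
#' Builds a full intervention: `n_cycles` CPR cycles, each consisting of
#' `cc_per_cycle` compressions at a rate drawn in 100--120 min^-1
#' followed by an insufflation pause, then a compression-free regular
#' AED analysis window of at least 10 s that terminates the record. The
#' ECG is the additive mixture of a clean rhythm trace and the CC
#' artefact; an impedance channel reflects compression deflections and
#' is flat during pauses.
#'
#' @param rhythm Rhythm class of the underlying ECG.
#' @param n_cycles Number of compression/insufflation cycles (>= 1).
#' @param protocol List with `cc_per_cycle` (default 30, the "30" of the
#'   30:2 protocol) and `insufflation_pause`, a length-2 range (s) from
#'   which pause durations are drawn uniformly (default `c(2, 8)`, the
#'   span reported for insufflation pauses in 30:2 CPR).
#' @param cc_rate Compression rate (min^-1); drawn uniformly in 100--120
#'   when `NULL`.
#' @param cc_amplitude Peak CC-artefact amplitude (uV); drawn
#'   log-uniformly in 200--3000 when `NULL`. Use 0 for artefact-free
#'   records.
#' @param fs Sampling rate (Hz).
#' @param record_id Identifier for the returned record.
#' @param seed Optional integer seed.
#' @return A list with elements `record` (a [cpr_record()]), `timeline`
#'   (a [cpr_timeline()] on the record clock, time 0 = record start) and
#'   `label` (the rhythm class).
#' @examples
#' iv <- build_intervention("VF", seed = 1)
#' iv$timeline
#' @export
build_intervention <- function(rhythm, n_cycles = 2,
                               protocol = list(cc_per_cycle = 30,
                                               insufflation_pause = c(2, 8)),
                               cc_rate = NULL, cc_amplitude = NULL,
                               fs = 125, record_id = "iv1", seed = NULL) {
  check_rhythm_class(rhythm)
  if (n_cycles < 1) {
    abort("`n_cycles` must be at least 1", class = "cprshock_error_bad_input")
  }
  cpc <- protocol$cc_per_cycle %||% 30
  pause_rng <- protocol$insufflation_pause %||% c(2, 8)
  if (length(pause_rng) != 2 || any(pause_rng <= 0) || diff(pause_rng) < 0) {
    abort("`protocol$insufflation_pause` must be a positive range",
          class = "cprshock_error_bad_input")
  }
  local_seed_if(seed)
  if (is.null(cc_rate)) cc_rate <- runif(1, 100, 120)
  if (is.null(cc_amplitude)) {
    cc_amplitude <- exp(runif(1, log(200), log(3000)))
  }

  ep_dur <- cpc / cc_rate * 60          # duration holding cc_per_cycle comps
  cur <- round(runif(1, 0.5, 1.5), 2)   # short lead-in before first CC
  starts <- stops <- numeric(n_cycles)
  for (i in seq_len(n_cycles)) {
    starts[i] <- cur
    stops[i] <- cur + ep_dur
    cur <- stops[i] +
      if (i < n_cycles) runif(1, pause_rng[1], pause_rng[2]) else 0
  }
  # regular AED analysis begins shortly after the last compression stops
  aed_start <- round((stops[n_cycles] + runif(1, 0.3, 1.0)) * fs) / fs
  total <- aed_start + 10.5
  n <- round(total * fs)

  timeline <- cpr_timeline(
    cc_episodes = tibble::tibble(start = starts, stop = stops,
                                 n_compressions = cpc),
    aed_analysis_start = aed_start,
    rhythm_segments = tibble::tibble(start = 0, stop = total, class = rhythm),
    cc_rate = cc_rate,
    coverage = c(0, total)
  )

  clean <- synth_rhythm(rhythm, total, fs)
  clean <- clean[seq_len(n)]
  artefact <- synth_cc_artefact(timeline, total, fs, cc_amplitude)[seq_len(n)]
  ecg <- clean + artefact

  # impedance: baseline with compression deflections, flat in pauses
  imp <- rep(60, n)
  t <- seq_len(n) / fs
  for (i in seq_len(n_cycles)) {
    idx <- which(t > starts[i] & t <= stops[i])
    imp[idx] <- imp[idx] +
      1.5 * abs(sin(pi * (t[idx] - starts[i]) * cc_rate / 60))
  }

  list(
    record = cpr_record(record_id, ecg, fs = fs, impedance = imp),
    timeline = timeline,
    label = rhythm
  )
}

#' Extract the 40 s period of interest around the regular AED analysis
#'
#' The period of interest covers relative time (-30 s; +10 s] around the
#' start of the regular AED analysis (mapped to 0), i.e. exactly
#' `40 * fs` samples: a 30 s CPR-contaminated buffer followed by the
#' 10 s compression-free analysis buffer. The timeline is re-expressed
#' on the relative clock and clipped to the period.
#'
#' @param record A [cpr_record()] covering at least
#'   `(aed_analysis_start - 30, aed_analysis_start + 10]`.
#' @param timeline The record's [cpr_timeline()] (absolute clock).
#' @return An object of class `cpr_poi` with elements `source`, `fs`,
#'   `samples` (length `40 * fs`), `timeline` (relative clock, coverage
#'   `(-30, 10]`) and `label`.
#' @examples
#' iv <- build_intervention("ASYS", seed = 2)
#' poi <- extract_poi(iv$record, iv$timeline)
#' length(poi$samples)
#' @export
extract_poi <- function(record, timeline) {
  stopifnot(inherits(record, "cpr_record"), inherits(timeline, "cpr_timeline"))
  fs <- record$fs
  a0 <- timeline$aed_analysis_start
  if (!is.finite(a0)) {
    abort("timeline has no `aed_analysis_start`",
          class = "cprshock_error_bad_timeline")
  }
  i_hi <- round((a0 + 10) * fs)
  i_lo <- round((a0 - 30) * fs) + 1L
  if (i_lo < 1L) {
    abort("record does not cover 30 s before the regular analysis",
          class = "cprshock_error_bad_input")
  }
  if (i_hi > length(record$ecg)) {
    abort("record does not cover 10 s after the regular analysis",
          class = "cprshock_error_bad_input")
  }
  rel <- shift_timeline(timeline, a0, coverage = c(-30, 10))
  label <- label_from_segments(rel$rhythm_segments)
  structure(
    list(source = record$record_id, fs = fs,
         samples = record$ecg[i_lo:i_hi],
         timeline = rel, label = label),
    class = "cpr_poi"
  )
}

# ground-truth label of a period: the rhythm during the regular-analysis
# buffer (0; 10], where annotation takes place
label_from_segments <- function(seg) {
  if (is.null(seg) || nrow(seg) == 0) return(NA_character_)
  hit <- seg$start < 5 & seg$stop >= 5
  if (!any(hit)) hit <- nrow(seg)       # fall back to last segment
  seg$class[which(hit)[1]]
}

#' @export
print.cpr_poi <- function(x, ...) {
  cat(sprintf("<cpr_poi> %s: %s (%s), %d samples @ %g Hz on (-30, 10] s\n",
              x$source, x$label, shock_category(x$label),
              length(x$samples), x$fs))
  invisible(x)
}

#' Check shock-advisory consistency of a period of interest
#'
#' A period is consistent when every rhythm segment covering it belongs
#' to the same shock category (Sh/NSh) as its ground-truth label.
#' Transitions between different non-shockable rhythms (e.g. ONR to
#' ASYS) do not change the shock decision and remain consistent;
#' transitions across the Sh/NSh boundary (e.g. return of spontaneous
#' circulation, refibrillation) make the period inconsistent.
#'
#' @param poi A `cpr_poi`.
#' @return `TRUE` or `FALSE`. Aborts if the rhythm segments do not cover
#'   the whole period.
#' @export
check_consistency <- function(poi) {
  stopifnot(inherits(poi, "cpr_poi"))
  seg <- poi$timeline$rhythm_segments
  if (is.null(seg) || nrow(seg) == 0) {
    abort("period has no rhythm segments", class = "cprshock_error_bad_input")
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  cov <- c(max(seg$start[1], -30), min(max(seg$stop), 10))
  gaps <- c(seg$start[-1] - seg$stop[-nrow(seg)])
  if (seg$start[1] > -30 + 1e-6 || max(seg$stop) < 10 - 1e-6 ||
      (length(gaps) && any(gaps > 1e-6))) {
    abort("rhythm segments do not cover the whole period",
          class = "cprshock_error_segment_gap")
  }
  all(shock_category(seg$class) == shock_category(poi$label))
}
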