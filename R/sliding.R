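## Sliding analysis grid and hands-off time ------------------------------

#' Decision-time grid of the sliding analysis
#'
#' The period of interest is analyzed in sliding windows shifted by 1 s.
#' Decision times (the last second of each analysis window) are aligned
#' on the integer grid -15 s, -14 s, ..., +10 s for every analysis
#' duration, giving 26 analyses per period. With duration `D` the
#' earliest window spans `(-15 - D, -15]`, which for `D = 15` exactly
#' reaches the period start at -30 s.
#'
#' @param D Analysis duration (s), one of 5, 10, 15.
#' @return Integer vector of 26 decision times.
#' @examples
#' decision_grid(10)
#' @export
decision_grid <- function(D = 10) {
  check_duration(D)
  -15:10
}

check_duration <- function(D) {
  if (!(length(D) == 1L && D %in% c(5, 10, 15))) {
    abort("analysis duration `D` must be one of 5, 10, 15 s",
          class = "cprshock_error_bad_input")
  }
  invisible(D)
}

#' Extract one analysis window from a period of interest
#'
#' Returns the `D * fs` ECG samples spanning `(t - D, t]`, the last
#' sample landing exactly on the decision time `t`.
#'
#' @param poi A `cpr_poi`.
#' @param t Decision time (s) in `[-15, 10]`.
#' @param D Analysis duration (s), one of 5, 10, 15.
#' @return Numeric vector of `D * fs` samples.
#' @examples
#' iv <- build_intervention("ASYS", seed = 3)
#' poi <- extract_poi(iv$record, iv$timeline)
#' length(extract_window(poi, 0, 10))
#' @export
extract_window <- function(poi, t, D = 10) {
  stopifnot(inherits(poi, "cpr_poi"))
  check_duration(D)
  fs <- poi$fs
  if (t - D < -30 - 1e-9 || t > 10 + 1e-9) {
    abort("window span lies outside the period of interest (-30, 10]",
          class = "cprshock_error_bad_input")
  }
  # sample i covers (-30 + (i-1)/fs, -30 + i/fs]
  i_hi <- round((t + 30) * fs)
  i_lo <- round((t - D + 30) * fs) + 1L
  poi$samples[i_lo:i_hi]
}

#' Hands-off episodes within a region
#'
#' Hands-off time (HOT) episodes are maximal CC-free intervals whose
#' full duration exceeds 1 s (shorter CC interruptions do not count);
#' typical sources are insufflation pauses and the regular AED analysis.
#' An interruption qualifies on its *full* length within the timeline's
#' known extent; the returned episodes are then clipped to `region`.
#'
#' @param timeline A [cpr_timeline()].
#' @param region Length-2 numeric `(start, stop]` to report episodes in;
#'   defaults to the timeline coverage.
#' @return Tibble with columns `start`, `stop`, `length` (the clipped
#'   overlap) and `full_length` (the unclipped interruption duration),
#'   sorted and disjoint.
#' @export
hot_episodes <- function(timeline, region = NULL) {
  stopifnot(inherits(timeline, "cpr_timeline"))
  if (is.null(region)) region <- timeline$coverage
  gaps <- cc_free_gaps(timeline)
  gaps$full_length <- gaps$stop - gaps$start
  gaps <- gaps[gaps$full_length > 1 + 1e-12, , drop = FALSE]  # strictly > 1 s
  out <- gaps
  out$start <- pmax(out$start, region[1])
  out$stop <- pmin(out$stop, region[2])
  out <- out[out$stop > out$start + 1e-12, , drop = FALSE]
  out$length <- out$stop - out$start
  tibble::as_tibble(out[, c("start", "stop", "length", "full_length")])
}

#' Sliding hands-off time (sHOT) of one analysis window
#'
#' sHOT is the cumulative duration of qualifying CC interruptions
#' (full length > 1 s) inside the analysis window `(t - D, t]`. The
#' hands-off episodes contributing to one window need not be contiguous.
#' By construction `0 <= sHOT <= D`.
#'
#' @param timeline A [cpr_timeline()] (period-of-interest clock).
#' @param t Decision time (s).
#' @param D Analysis duration (s), one of 5, 10, 15.
#' @return sHOT in seconds.
#' @examples
#' iv <- build_intervention("ONR", seed = 4)
#' poi <- extract_poi(iv$record, iv$timeline)
#' compute_shot(poi$timeline, 10, 10)  # clean analysis window: sHOT = 10
#' @export
compute_shot <- function(timeline, t, D = 10) {
  check_duration(D)
  ep <- hot_episodes(timeline, region = c(t - D, t))
  s <- sum(ep$length)
  min(max(s, 0), D)
}

#' sHOT series over the decision grid
#'
#' @param poi A `cpr_poi`.
#' @param D Analysis duration (s).
#' @return Tibble with `poi_id`, `decision_time`, `shot`.
#' @export
shot_series <- function(poi, D = 10) {
  stopifnot(inherits(poi, "cpr_poi"))
  grid <- decision_grid(D)
  tibble::tibble(
    poi_id = poi$source,
    decision_time = grid,
    shot = vapply(grid, function(t) compute_shot(poi$timeline, t, D),
                  numeric(1))
  )
}
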