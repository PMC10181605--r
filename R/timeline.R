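## Event timelines -------------------------------------------------------
##
## All times are seconds on a continuous clock; intervals are half-open
## [start, stop). Sample i of a signal at rate fs covers the interval
## ((i-1)/fs, i/fs], i.e. its timestamp is the *right* edge. This single
## convention keeps the (-30 s; +10 s] period notation, window extraction
## and sHOT interval arithmetic consistent.

#' Construct an event timeline
#'
#' An event timeline carries everything the shock-advisory pipeline needs
#' to know about an intervention besides the waveform itself: when chest
#' compressions (CC) were delivered, when the regular AED analysis
#' started, and which rhythm was present when.
#'
#' @param cc_episodes Data frame with columns `start`, `stop` (seconds,
#'   half-open `[start, stop)`) during which compressions are delivered;
#'   may have zero rows. Episodes must be sorted and disjoint.
#' @param aed_analysis_start Time (s) at which the regular AED analysis
#'   begins. No CC episode may intersect the following 10 s.
#' @param rhythm_segments Data frame with columns `start`, `stop`,
#'   `class` giving the underlying rhythm over time.
#' @param cc_rate Compression rate within an episode (min^-1). Guideline
#'   CPR uses 100--120 min^-1.
#' @param coverage Length-2 numeric: the time span over which the
#'   timeline is informative (used to bound hands-off episodes).
#' @return An object of class `cpr_timeline`.
#' @examples
#' tl <- cpr_timeline(
#'   cc_episodes = data.frame(start = 0, stop = 17),
#'   aed_analysis_start = 20,
#'   rhythm_segments = data.frame(start = 0, stop = 30, class = "ASYS"),
#'   cc_rate = 110, coverage = c(0, 30)
#' )
#' tl
#' @export
cpr_timeline <- function(cc_episodes = data.frame(start = numeric(), stop = numeric()),
                         aed_analysis_start = NA_real_,
                         rhythm_segments = NULL,
                         cc_rate = NA_real_,
                         coverage = NULL) {
  cc_episodes <- tibble::as_tibble(cc_episodes)
  if (!all(c("start", "stop") %in% names(cc_episodes))) {
    abort("`cc_episodes` needs columns `start` and `stop`",
          class = "cprshock_error_bad_timeline")
  }
  if (!is.null(rhythm_segments)) {
    rhythm_segments <- tibble::as_tibble(rhythm_segments)
    if (!all(c("start", "stop", "class") %in% names(rhythm_segments))) {
      abort("`rhythm_segments` needs columns `start`, `stop`, `class`",
            class = "cprshock_error_bad_timeline")
    }
    check_rhythm_class(rhythm_segments$class)
  }
  if (is.null(coverage)) {
    lo <- suppressWarnings(min(cc_episodes$start, rhythm_segments$start, 0))
    hi <- suppressWarnings(max(cc_episodes$stop, rhythm_segments$stop,
                               aed_analysis_start + 10, na.rm = TRUE))
    coverage <- c(lo, hi)
  }
  tl <- structure(
    list(
      cc_episodes = cc_episodes,
      aed_analysis_start = aed_analysis_start,
      rhythm_segments = rhythm_segments,
      cc_rate = cc_rate,
      coverage = as.numeric(coverage)
    ),
    class = "cpr_timeline"
  )
  validate_timeline(tl)
  tl
}

#' Validate timeline invariants
#'
#' Checks that CC episodes are sorted, disjoint, of positive length, and
#' that none intersects the 10 s regular-analysis window
#' `(aed_analysis_start, aed_analysis_start + 10]`.
#'
#' @param tl A `cpr_timeline`.
#' @return `tl`, invisibly; aborts with a classed error on violation.
#' @export
validate_timeline <- function(tl) {
  ep <- tl$cc_episodes
  if (nrow(ep) > 0) {
    if (any(ep$stop <= ep$start)) {
      abort("CC episodes must have stop > start",
            class = "cprshock_error_bad_timeline")
    }
    if (is.unsorted(ep$start, strictly = FALSE)) {
      abort("CC episodes must be sorted by start",
            class = "cprshock_error_bad_timeline")
    }
    if (nrow(ep) > 1 && any(ep$start[-1] < ep$stop[-nrow(ep)])) {
      abort("CC episodes overlap", class = "cprshock_error_episode_overlap")
    }
    a0 <- tl$aed_analysis_start
    if (is.finite(a0)) {
      # (a0, a0 + 10] must be CC free
      if (any(ep$start < a0 + 10 & ep$stop > a0)) {
        abort("a CC episode intersects the regular-analysis window",
              class = "cprshock_error_bad_timeline")
      }
    }
  }
  seg <- tl$rhythm_segments
  if (!is.null(seg) && nrow(seg) > 0 && any(seg$stop <= seg$start)) {
    abort("rhythm segments must have stop > start",
          class = "cprshock_error_bad_timeline")
  }
  invisible(tl)
}

#' @export
print.cpr_timeline <- function(x, ...) {
  cat("<cpr_timeline>\n")
  cat(sprintf("  coverage: (%.2f, %.2f] s\n", x$coverage[1], x$coverage[2]))
  cat(sprintf("  CC episodes: %d (rate %s min^-1)\n",
              nrow(x$cc_episodes),
              ifelse(is.na(x$cc_rate), "?", format(x$cc_rate, digits = 4))))
  cat(sprintf("  AED analysis start: %s s\n",
              ifelse(is.na(x$aed_analysis_start), "?",
                     format(x$aed_analysis_start, digits = 6))))
  if (!is.null(x$rhythm_segments)) {
    cat(sprintf("  rhythm: %s\n",
                paste(unique(x$rhythm_segments$class), collapse = " -> ")))
  }
  invisible(x)
}

## interval helpers (internal) -------------------------------------------

# clip intervals (tibble start/stop) to [lo, hi); drop empties
clip_intervals <- function(iv, lo, hi) {
  if (nrow(iv) == 0) return(iv)
  iv$start <- pmax(iv$start, lo)
  iv$stop <- pmin(iv$stop, hi)
  iv[iv$stop > iv$start + 1e-12, , drop = FALSE]
}

# shift all times in a timeline by -origin (origin maps to 0)
shift_timeline <- function(tl, origin, coverage = NULL) {
  ep <- tl$cc_episodes
  ep$start <- ep$start - origin
  ep$stop <- ep$stop - origin
  seg <- tl$rhythm_segments
  if (!is.null(seg)) {
    seg$start <- seg$start - origin
    seg$stop <- seg$stop - origin
  }
  if (is.null(coverage)) coverage <- tl$coverage - origin
  if (!is.null(seg)) seg <- clip_intervals(seg, coverage[1], coverage[2])
  ep <- clip_intervals(ep, coverage[1], coverage[2])
  cpr_timeline(
    cc_episodes = ep,
    aed_analysis_start = tl$aed_analysis_start - origin,
    rhythm_segments = seg,
    cc_rate = tl$cc_rate,
    coverage = coverage
  )
}

# complement of cc episodes within the coverage span: the CC-free gaps,
# as a tibble(start, stop); gaps are maximal by construction
cc_free_gaps <- function(tl) {
  lo <- tl$coverage[1]
  hi <- tl$coverage[2]
  ep <- clip_intervals(tl$cc_episodes, lo, hi)
  if (nrow(ep) == 0) {
    return(tibble::tibble(start = lo, stop = hi))
  }
  starts <- c(lo, ep$stop)
  stops <- c(ep$start, hi)
  gaps <- tibble::tibble(start = starts, stop = stops)
  gaps[gaps$stop > gaps$start + 1e-12, , drop = FALSE]
}
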