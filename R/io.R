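## On-disk formats --------------------------------------------------------
##
## A record is stored as two plain-text files sharing a stem:
##   <stem>_signal.csv   columns time_s, ecg_uV [, impedance_ohm]
##   <stem>_events.json  {fs, cc_episodes: [[start, stop], ...],
##                        aed_analysis_start, cc_rate,
##                        rhythm_segments: [{start, stop, class}, ...],
##                        label, coverage}
## Times are seconds (floats) on the half-open [start, stop) convention;
## the signal file is written with full precision so the write -> read
## round trip is lossless.

#' Write a record and its timeline to disk
#'
#' @param record A [cpr_record()].
#' @param timeline The matching [cpr_timeline()].
#' @param stem Path stem; `<stem>_signal.csv` and `<stem>_events.json`
#'   are created.
#' @param label Optional rhythm label stored in the sidecar.
#' @return `stem`, invisibly.
#' @export
write_record <- function(record, timeline, stem, label = NULL) {
  stopifnot(inherits(record, "cpr_record"), inherits(timeline, "cpr_timeline"))
  validate_timeline(timeline)
  cols <- list(time_s = seq_along(record$ecg) / record$fs,
               ecg_uV = record$ecg)
  if (!is.null(record$impedance)) cols$impedance_ohm <- record$impedance
  # %.17g guarantees an exact double round trip through the text file
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)),
                           sep = ","))
  readr::write_lines(c(paste(names(cols), collapse = ","), body),
                     paste0(stem, "_signal.csv"))
  ev <- list(
    record_id = record$record_id,
    fs = record$fs,
    band = record$band,
    cc_episodes = timeline$cc_episodes[, c("start", "stop")],
    aed_analysis_start = timeline$aed_analysis_start,
    cc_rate = timeline$cc_rate,
    rhythm_segments = timeline$rhythm_segments,
    coverage = timeline$coverage,
    label = label
  )
  jsonlite::write_json(ev, paste0(stem, "_events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a record and its timeline from disk
#'
#' Inverse of [write_record()]. Malformed inputs raise classed errors:
#' `cprshock_error_bad_timeline` / `cprshock_error_episode_overlap` for
#' inconsistent event sidecars, `cprshock_error_fs_mismatch` when the
#' signal time base disagrees with the sidecar sampling rate, and
#' `cprshock_error_length_mismatch` when channel lengths disagree.
#'
#' @param stem Path stem used by [write_record()].
#' @return List with `record`, `timeline`, `label`.
#' @export
read_record <- function(stem) {
  sig_path <- paste0(stem, "_signal.csv")
  ev_path <- paste0(stem, "_events.json")
  if (!file.exists(sig_path) || !file.exists(ev_path)) {
    abort(sprintf("missing signal or events file for stem '%s'", stem),
          class = "cprshock_error_missing_file")
  }
  # base read.csv: correctly rounded double parsing (exact round trip)
  sig <- tibble::as_tibble(utils::read.csv(sig_path))
  ev <- jsonlite::read_json(ev_path, simplifyVector = TRUE)
  fs <- as.numeric(ev$fs)
  if (nrow(sig) >= 2) {
    dt <- stats::median(diff(sig$time_s))
    if (abs(dt - 1 / fs) > 1e-6) {
      abort("signal time base disagrees with sidecar sampling rate",
            class = "cprshock_error_fs_mismatch")
    }
  }
  if (!is.null(sig[["impedance_ohm"]]) &&
      length(sig[["impedance_ohm"]]) != length(sig$ecg_uV)) {
    abort("impedance and ECG lengths disagree",
          class = "cprshock_error_length_mismatch")
  }
  eps <- ev$cc_episodes
  cc <- if (is.data.frame(eps) && nrow(eps)) {
    tibble::tibble(start = as.numeric(eps$start), stop = as.numeric(eps$stop))
  } else {
    tibble::tibble(start = numeric(), stop = numeric())
  }
  timeline <- cpr_timeline(
    cc_episodes = cc,
    aed_analysis_start = ev$aed_analysis_start %||% NA_real_,
    rhythm_segments = ev$rhythm_segments,
    cc_rate = ev$cc_rate %||% NA_real_,
    coverage = ev$coverage
  )
  record <- cpr_record(ev$record_id %||% basename(stem),
                       ecg = sig$ecg_uV, fs = fs,
                       impedance = sig[["impedance_ohm"]],
                       band = ev$band %||% c(1, 30))
  list(record = record, timeline = timeline, label = ev$label)
}

#' Write a dataset to a directory
#'
#' Writes every period's source signal and event sidecar plus a TSV
#' manifest (`manifest.tsv`: `patient_id`, `poi_id`, `split`, `label`,
#' `category`, `stem`).
#'
#' @param dataset A `cpr_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cpr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$stem <- file.path(dir, man$poi_id)
  for (i in seq_len(nrow(man))) {
    poi <- dataset$pois[[man$poi_id[i]]]
    rec <- cpr_record(poi$source, poi$samples, fs = poi$fs)
    write_record(rec, poi$timeline, man$stem[i], label = poi$label)
  }
  readr::write_tsv(man, file.path(dir, "manifest.tsv"))
  invisible(man)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.tsv` and the record files.
#' @return A `cpr_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                         show_col_types = FALSE)
  pois <- list()
  for (i in seq_len(nrow(man))) {
    rr <- read_record(man$stem[i])
    pois[[man$poi_id[i]]] <- structure(
      list(source = rr$record$record_id, fs = rr$record$fs,
           samples = rr$record$ecg, timeline = rr$timeline,
           label = rr$label),
      class = "cpr_poi"
    )
  }
  structure(list(manifest = tibble::as_tibble(man[, setdiff(names(man), "stem")]),
                 pois = pois),
            class = "cpr_dataset")
}
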