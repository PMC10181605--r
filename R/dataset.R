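## Synthetic OHCA dataset ------------------------------------------------

#' Simulate a patient-wise split dataset of periods of interest
#'
#' Generates `n_patients` synthetic OHCA patients, each contributing
#' `periods_per_patient` interventions (and hence periods of interest),
#' with rhythm classes drawn from `class_mix`. Patients are split into
#' two uniform parts for independent learning and testing; no patient
#' contributes periods to both splits.
#'
#' The default class mix mirrors the real-life proportion of OHCA
#' rhythms around a regular AED analysis: mostly asystole (about 63%)
#' and other organized non-shockable rhythms (about 28%), rare
#' ventricular fibrillation (about 6%) and normal sinus rhythm (about
#' 3%).
#'
#' @param n_patients Number of patients (>= 2).
#' @param class_mix Named proportions over `VF`, `NSR`, `ONR`, `ASYS`;
#'   must sum to 1.
#' @param periods_per_patient Periods of interest per patient, each from
#'   its own independently simulated intervention (the OHCA registries
#'   this emulates average close to five periods per patient, the
#'   episodes being separated by 2-minute CPR cycles and treated as
#'   independent samples because the artefact process is
#'   nonstationary). Default 3.
#' @param seed Optional integer seed making the whole dataset
#'   reproducible.
#' @param n_cycles,cc_amplitude Passed to [build_intervention()].
#' @return An object of class `cpr_dataset`: a list with `manifest`
#'   (tibble: `patient_id`, `poi_id`, `split`, `label`, `category`) and
#'   `pois` (named list of [extract_poi()] results).
#' @examples
#' ds <- make_dataset(6, seed = 1)
#' ds$manifest
#' @export
make_dataset <- function(n_patients,
                         class_mix = c(VF = 0.06, NSR = 0.03,
                                       ONR = 0.28, ASYS = 0.63),
                         periods_per_patient = 3,
                         seed = NULL, n_cycles = 2, cc_amplitude = NULL) {
  if (n_patients < 2) {
    abort("`n_patients` must be at least 2", class = "cprshock_error_bad_input")
  }
  check_rhythm_class(names(class_mix))
  if (abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` must sum to 1", class = "cprshock_error_bad_input")
  }
  local_seed_if(seed)

  patient_id <- sprintf("P%04d", seq_len(n_patients))
  learning <- sample(patient_id, floor(n_patients / 2))
  rows <- list()
  pois <- list()
  k <- 0L
  for (p in patient_id) {
    for (j in seq_len(periods_per_patient)) {
      k <- k + 1L
      poi_id <- sprintf("%s_poi%02d", p, j)
      label <- sample(names(class_mix), 1, prob = class_mix)
      iv <- build_intervention(label, n_cycles = n_cycles,
                               cc_amplitude = cc_amplitude,
                               record_id = poi_id)
      poi <- extract_poi(iv$record, iv$timeline)
      stopifnot(check_consistency(poi))
      pois[[poi_id]] <- poi
      rows[[k]] <- tibble::tibble(
        patient_id = p, poi_id = poi_id,
        split = if (p %in% learning) "learning" else "test",
        label = label, category = shock_category(label)
      )
    }
  }
  structure(
    list(manifest = dplyr::bind_rows(rows), pois = pois),
    class = "cpr_dataset"
  )
}

#' @export
print.cpr_dataset <- function(x, ...) {
  cat(sprintf("<cpr_dataset> %d periods of interest from %d patients\n",
              nrow(x$manifest), dplyr::n_distinct(x$manifest$patient_id)))
  print(dplyr::count(x$manifest, .data$split, .data$label))
  invisible(x)
}
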