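## Shock-advisory performance metrics ------------------------------------

#' Sensitivity and specificity from confusion counts
#'
#' `Se = TP / (TP + FN)` over shockable cases and `Sp = TN / (TN + FP)`
#' over non-shockable cases. A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return Named numeric vector `c(se =, sp =)`.
#' @examples
#' se_sp(tp = 92, fn = 8, tn = 188, fp = 12)
#' @export
se_sp <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "cprshock_error_bad_input")
  }
  c(se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided interval at confidence `level` (default 90%,
#' z = 1.6449), clipped to [0, 1]. The Wilson interval behaves well at
#' the boundary proportions 0 and 1 that perfect classifiers produce.
#'
#' @param successes,n Observed successes out of `n` trials.
#' @param level Confidence level.
#' @return Named numeric vector `c(lo =, hi =)`.
#' @examples
#' ci_wilson(9, 10)
#' @export
ci_wilson <- function(successes, n, level = 0.90) {
  if (n <= 0 || successes < 0 || successes > n) {
    abort("need 0 <= successes <= n with n > 0",
          class = "cprshock_error_bad_input")
  }
  z <- qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' sHOT bin labels
#'
#' The twelve ordered sHOT strata: exactly 0 s, the half-open 1 s
#' intervals (0-1], (1-2], ..., (9-10], and >10 s. Every non-negative
#' sHOT value maps to exactly one bin. For 5 s and 10 s analysis
#' durations only the bins reachable up to the duration can be
#' populated.
#'
#' @param shot Numeric vector of sHOT values (s), all >= 0.
#' @return Ordered factor with the twelve bin levels.
#' @examples
#' bin_shot(c(0, 0.5, 10, 10.2))
#' @export
bin_shot <- function(shot) {
  if (any(shot < 0)) {
    abort("sHOT values must be non-negative",
          class = "cprshock_error_bad_input")
  }
  lv <- shot_bin_levels()
  k <- as.integer(pmax(1, ceiling(shot - 1e-9)))  # (k-1, k] -> k, float tolerant
  lab <- ifelse(shot <= 1e-9, "0",
                ifelse(shot > 10 + 1e-9, ">10",
                       sprintf("(%d-%d]", k - 1, k)))
  factor(lab, levels = lv, ordered = TRUE)
}

shot_bin_levels <- function() {
  c("0", sprintf("(%d-%d]", 0:9, 1:10), ">10")
}

# Se for VF rows, Sp for NSh rows, from an advice subset
metric_from_advices <- function(category, decision) {
  n <- length(decision)
  if (n == 0) return(c(n = 0, successes = NA_real_, estimate = NA_real_))
  if (category == "Sh") {
    s <- sum(decision == "Sh")
  } else {
    s <- sum(decision == "NSh")
  }
  c(n = n, successes = s, estimate = s / n)
}

summarise_groups <- function(advices, group_col, level = 0.90) {
  groups <- dplyr::group_split(dplyr::group_by(
    advices, .data$label, .data[[group_col]]), .keep = TRUE)
  rows <- lapply(groups, function(g) {
    lab <- g$label[1]
    cat <- shock_category(lab)
    m <- metric_from_advices(cat, g$decision)
    ci <- if (m[["n"]] > 0) ci_wilson(m[["successes"]], m[["n"]], level)
          else c(lo = NA_real_, hi = NA_real_)
    tibble::tibble(
      label = lab,
      !!group_col := g[[group_col]][1],
      metric = if (cat == "Sh") "Se" else "Sp",
      n = as.integer(m[["n"]]),
      estimate = m[["estimate"]],
      lo = ci[["lo"]], hi = ci[["hi"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Performance per decision time
#'
#' Sensitivity (VF) or specificity (NSR, ONR, ASYS) per rhythm class at
#' each of the 26 decision times, each period contributing exactly one
#' decision per time, with two-sided Wilson confidence intervals.
#'
#' @param advices Advice tibble from [evaluate_sliding()] (columns
#'   `poi_id`, `label`, `decision_time`, `decision`).
#' @param level Confidence level for the interval (default 0.90).
#' @return Tibble with one row per (class, decision time): `label`,
#'   `decision_time`, `metric` (`"Se"`/`"Sp"`), `n`, `estimate`, `lo`,
#'   `hi`, `aha_pass`.
#' @export
performance_by_time <- function(advices, level = 0.90) {
  check_advices(advices)
  counts <- dplyr::count(advices, .data$poi_id, .data$decision_time)
  if (any(counts$n != 1)) {
    abort("each period must contribute exactly one decision per time",
          class = "cprshock_error_bad_input")
  }
  out <- summarise_groups(advices, "decision_time", level)
  out$aha_pass <- aha_check(out$label, out$estimate)
  dplyr::arrange(out, .data$label, .data$decision_time)
}

#' Performance per sHOT stratum
#'
#' Pools all 26 sliding decisions of all periods and groups them by the
#' twelve sHOT bins, reporting Se (VF) or Sp (NSR/ONR/ASYS) per rhythm
#' class and bin. Empty strata are reported with `n = 0` and an
#' undefined (`NA`) metric.
#'
#' @param advices Advice tibble from [evaluate_sliding()], with a
#'   `shot` column.
#' @param level Confidence level for the Wilson interval.
#' @return Tibble with one row per (class, sHOT bin), columns as in
#'   [performance_by_time()] plus `shot_bin`.
#' @export
performance_by_shot <- function(advices, level = 0.90) {
  check_advices(advices, need_shot = TRUE)
  advices$shot_bin <- bin_shot(advices$shot)
  out <- summarise_groups(advices, "shot_bin", level)
  # surface empty strata explicitly
  full <- tidyr::crossing(
    label = intersect(rhythm_classes(), unique(advices$label)),
    shot_bin = factor(shot_bin_levels(), levels = shot_bin_levels(),
                      ordered = TRUE)
  )
  out <- dplyr::left_join(full, out, by = c("label", "shot_bin"))
  out$metric <- ifelse(shock_category(out$label) == "Sh", "Se", "Sp")
  out$n[is.na(out$n)] <- 0L
  out$aha_pass <- aha_check(out$label, out$estimate)
  dplyr::arrange(out, .data$label, .data$shot_bin)
}

check_advices <- function(advices, need_shot = FALSE) {
  need <- c("poi_id", "label", "decision_time", "decision")
  if (need_shot) need <- c(need, "shot")
  missing_cols <- setdiff(need, names(advices))
  if (length(missing_cols)) {
    abort(sprintf("advice table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cprshock_error_bad_input")
  }
  check_rhythm_class(advices$label)
  invisible(advices)
}

#' ROC curve and AUC
#'
#' Sweeps all observed score thresholds (decision rule `score >=
#' threshold`) and integrates the curve trapezoidally. On small sets
#' the AUC equals the pairwise concordance (Mann-Whitney U) statistic,
#' with ties counted 1/2.
#'
#' @param scores Classifier scores (higher = more shockable).
#' @param labels Shock categories, logical or 0/1, parallel to `scores`.
#' @return List of class `roc_curve` with `points` (tibble `threshold`,
#'   `tpr`, `fpr`) and `auc`.
#' @examples
#' roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_curve <- function(scores, labels) {
  delta <- as_shock_indicator(labels)
  if (all(delta == 1) || all(delta == 0)) {
    abort("both classes must be present for a ROC curve",
          class = "cprshock_error_bad_input")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sh <- scores[delta == 1]
  nsh <- scores[delta == 0]
  tpr <- vapply(thr, function(th) mean(sh >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(nsh >= th), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(points = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
         auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' AED rhythm-analysis performance goals
#'
#' Flags whether a per-class metric satisfies the AHA goals for AED
#' rhythm analysis on artefact-free ECG: Se(VF) 90%, Sp(ASYS) 95%,
#' Sp(ONR) 95%, Sp(NSR) 99%. Boundary values equal to the goal are
#' treated as passing. Undefined metrics yield `NA`.
#'
#' @param class Rhythm class vector.
#' @param estimate Metric estimates in [0, 1] (Se for VF, Sp otherwise).
#' @return Logical vector.
#' @examples
#' aha_check(c("VF", "ASYS"), c(0.878, 0.969))
#' @export
aha_check <- function(class, estimate) {
  check_rhythm_class(class)
  goal <- c(VF = 0.90, NSR = 0.99, ONR = 0.95, ASYS = 0.95)[class]
  ifelse(is.na(estimate), NA, estimate >= goal - 1e-9)
}
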