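## Training protocol -----------------------------------------------------

#' Prevalence-based class weights
#'
#' The loss penalty is proportional to the prevalence of the *other*
#' class: `w_Sh = n_NSh / (n_Sh + n_NSh)` and
#' `w_NSh = n_Sh / (n_Sh + n_NSh)`, so the weights sum to exactly 1 and
#' the rare shockable class carries the large weight. With the
#' period-level learning counts 409 shockable and 6763 non-shockable
#' this gives (0.943, 0.057) to three decimals.
#'
#' @param n_sh,n_nsh Positive class counts (shockable / non-shockable).
#' @return Named numeric vector `c(w_sh =, w_nsh =)`.
#' @examples
#' class_weights(409, 6763)
#' @export
class_weights <- function(n_sh, n_nsh) {
  if (n_sh <= 0 || n_nsh <= 0) {
    abort("both class counts must be positive",
          class = "cprshock_error_bad_input")
  }
  tot <- n_sh + n_nsh
  c(w_sh = n_nsh / tot, w_nsh = n_sh / tot)
}

#' Class-weighted binary cross-entropy
#'
#' `Loss = -(1/M) * sum_m [ delta_m * w_Sh * log P_m +
#' (1 - delta_m) * w_NSh * log(1 - P_m) ]`, where `delta_m` indicates a
#' shockable target and `P_m` is the predicted shock probability.
#' Probabilities are clipped to `[eps, 1 - eps]` inside the logs. With
#' equal weights (0.5, 0.5) the value is exactly half the unweighted
#' mean binary cross-entropy.
#'
#' @param p Predicted probabilities.
#' @param delta 0/1 indicators (1 = shockable), same length as `p`.
#' @param w_sh,w_nsh Class weights (positive, summing to 1).
#' @param eps Clipping constant for numerical safety.
#' @return Non-negative scalar loss.
#' @examples
#' weighted_bce(0.5, 1, 0.943, 0.057)  # 0.943 * log(2)
#' @export
weighted_bce <- function(p, delta, w_sh = 0.943, w_nsh = 0.057, eps = 1e-7) {
  if (length(p) != length(delta)) {
    abort("`p` and `delta` must have the same length",
          class = "cprshock_error_length_mismatch")
  }
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(delta * w_sh * log(pc) + (1 - delta) * w_nsh * log(1 - pc))
}

#' Expand periods of interest into the sliding training set
#'
#' Every period contributes one analysis window per decision time of
#' the sliding grid, i.e. exactly 26 labelled windows inheriting the
#' period label. The learning database is thereby multiplied by 26.
#'
#' @param manifest A `cpr_dataset` or its manifest tibble (columns
#'   `poi_id`, `label`, and optionally `patient_id`, `split`).
#' @param D Analysis duration (s).
#' @param split Restrict to one split (`"learning"`, `"test"`) or
#'   `NULL` for all rows.
#' @return Tibble with one row per (period, decision time):
#'   `poi_id`, `decision_time`, `label`, `category` plus any carried
#'   columns.
#' @examples
#' m <- tibble::tibble(poi_id = c("a", "b"), label = c("VF", "ASYS"))
#' nrow(expand_windows(m, 10))
#' @export
expand_windows <- function(manifest, D = 10, split = NULL) {
  if (inherits(manifest, "cpr_dataset")) manifest <- manifest$manifest
  manifest <- tibble::as_tibble(manifest)
  if (!is.null(split) && "split" %in% names(manifest)) {
    manifest <- manifest[manifest$split == split, , drop = FALSE]
  }
  grid <- decision_grid(D)
  out <- tidyr::crossing(manifest, decision_time = grid)
  out$category <- shock_category(out$label)
  dplyr::arrange(out, .data$poi_id, .data$decision_time)
}

#' Training configuration
#'
#' Defaults follow the full training protocol: Adam (learning rate
#' 0.001, beta1 = 0.9, beta2 = 0.999), batch size 128, at most 750
#' epochs with early stopping after 150 epochs without validation-loss
#' improvement, a patient-wise 70/30 train/validation split of the
#' learning set, and 5 independent runs of which the one with minimal
#' validation loss is kept. Reduced budgets (fewer epochs/runs) are the
#' practical choice for synthetic desk-scale experiments.
#'
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); must be below `epochs`. The weights giving the best
#'   validation loss are restored.
#' @param batch_size Minibatch size.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param runs Independent training runs.
#' @param val_fraction Fraction of learning patients held out for
#'   validation.
#' @param eps Probability clipping inside the loss.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 750, patience = 150, batch_size = 128,
                         lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         runs = 5, val_fraction = 0.3, eps = 1e-7) {
  if (patience >= epochs) {
    abort("`patience` must be smaller than `epochs`",
          class = "cprshock_error_bad_input")
  }
  structure(list(epochs = epochs, patience = patience,
                 batch_size = batch_size, lr = lr, beta1 = beta1,
                 beta2 = beta2, runs = runs, val_fraction = val_fraction,
                 eps = eps),
            class = "train_config")
}

## flat parameter list helpers for the optimiser
cnn_param_list <- function(w) c(w$W, w$b, list(w$wd), list(w$bd))
cnn_param_restore <- function(model, pl) {
  n_l <- length(model$kernels)
  model$weights$W <- pl[seq_len(n_l)]
  model$weights$b <- pl[n_l + seq_len(n_l)]
  model$weights$wd <- pl[[2 * n_l + 1]]
  model$weights$bd <- pl[[2 * n_l + 2]]
  model
}
grad_param_list <- function(g) c(g$W, g$b, list(g$wd), list(g$bd))

adam_init <- function(pl) {
  list(m = lapply(pl, function(x) x * 0),
       v = lapply(pl, function(x) x * 0), t = 0L)
}

adam_step <- function(pl, gl, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (j in seq_along(pl)) {
    st$m[[j]] <- beta1 * st$m[[j]] + (1 - beta1) * gl[[j]]
    st$v[[j]] <- beta2 * st$v[[j]] + (1 - beta2) * gl[[j]]^2
    pl[[j]] <- pl[[j]] - lr * (st$m[[j]] / bc1) / (sqrt(st$v[[j]] / bc2) + eps)
  }
  list(pl = pl, st = st)
}

# materialise all analysis windows of the given POIs as one N x (26*nPOI)
# matrix, column order matching expand_windows() (poi_id, then time)
window_matrix <- function(dataset, poi_ids, D) {
  grid <- decision_grid(D)
  fs <- dataset$pois[[poi_ids[1]]]$fs
  N <- round(D * fs)
  X <- matrix(0, N, length(poi_ids) * length(grid))
  j <- 0L
  for (id in poi_ids) {
    poi <- dataset$pois[[id]]
    for (t in grid) {
      j <- j + 1L
      X[, j] <- extract_window(poi, t, D)
    }
  }
  X
}

#' Train the shock-advisory CNN on a synthetic dataset
#'
#' Implements the full protocol: the learning split is expanded 26-fold
#' into sliding analysis windows, partitioned patient-wise 70/30 into
#' training and validation, and the network is trained with Adam on the
#' prevalence-weighted binary cross-entropy. `config$runs` independent
#' runs are performed; the run with the minimum validation loss is
#' selected, and its validation scores determine the ROC operating
#' point by maximising Se + Sp.
#'
#' @param dataset A `cpr_dataset` from [make_dataset()].
#' @param D Analysis duration (s), one of 5, 10, 15.
#' @param config A [train_config()].
#' @param seed Integer seed; run `r` uses seed `seed + r` for weight
#'   initialisation, shuffling and dropout, making training
#'   deterministic given seeds.
#' @param verbose Print per-epoch progress.
#' @return An object of class `cnn_cpr_fit`: list with `model` (best
#'   run, best-epoch weights), `operating_point`, `runs` (per-run
#'   summary tibble), `history` (per-epoch tibble of the selected run),
#'   `validation` (tibble of validation scores and categories),
#'   `class_weights`, `config`, `D`.
#' @export
train_cnn <- function(dataset, D = 10, config = train_config(),
                      seed = 1, verbose = FALSE) {
  stopifnot(inherits(dataset, "cpr_dataset"))
  check_duration(D)
  man <- dataset$manifest
  learn <- man[man$split == "learning", , drop = FALSE]
  if (nrow(learn) == 0) {
    abort("learning split is empty", class = "cprshock_error_bad_input")
  }
  # class weights from period-level counts of the learning database
  n_sh <- sum(learn$category == "Sh")
  n_nsh <- sum(learn$category == "NSh")
  if (n_sh == 0 || n_nsh == 0) {
    abort("learning split must contain both shock categories",
          class = "cprshock_error_bad_input")
  }
  cw <- class_weights(n_sh, n_nsh)

  # patient-wise 70/30 train/validation partition (fixed across runs);
  # re-drawn if a side misses one of the two shock categories, which
  # happens easily at small n with a 6% shockable prevalence
  withr::with_seed(as.integer(seed), {
    pats <- unique(learn$patient_id)
    n_val <- max(1L, round(config$val_fraction * length(pats)))
    for (attempt in seq_len(50)) {
      val_pats <- sample(pats, n_val)
      both <- function(ids) length(unique(learn$category[ids])) == 2
      if (both(learn$patient_id %in% val_pats) &&
          both(!(learn$patient_id %in% val_pats))) break
    }
  })
  tr_ids <- sort(learn$poi_id[!(learn$patient_id %in% val_pats)])
  va_ids <- sort(learn$poi_id[learn$patient_id %in% val_pats])
  if (!length(tr_ids) || !length(va_ids) ||
      length(unique(learn$category[learn$poi_id %in% va_ids])) < 2 ||
      length(unique(learn$category[learn$poi_id %in% tr_ids])) < 2) {
    abort("train/validation partition is degenerate (a side misses a class)",
          class = "cprshock_error_bad_input")
  }

  ex_tr <- expand_windows(learn[learn$poi_id %in% tr_ids, ], D)
  ex_va <- expand_windows(learn[learn$poi_id %in% va_ids, ], D)
  X_tr <- window_matrix(dataset, tr_ids, D)
  X_va <- window_matrix(dataset, va_ids, D)
  y_tr <- as.numeric(ex_tr$category == "Sh")
  y_va <- as.numeric(ex_va$category == "Sh")

  run_results <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    run_results[[r]] <- withr::with_seed(as.integer(seed) + r, {
      train_one_run(D, X_tr, y_tr, X_va, y_va, cw, config,
                    fs = dataset$pois[[tr_ids[1]]]$fs, verbose = verbose,
                    run_id = r)
    })
  }
  best_loss <- vapply(run_results, function(z) z$best_val_loss, numeric(1))
  sel <- which.min(best_loss)
  best <- run_results[[sel]]

  val_scores <- cnn_predict(best$model, X_va)
  op <- select_operating_point(val_scores, ex_va$category)

  structure(
    list(
      model = best$model,
      operating_point = op,
      runs = tibble::tibble(
        run = seq_len(config$runs),
        seed = as.integer(seed) + seq_len(config$runs),
        epochs_run = vapply(run_results, function(z) z$epochs_run, numeric(1)),
        best_val_loss = best_loss,
        selected = seq_len(config$runs) == sel
      ),
      history = best$history,
      validation = tibble::tibble(poi_id = ex_va$poi_id,
                                  decision_time = ex_va$decision_time,
                                  score = val_scores,
                                  category = ex_va$category,
                                  label = ex_va$label),
      class_weights = cw,
      config = config,
      D = D
    ),
    class = "cnn_cpr_fit"
  )
}

train_one_run <- function(D, X_tr, y_tr, X_va, y_va, cw, config, fs,
                          verbose = FALSE, run_id = 1L) {
  model <- build_cnn(D, fs = fs)
  pl <- cnn_param_list(model$weights)
  st <- adam_init(pl)
  n <- length(y_tr)
  best_val <- Inf
  best_pl <- pl
  best_epoch <- 0L
  hist <- vector("list", config$epochs)
  wait <- 0L
  ep <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(n, s + config$batch_size - 1L)]
      fwd <- cnn_forward(model, X_tr[, idx, drop = FALSE], training = TRUE)
      d <- y_tr[idx]
      p <- fwd$p
      tr_loss <- tr_loss + length(idx) *
        weighted_bce(p, d, cw[["w_sh"]], cw[["w_nsh"]], config$eps)
      dz <- (-d * cw[["w_sh"]] * (1 - p) +
               (1 - d) * cw[["w_nsh"]] * p) / length(idx)
      g <- cnn_backward(model, fwd, dz)
      upd <- adam_step(pl, grad_param_list(g), st,
                       config$lr, config$beta1, config$beta2)
      pl <- upd$pl
      st <- upd$st
      model <- cnn_param_restore(model, pl)
    }
    val_p <- cnn_predict(model, X_va)
    val_loss <- weighted_bce(val_p, y_va, cw[["w_sh"]], cw[["w_nsh"]],
                             config$eps)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / n,
                                 val_loss = val_loss)
    if (verbose) {
      message(sprintf("run %d epoch %3d: train %.5f val %.5f",
                      run_id, ep, tr_loss / n, val_loss))
    }
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_pl <- pl
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(model = cnn_param_restore(model, best_pl),
       best_val_loss = best_val, best_epoch = best_epoch,
       epochs_run = ep, history = dplyr::bind_rows(hist))
}

#' Select the ROC operating point by maximising Se + Sp
#'
#' Scans the finite candidate set of observed scores (plus 0 and 1) for
#' the decision threshold maximising sensitivity plus specificity on
#' the validation scores. The decision rule is `shock iff pSh >=
#' threshold`. Ties in Se + Sp are broken toward higher sensitivity
#' (the smallest tied threshold).
#'
#' @param scores Validation shock probabilities.
#' @param labels Shock categories (`"Sh"`/`"NSh"`), logical, or 0/1
#'   indicators, parallel to `scores`.
#' @return A list of class `operating_point` with `threshold`, `se`,
#'   `sp` and `criterion` (= Se + Sp).
#' @examples
#' select_operating_point(c(0.2, 0.8), c("NSh", "Sh"))
#' @export
select_operating_point <- function(scores, labels) {
  delta <- as_shock_indicator(labels)
  if (length(scores) != length(delta)) {
    abort("`scores` and `labels` must have the same length",
          class = "cprshock_error_length_mismatch")
  }
  if (all(delta == 1) || all(delta == 0)) {
    abort("both classes must be present to choose an operating point",
          class = "cprshock_error_bad_input")
  }
  cand <- sort(unique(c(0, scores, 1)))
  sh <- sort(scores[delta == 1])
  nsh <- sort(scores[delta == 0])
  # Se(theta) = P(sh score >= theta); Sp(theta) = P(nsh score < theta)
  se <- 1 - findInterval(cand - 1e-12, sh) / length(sh)
  sp <- findInterval(cand - 1e-12, nsh) / length(nsh)
  crit <- se + sp
  # float-tolerant argmax; candidates ascending so ties resolve to the
  # smallest threshold (the highest-sensitivity operating point)
  best <- which(crit > max(crit) - 1e-9)[1]
  structure(list(threshold = cand[best], se = se[best], sp = sp[best],
                 criterion = crit[best]),
            class = "operating_point")
}

as_shock_indicator <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (all(labels %in% c("Sh", "NSh"))) return(as.numeric(labels == "Sh"))
  check_rhythm_class(labels)
  as.numeric(shock_category(labels) == "Sh")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.4f: Se %.3f + Sp %.3f = %.3f\n",
              x$threshold, x$se, x$sp, x$criterion))
  invisible(x)
}

#' Sliding shock advice for one period of interest
#'
#' Applies the trained model at each of the 26 decision times, reporting
#' sHOT, the shock probability and the thresholded decision.
#'
#' @param fit A `cnn_cpr_fit` (or a bare `cnn_cpr` model plus explicit
#'   `threshold`).
#' @param poi A `cpr_poi`.
#' @param threshold Decision threshold on `pSh`; defaults to the fitted
#'   operating point.
#' @return Tibble with 26 rows: `poi_id`, `decision_time`, `shot`,
#'   `p_sh`, `decision` (`"Sh"`/`"NSh"`).
#' @export
predict_sliding <- function(fit, poi, threshold = NULL) {
  model <- if (inherits(fit, "cnn_cpr_fit")) fit$model else fit
  stopifnot(inherits(model, "cnn_cpr"), inherits(poi, "cpr_poi"))
  if (is.null(threshold)) {
    if (!inherits(fit, "cnn_cpr_fit")) {
      abort("`threshold` is required when `fit` is a bare model",
            class = "cprshock_error_bad_input")
    }
    threshold <- fit$operating_point$threshold
  }
  D <- model$D
  grid <- decision_grid(D)
  X <- vapply(grid, function(t) extract_window(poi, t, D),
              numeric(round(D * poi$fs)))
  p <- cnn_predict(model, X)
  out <- shot_series(poi, D)
  out$p_sh <- p
  out$decision <- ifelse(p >= threshold, "Sh", "NSh")
  out
}

#' Sliding shock advice for a whole dataset split
#'
#' @param fit A `cnn_cpr_fit`.
#' @param dataset A `cpr_dataset`.
#' @param split Which split to evaluate (default `"test"`).
#' @param threshold Decision threshold; defaults to the fitted operating
#'   point.
#' @return Advice tibble: one row per (period, decision time) with
#'   `poi_id`, `label`, `category`, `decision_time`, `shot`, `p_sh`,
#'   `decision`.
#' @export
evaluate_sliding <- function(fit, dataset, split = "test", threshold = NULL) {
  stopifnot(inherits(fit, "cnn_cpr_fit"), inherits(dataset, "cpr_dataset"))
  if (is.null(threshold)) threshold <- fit$operating_point$threshold
  man <- dataset$manifest
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  if (nrow(man) == 0) {
    abort("no periods in the requested split",
          class = "cprshock_error_bad_input")
  }
  D <- fit$D
  ex <- expand_windows(man, D)
  X <- window_matrix(dataset, man$poi_id[order(man$poi_id)], D)
  # expand_windows sorts by poi_id then time; window_matrix follows suit
  p <- cnn_predict(fit$model, X)
  shots <- dplyr::bind_rows(
    lapply(man$poi_id[order(man$poi_id)],
           function(id) shot_series(dataset$pois[[id]], D))
  )
  out <- ex[, c("poi_id", "label", "category", "decision_time")]
  out$shot <- shots$shot
  out$p_sh <- p
  out$decision <- ifelse(p >= threshold, "Sh", "NSh")
  tibble::as_tibble(out)
}
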