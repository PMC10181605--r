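test_that("class weights follow prevalence and sum to one", {
  cw <- class_weights(409, 6763)
  expect_equal(round(cw[["w_sh"]], 3), 0.943)
  expect_equal(round(cw[["w_nsh"]], 3), 0.057)
  expect_equal(sum(cw), 1)
  expect_equal(unname(class_weights(5, 5)), c(0.5, 0.5))
  expect_equal(unname(class_weights(1, 3)), c(0.75, 0.25))
  expect_error(class_weights(0, 10), class = "cprshock_error_bad_input")
})

test_that("weighted cross-entropy matches hand-computed values", {
  # single shockable sample at p = 0.5 with w_Sh = 0.943
  expect_equal(weighted_bce(0.5, 1, 0.943, 0.057), 0.943 * log(2))
  # perfect predictions give zero loss (up to the clipping epsilon)
  expect_equal(weighted_bce(c(1, 0), c(1, 0), 0.943, 0.057), 0,
               tolerance = 1e-6)
  # equal weights halve the standard mean BCE
  set.seed(2)
  p <- runif(50, 0.05, 0.95)
  d <- rbinom(50, 1, 0.5)
  bce <- -mean(d * log(p) + (1 - d) * log(1 - p))
  expect_equal(weighted_bce(p, d, 0.5, 0.5), bce / 2)
  expect_error(weighted_bce(c(0.1, 0.2), 1),
               class = "cprshock_error_length_mismatch")
})

test_that("window expansion multiplies the learning set by 26", {
  m1 <- tibble::tibble(poi_id = "a", label = "VF")
  expect_equal(nrow(expand_windows(m1, 10)), 26)
  # the printed learning-database composition expands to 186,498 windows
  tab1 <- c(VF = 409, NSR = 175, ONR = 1976, ASYS = 4613)
  man <- tibble::tibble(
    poi_id = sprintf("p%05d", seq_len(sum(tab1))),
    label = rep(names(tab1), tab1)
  )
  ex <- expand_windows(man, 10)
  expect_equal(nrow(ex), 186498)
  cnt <- table(ex$label)
  expect_equal(unname(cnt[["VF"]]), 10634)
  expect_equal(unname(cnt[["NSR"]]), 4550)
  expect_equal(unname(cnt[["ONR"]]), 51376)
  expect_equal(unname(cnt[["ASYS"]]), 119938)
})

test_that("operating point equals the exhaustive Se+Sp maximum", {
  # separable toy: the smallest candidate attaining Se + Sp = 2
  op <- select_operating_point(c(0.2, 0.8), c("NSh", "Sh"))
  expect_equal(op$threshold, 0.8)
  expect_equal(op$criterion, 2)
  set.seed(31)
  for (rep in 1:20) {
    sc <- round(runif(20), 2)             # duplicates create ties
    dl <- rbinom(20, 1, 0.4)
    if (all(dl == dl[1])) dl[1] <- 1 - dl[1]
    op <- select_operating_point(sc, dl)
    bf <- op_oracle(sc, dl)
    expect_equal(op$criterion, bf$criterion)
    expect_equal(op$threshold, bf$threshold)
  }
  expect_error(select_operating_point(c(0.1, 0.9), c("Sh", "Sh")),
               class = "cprshock_error_bad_input")
})

test_that("training reduces the loss on a separable toy problem and is seed-stable", {
  # toy windows: class 1 = strong 5 Hz oscillation, class 0 = near-flat
  set.seed(5)
  N <- 625
  mk <- function(lab) {
    if (lab == 1) 400 * sin(2 * pi * 5 * seq_len(N) / 125 + runif(1, 0, 6)) +
      rnorm(N, 0, 30) else rnorm(N, 0, 30)
  }
  y <- rep(c(1, 0), each = 40)
  X <- vapply(y, mk, numeric(N))
  cfg <- train_config(epochs = 4, patience = 3, batch_size = 16,
                      runs = 1)
  r1 <- withr::with_seed(9, cprshock:::train_one_run(
    5, X, y, X, y, c(w_sh = 0.5, w_nsh = 0.5), cfg, fs = 125))
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  expect_lt(r1$best_val_loss, 0.35)       # well below the ln(2)/2 start
  r2 <- withr::with_seed(9, cprshock:::train_one_run(
    5, X, y, X, y, c(w_sh = 0.5, w_nsh = 0.5), cfg, fs = 125))
  expect_identical(r1$model$weights, r2$model$weights)
})

test_that("the minimum-validation-loss run is selected", {
  runs <- tibble::tibble(run = 1:2, best_val_loss = c(0.31, 0.27))
  expect_equal(runs$run[which.min(runs$best_val_loss)], 2)
  # end-to-end on a small dataset: selected flag matches the loss argmin
  ds <- tiny_dataset(24, seed = 44, class_mix = rich_mix)
  cfg <- train_config(epochs = 2, patience = 1, runs = 2, batch_size = 64)
  fit <- train_cnn(ds, D = 5, config = cfg, seed = 3)
  expect_equal(which(fit$runs$selected), which.min(fit$runs$best_val_loss))
  expect_equal(fit$config$batch_size, 64)
  expect_equal(nrow(fit$history), fit$runs$epochs_run[fit$runs$selected])
})

test_that("sliding prediction emits 26 thresholded advices per period", {
  ds <- tiny_dataset(20, seed = 55, class_mix = rich_mix)
  cfg <- train_config(epochs = 2, patience = 1, runs = 1, batch_size = 64)
  fit <- train_cnn(ds, D = 5, config = cfg, seed = 2)
  poi <- ds$pois[[1]]
  adv <- predict_sliding(fit, poi)
  expect_equal(nrow(adv), 26)
  expect_true(all(adv$decision %in% c("Sh", "NSh")))
  # degenerate thresholds flip every decision
  adv0 <- predict_sliding(fit, poi, threshold = 0)
  expect_true(all(adv0$decision == "Sh"))
  adv1 <- predict_sliding(fit, poi, threshold = 1 + 1e-9)
  expect_true(all(adv1$decision == "NSh"))
  # dataset-level evaluation: 26 rows per test period
  adv_all <- evaluate_sliding(fit, ds, split = "test")
  expect_equal(nrow(adv_all), 26 * sum(ds$manifest$split == "test"))
})

test_that("patient-wise validation split keeps windows of one patient together", {
  ds <- make_dataset(20, periods_per_patient = 2, seed = 66,
                     class_mix = rich_mix)
  cfg <- train_config(epochs = 2, patience = 1, runs = 1, batch_size = 64)
  fit <- train_cnn(ds, D = 5, config = cfg, seed = 4)
  val_patients <- unique(sub("_poi.*", "", fit$validation$poi_id))
  learn <- ds$manifest[ds$manifest$split == "learning", ]
  # every patient in validation contributes *all* their periods there
  for (p in val_patients) {
    expect_true(all(learn$poi_id[learn$patient_id == p] %in%
                      fit$validation$poi_id))
  }
})
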