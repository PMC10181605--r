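test_that("sensitivity and specificity follow their defining ratios", {
  expect_equal(unname(se_sp(10, 0, 10, 0)), c(1, 1))
  expect_equal(se_sp(9, 1, 0, 0)[["se"]], 0.9)
  expect_true(is.na(se_sp(9, 1, 0, 0)[["sp"]]))   # undefined, not zero
  expect_equal(unname(se_sp(92, 8, 188, 12)), c(0.92, 0.94))
  expect_error(se_sp(-1, 0, 1, 1), class = "cprshock_error_bad_input")
})

test_that("Wilson interval matches its closed form and boundary behaviour", {
  z <- qnorm(0.95)
  wilson <- function(s, n) {
    p <- s / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  for (case in list(c(9, 10), c(50, 200), c(1, 7))) {
    expect_equal(unname(ci_wilson(case[1], case[2])),
                 wilson(case[1], case[2]))
  }
  expect_equal(round(unname(ci_wilson(9, 10)), 3), c(0.652, 0.977))
  expect_equal(ci_wilson(10, 10)[["hi"]], 1)
  expect_equal(ci_wilson(0, 10)[["lo"]], 0)
  # interval contains the point estimate
  ci <- ci_wilson(37, 90)
  expect_lt(ci[["lo"]], 37 / 90)
  expect_gt(ci[["hi"]], 37 / 90)
})

test_that("sHOT binning maps values to the twelve ordered strata", {
  expect_equal(as.character(bin_shot(c(0, 0.5, 1, 1.001, 10, 10.2))),
               c("0", "(0-1]", "(0-1]", "(1-2]", "(9-10]", ">10"))
  expect_equal(levels(bin_shot(0)), shot_bin_levels())
  expect_length(shot_bin_levels(), 12)
  expect_error(bin_shot(-0.1), class = "cprshock_error_bad_input")
})

make_toy_advices <- function(n_per_class = 4, p_correct = 1) {
  set.seed(77)
  grid <- decision_grid(10)
  rows <- list()
  for (cl in rhythm_classes()) {
    for (i in seq_len(n_per_class)) {
      correct <- shock_category(cl)
      wrong <- setdiff(c("Sh", "NSh"), correct)
      dec <- ifelse(runif(26) < p_correct, correct, wrong)
      rows[[length(rows) + 1]] <- tibble::tibble(
        poi_id = paste0(cl, i), label = cl,
        category = shock_category(cl),
        decision_time = grid,
        shot = pmin(10, pmax(0, round(runif(26, 0, 11), 1))),
        decision = dec
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("performance by time yields one row per class and decision time", {
  adv <- make_toy_advices(p_correct = 1)
  pt <- performance_by_time(adv)
  expect_equal(nrow(pt), 26 * 4)
  expect_true(all(pt$estimate == 1))
  expect_true(all(pt$metric[pt$label == "VF"] == "Se"))
  expect_true(all(pt$metric[pt$label != "VF"] == "Sp"))
  # constant-shock classifier: Se rows 1, Sp rows 0
  adv$decision <- "Sh"
  pt0 <- performance_by_time(adv)
  expect_true(all(pt0$estimate[pt0$label == "VF"] == 1))
  expect_true(all(pt0$estimate[pt0$label != "VF"] == 0))
  # duplicated decision rejected
  expect_error(performance_by_time(rbind(adv, adv[1, ])),
               class = "cprshock_error_bad_input")
})

test_that("performance by sHOT pools all 26 decisions and reports empty bins", {
  adv <- make_toy_advices(p_correct = 0.8)
  ps <- performance_by_shot(adv)
  expect_equal(nrow(ps), 12 * 4)
  # conservation: per class, bin counts sum to 26 * periods
  tot <- tapply(ps$n, ps$label, sum)
  expect_true(all(tot == 26 * 4))
  # brute-force regrouping oracle
  for (cl in rhythm_classes()) {
    sub <- adv[adv$label == cl, ]
    key <- as.character(bin_shot(sub$shot))
    for (b in unique(key)) {
      ok <- if (shock_category(cl) == "Sh") "Sh" else "NSh"
      expect_equal(
        ps$estimate[ps$label == cl & as.character(ps$shot_bin) == b],
        mean(sub$decision[key == b] == ok)
      )
    }
  }
  # all decisions during continuous CC populate only the "0" bin
  adv0 <- make_toy_advices()
  adv0$shot <- 0
  ps0 <- performance_by_shot(adv0)
  expect_true(all(ps0$n[ps0$shot_bin == "0"] > 0))
  expect_true(all(ps0$n[ps0$shot_bin != "0"] == 0))
  expect_true(all(is.na(ps0$estimate[ps0$shot_bin != "0"])))
})

test_that("sHOT strata beyond the analysis duration stay empty for short windows", {
  tl <- poi_timeline(list(c(-30, -25)))   # compressions end early: max sHOT
  for (D in c(5, 10)) {
    shots <- vapply(decision_grid(D), function(t) compute_shot(tl, t, D),
                    numeric(1))
    bins <- bin_shot(shots)
    reachable <- shot_bin_levels()[seq_len(D + 1)]
    expect_true(all(as.character(bins) %in% reachable))
  }
})

test_that("ROC AUC equals the concordance statistic", {
  # hand-checkable separations
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  set.seed(88)
  for (rep in 1:10) {
    sc <- round(runif(12), 1)            # ties included
    dl <- rbinom(12, 1, 0.5)
    if (all(dl == dl[1])) dl[1] <- 1 - dl[1]
    expect_equal(roc_curve(sc, dl)$auc, auc_oracle(sc, dl))
  }
  # chance level for shuffled labels at larger n
  set.seed(89)
  sc <- runif(4000)
  dl <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_curve(sc, dl)$auc - 0.5), 0.05)
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)),
               class = "cprshock_error_bad_input")
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(90)
  sc <- runif(60)
  dl <- rbinom(60, 1, 0.4)
  ours <- roc_curve(sc, dl)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(dl, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("AED goal flags follow the class-specific thresholds", {
  expect_false(aha_check("VF", 0.878))
  expect_true(aha_check("VF", 0.901))
  expect_true(aha_check("VF", 0.90))     # boundary counts as passing
  expect_false(aha_check("ASYS", 0.906))
  expect_true(aha_check("ASYS", 0.969))
  expect_true(aha_check("NSR", 0.99))
  expect_false(aha_check("NSR", 0.978))
  expect_true(is.na(aha_check("ONR", NA)))
  expect_error(aha_check("XX", 0.5), class = "cprshock_error_bad_class")
})
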