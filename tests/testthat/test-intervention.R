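test_that("30:2 protocol structure holds in simulated interventions", {
  for (seed in 1:4) {
    iv <- build_intervention("ASYS", n_cycles = 2, seed = seed)
    ep <- iv$timeline$cc_episodes
    expect_equal(nrow(ep), 2)
    expect_true(all(ep$n_compressions == 30))
    # episode duration carries exactly 30 compressions at the drawn rate
    expect_equal(ep$stop - ep$start, rep(30 / iv$timeline$cc_rate * 60, 2),
                 tolerance = 1e-8)
    # insufflation pause between episodes within the configured range
    pause <- ep$start[2] - ep$stop[1]
    expect_gte(pause, 2)
    expect_lte(pause, 8)
    # the final 10 s analysis window is CC free
    a0 <- iv$timeline$aed_analysis_start
    expect_true(all(ep$stop <= a0))
    expect_gte(length(iv$record$ecg) / iv$record$fs, a0 + 10)
  }
})

test_that("mixing is additive: zero artefact reproduces the clean rhythm", {
  iv <- build_intervention("ASYS", cc_amplitude = 0, seed = 10)
  # with zero artefact gain the ECG must satisfy the pure-ASYS criterion
  expect_lte(max_pp_in_windows(iv$record$ecg, iv$record$fs, 4), 100)
  # impedance still shows compressions, flat in pauses
  t <- seq_along(iv$record$impedance) / iv$record$fs
  ep <- iv$timeline$cc_episodes
  inside <- t > ep$start[1] & t <= ep$stop[1]
  a0 <- iv$timeline$aed_analysis_start
  analysis <- t > a0
  expect_gt(stats::sd(iv$record$impedance[inside]), 0)
  expect_equal(stats::sd(iv$record$impedance[analysis]), 0)
})

test_that("period of interest extraction returns exactly 40 s on the relative clock", {
  iv <- build_intervention("VF", seed = 2)
  poi <- extract_poi(iv$record, iv$timeline)
  expect_length(poi$samples, 40 * 125)
  expect_equal(poi$timeline$aed_analysis_start, 0)
  expect_equal(poi$timeline$coverage, c(-30, 10))
  # extracted samples are the record samples of (a0 - 30, a0 + 10]
  fs <- iv$record$fs
  a0 <- iv$timeline$aed_analysis_start
  idx <- (round((a0 - 30) * fs) + 1):round((a0 + 10) * fs)
  expect_identical(poi$samples, iv$record$ecg[idx])
})

test_that("timeline intervals are shifted and clipped to the period", {
  rec <- cpr_record("r", rep(0, 170 * 125), fs = 125)
  tl <- cpr_timeline(
    cc_episodes = data.frame(start = c(100, 130), stop = c(118, 145)),
    aed_analysis_start = 150,
    rhythm_segments = data.frame(start = 0, stop = 170, class = "ONR"),
    cc_rate = 105, coverage = c(0, 170)
  )
  poi <- extract_poi(rec, tl)
  ep <- poi$timeline$cc_episodes
  # [100, 118) is entirely before -30 relative: dropped; [130, 145) -> [-20, -5)
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start, ep$stop), c(-20, -5))
  expect_equal(poi$label, "ONR")
})

test_that("insufficient anterior or posterior signal is rejected", {
  rec <- cpr_record("r", rep(0, 35 * 125), fs = 125)
  tl <- cpr_timeline(aed_analysis_start = 20, cc_rate = 110,
                     coverage = c(0, 35))
  expect_error(extract_poi(rec, tl), class = "cprshock_error_bad_input")
  tl2 <- cpr_timeline(aed_analysis_start = 31, cc_rate = 110,
                      coverage = c(0, 41))
  expect_error(extract_poi(rec, tl2), class = "cprshock_error_bad_input")
})

test_that("consistency accepts NSh-to-NSh transitions and rejects category changes", {
  mk <- function(segments) {
    iv <- build_intervention("ASYS", seed = 3)
    poi <- extract_poi(iv$record, iv$timeline)
    poi$timeline$rhythm_segments <- tibble::as_tibble(segments)
    poi$label <- label_last <- segments$class[nrow(segments)]
    poi
  }
  expect_true(check_consistency(mk(data.frame(
    start = -30, stop = 10, class = "ASYS"))))
  expect_true(check_consistency(mk(data.frame(
    start = c(-30, -10), stop = c(-10, 10), class = c("ONR", "ASYS")))))
  expect_false(check_consistency(mk(data.frame(
    start = c(-30, -5), stop = c(-5, 10), class = c("ASYS", "VF")))))
  expect_false(check_consistency(mk(data.frame(
    start = c(-30, 0), stop = c(0, 10), class = c("VF", "NSR")))))
  expect_error(check_consistency(mk(data.frame(
    start = c(-30, -5), stop = c(-10, 10), class = c("ASYS", "ASYS")))),
    class = "cprshock_error_segment_gap")
})

test_that("timeline invariants are enforced", {
  expect_error(
    cpr_timeline(cc_episodes = data.frame(start = c(0, 5), stop = c(6, 9)),
                 aed_analysis_start = 20, coverage = c(0, 30)),
    class = "cprshock_error_episode_overlap"
  )
  expect_error(
    cpr_timeline(cc_episodes = data.frame(start = 15, stop = 25),
                 aed_analysis_start = 20, coverage = c(0, 30)),
    class = "cprshock_error_bad_timeline"
  )
  expect_error(
    build_intervention("ASYS",
                       protocol = list(cc_per_cycle = 30,
                                       insufflation_pause = c(-1, 2))),
    class = "cprshock_error_bad_input"
  )
})
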