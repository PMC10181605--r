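test_that("decision grid covers [-15, 10] in 26 one-second steps", {
  for (D in c(5, 10, 15)) {
    g <- decision_grid(D)
    expect_length(g, 26)
    expect_equal(g[1], -15)
    expect_equal(g[26], 10)
    expect_true(all(diff(g) == 1))
  }
  # earliest D = 15 window exactly reaches the period start
  expect_equal(decision_grid(15)[1] - 15, -30)
  expect_error(decision_grid(7), class = "cprshock_error_bad_input")
})

test_that("window extraction returns D*fs samples ending at the decision time", {
  iv <- build_intervention("VF", seed = 6)
  poi <- extract_poi(iv$record, iv$timeline)
  expect_length(extract_window(poi, 0, 10), 1250)
  expect_length(extract_window(poi, -15, 5), 625)
  expect_length(extract_window(poi, 10, 15), 1875)
  # adjacent 5 s windows concatenate into the 10 s window
  w5a <- extract_window(poi, -15, 5)
  w5b <- extract_window(poi, -10, 5)
  expect_identical(c(w5a, w5b), extract_window(poi, -10, 10))
  # last sample of the (t-D, t] window is the sample at time t
  w <- extract_window(poi, 3, 10)
  expect_identical(w[1250], poi$samples[round((3 + 30) * 125)])
  expect_error(extract_window(poi, -16, 15), class = "cprshock_error_bad_input")
})

test_that("hands-off episodes qualify on full length strictly above 1 s", {
  # continuous CC: no episodes
  tl <- poi_timeline(list(c(-30, 10)))
  expect_equal(nrow(hot_episodes(tl)), 0)
  # a 0.8 s gap and an exactly 1.0 s gap do not qualify
  tl <- poi_timeline(list(c(-30, -10), c(-9.2, -5), c(-4, 10)))
  expect_equal(nrow(hot_episodes(tl)), 0)
  tl <- poi_timeline(list(c(-30, -10), c(-9, -5), c(-4, 10)))
  expect_equal(nrow(hot_episodes(tl)), 0)
  # 5 s insufflation and 10 s analysis-pause episodes
  tl <- poi_timeline(list(c(-30, -15), c(-10, 0)))
  ep <- hot_episodes(tl)
  expect_equal(ep$length, c(5, 10))
  expect_equal(ep$start, c(-15, 0))
})

test_that("sHOT matches the stated worked example and bounds", {
  # CC stops at -8 s and resumes at -3 s; window (-12, -2] of D = 10 -> 5 s
  tl <- poi_timeline(list(c(-30, -8), c(-3, 0)))
  expect_equal(compute_shot(tl, -2, 10), 5)
  # window fully inside a CC episode -> 0
  expect_equal(compute_shot(tl, -10, 5), 0)
  # no CC anywhere near the window -> sHOT = D
  tl2 <- poi_timeline(list(c(-30, -25)))
  for (D in c(5, 10, 15)) expect_equal(compute_shot(tl2, 10, D), D)
})

test_that("interval-arithmetic sHOT equals the per-sample mask oracle", {
  set.seed(404)
  n_cases <- 0
  for (rep in 1:60) {
    # randomized timeline: alternating CC/pause segments over (-30, 10]
    cur <- -30
    eps <- list()
    while (cur < 8) {
      on <- runif(1, 0.4, 12)
      if (runif(1) < 0.85) eps[[length(eps) + 1]] <- c(cur, min(cur + on, 8))
      cur <- cur + on + runif(1, 0.3, 6)
    }
    tl <- poi_timeline(eps)
    D <- sample(c(5, 10, 15), 1)
    for (t in sample(decision_grid(D), 6)) {
      n_cases <- n_cases + 1
      s <- compute_shot(tl, t, D)
      expect_lt(abs(s - shot_oracle(tl, t, D)), 2 / 125)
      expect_gte(s, 0)
      expect_lte(s, D)
    }
  }
  expect_gte(n_cases, 300)
})

test_that("sHOT grows by exactly 1 s per step after compressions cease", {
  # compressions stop permanently at -5 s
  tl <- poi_timeline(list(c(-30, -5)))
  for (D in c(5, 10, 15)) {
    shots <- vapply(decision_grid(D),
                    function(t) compute_shot(tl, t, D), numeric(1))
    grid <- decision_grid(D)
    growing <- grid > -4 & shots < D  # past c + 1 s, before saturation
    expect_true(all(abs(diff(shots)[growing[-1]] - 1) < 1e-9))
    expect_equal(max(shots), min(D, 15))  # saturates at D (15 s available)
  }
})

test_that("sHOT is timeline-driven only and invariant to signal content", {
  iv <- build_intervention("VF", seed = 12)
  poi <- extract_poi(iv$record, iv$timeline)
  s1 <- shot_series(poi, 10)
  poi$samples <- poi$samples * 0
  s2 <- shot_series(poi, 10)
  expect_identical(s1$shot, s2$shot)
})
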