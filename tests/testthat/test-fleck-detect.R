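# Windfleck detection: spectral conversion, turning points, thresholds,
# event metrics, and brute-force oracle agreement.

test_that("ppfd_from_spectrum evaluates the photon integral", {
  wl <- seq(280, 898, by = 2)
  expect_equal(ppfd_from_spectrum(wl, rep(0, length(wl))), 0)
  # flat 1 W m^-2 nm^-1 over 400-700 nm: integral of lambda/(h c N_A)
  flat <- ppfd_from_spectrum(wl, rep(1, length(wl)))
  h <- 6.62607015e-34; c0 <- 2.99792458e8; na <- 6.02214076e23
  analytic <- 1e6 * (700e-9^1 * 0) # placeholder to keep units explicit
  analytic <- 1e6 * ((700^2 - 400^2) / 2) * 1e-9 / (h * c0 * na)
  expect_equal(flat, analytic, tolerance = 1e-6)
  expect_equal(round(flat), 1379)
  # linearity
  expect_equal(ppfd_from_spectrum(wl, rep(2, length(wl))), 2 * flat)
  expect_error(ppfd_from_spectrum(450:700, rep(1, 251)), "cover 400-700")
})

test_that("find_turning_points alternates and applies the plateau rule", {
  expect_equal(nrow(find_turning_points(1:10)), 0)       # monotone
  tp <- find_turning_points(c(100, 200, 100))
  expect_equal(tp$index, 2); expect_equal(tp$type, "max")
  # plateau: single turning point at the first index of the run
  tp2 <- find_turning_points(c(100, 150, 150, 100))
  expect_equal(tp2$index, 2); expect_equal(tp2$type, "max")
  expect_error(find_turning_points(c(1, 2)), "at least 3")

  set.seed(8)
  for (rep in 1:20) {
    x <- round(cumsum(rnorm(60)), 1)
    tp <- find_turning_points(x)
    if (nrow(tp) > 1) # strict min/max alternation
      expect_true(all(tp$type[-1] != tp$type[-nrow(tp)]))
  }
})

test_that("detector resolves a clean triangular pulse exactly", {
  s <- triangle_series(baseline = 100, height = 100, half_n = 10)
  ev <- detect_windflecks(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.2)
  expect_equal(ev$intensity, 100)
  expect_equal(ev$baseline, 100)
  expect_equal(ev$integrated_increase, 10)  # triangle area 100 * 0.2 / 2

  # constant series and sub-threshold ripple yield nothing
  expect_equal(nrow(detect_windflecks(wfl_series(0:99 / 100, rep(100, 100),
                                                 100))), 0)
  tt <- (0:999) / 100
  ripple <- wfl_series(tt, 100 + 1.5 * sin(2 * pi * 5 * tt), 100)
  expect_equal(nrow(detect_windflecks(ripple)), 0)
})

test_that("every retained event passes both amplitude criteria", {
  s <- random_walk_series(n = 2000, seed = 10, step_sd = 3)
  ev <- detect_windflecks(s)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$intensity >= 5))
  expect_true(all(ev$intensity >= 0.05 * ev$baseline))
  expect_true(all(ev$start_s < ev$peak_s & ev$peak_s < ev$end_s))
  expect_true(all(ev$integrated_increase >= 0))
})

test_that("raising either threshold never increases the event count", {
  for (seed in c(2, 4, 6)) {
    s <- random_walk_series(n = 1500, seed = seed, step_sd = 3)
    n0 <- nrow(detect_windflecks(s, 0.05, 5))
    expect_lte(nrow(detect_windflecks(s, 0.10, 5)), n0)
    expect_lte(nrow(detect_windflecks(s, 0.05, 10)), n0)
  }
})

test_that("events are scale-covariant when both thresholds scale", {
  s <- random_walk_series(n = 1500, seed = 12, step_sd = 3)
  ev <- detect_windflecks(s, 0.05, 5)
  s2 <- wfl_series(s$time, 3.7 * s$value, attr(s, "rate"))
  ev2 <- detect_windflecks(s2, 0.05, 3.7 * 5)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$start_s, ev$start_s)
  expect_equal(ev2$duration_s, ev$duration_s)
  expect_equal(ev2$intensity, 3.7 * ev$intensity)
  expect_equal(ev2$integrated_increase, 3.7 * ev$integrated_increase)
})

test_that("detector agrees event-for-event with the brute-force oracle", {
  for (seed in 1:60) {
    s <- random_walk_series(n = 500, seed = 100 + seed, step_sd = 2)
    ev <- detect_windflecks(s)
    orc <- oracle_detect(s$time, s$value)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(ev)) {
      expect_equal(ev$start_s, orc$start_s)
      expect_equal(ev$peak_s, orc$peak_s)
      expect_equal(ev$end_s, orc$end_s)
      expect_equal(ev$baseline, orc$baseline)
      expect_equal(ev$intensity, orc$intensity)
    }
  }
})

test_that("records with gaps are split and other irregularity is rejected", {
  s <- triangle_series()
  # cut a gap of 5 sample intervals into the flat region after the pulse
  keep <- c(1:250, 256:301)
  gappy <- wfl_series(s$time[keep], s$value[keep], 100)
  ev <- detect_windflecks(gappy)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.2)

  bad <- wfl_series(c(0, 0.01, 0.0225, 0.03, 0.04), rep(c(1, 2), length.out = 5),
                    100)
  expect_error(detect_windflecks(bad), "uniform")
})

test_that("integrated_increase matches geometry and quadrature", {
  s <- triangle_series(baseline = 50, height = 80, half_n = 15)
  ev <- detect_windflecks(s)
  # triangle area: 80 * 0.3 / 2
  expect_equal(integrated_increase(ev[1, ], s), 12)

  # interior equal to the chord: zero excess
  ramp <- wfl_series((0:100) / 100, seq(10, 20, length.out = 101), 100)
  expect_equal(integrated_increase(list(start_s = 0.1, end_s = 0.9), ramp), 0)

  # sampled sine half-wave vs brute-force quadrature of the interpolant
  tt <- (0:400) / 100
  v <- rep(20, 401)
  win <- tt >= 1 & tt <= 3
  v[win] <- 20 + 50 * sin(pi * (tt[win] - 1) / 2)
  s3 <- wfl_series(tt, v, 100)
  got <- integrated_increase(list(start_s = 1, end_s = 3), s3)
  # brute-force quadrature of the linear interpolant on a refined grid that
  # contains every sample knot (exact for a piecewise-linear integrand)
  fine <- sort(unique(c(seq(1, 3, by = 1e-4), tt[win])))
  quad <- pracma::trapz(fine, approx(tt, v, xout = fine)$y - 20)
  expect_equal(got, quad, tolerance = 1e-6)
  # and close to the analytic (2/pi) * A * w for the continuous half-wave
  expect_equal(got, (2 / pi) * 50 * 2, tolerance = 1e-3)
})

test_that("summarize_flecks reports frequencies and inter-fleck gaps", {
  ev0 <- detect_windflecks(wfl_series((0:999) / 100, rep(5, 1000), 100))
  s0 <- summarize_flecks(ev0, total_time = 100)
  expect_equal(s0$frequency, 0)
  expect_true(is.na(s0$mean_time_between))

  ev2 <- data.frame(start_s = c(1, 4), end_s = c(2.5, 5))
  s2 <- summarize_flecks(ev2, total_time = 10)
  expect_equal(s2$frequency, 0.2)
  expect_equal(s2$frequency_per_100s, 20)
  expect_equal(s2$mean_time_between, 1.5)
  expect_error(summarize_flecks(ev2, total_time = 0), "positive")
})

test_that("sparse strong events from gen_ppfd are recovered one for one", {
  w <- gen_wind(wind_model_params(seed = 53), 120)
  m <- gen_motion(w, motion_model_params(seed = 54))
  # sparse events (low rate gain), amplitudes far above both thresholds,
  # narrow spread, and no sensor noise
  sim <- gen_ppfd(m, fleck_model_params(rate_gain = 30,
                                        amplitude_dist = c(log(150), 0.1),
                                        sensor_noise_sd = 0, seed = 55))
  ne <- nrow(sim$events)
  expect_gt(ne, 5)
  # fixture precondition: events must not overlap (overlaps would merge)
  expect_equal(sum(sim$events$start_s[-1] < sim$events$end_s[-ne]), 0)
  ev <- detect_windflecks(sim$series)
  expect_equal(nrow(ev), ne)
})
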