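# Trait formulas, binning schemes, class-conditional frequencies, cultivar
# indices, and the variance decomposition.

test_that("natural_frequency is three over the oscillation time", {
  expect_equal(natural_frequency(3), 1)
  expect_equal(natural_frequency(c(1.5, 6)), c(2, 0.5))
  expect_error(natural_frequency(0), "positive")
})

test_that("allometry computes LMA, HM and LTM with the LTM guard", {
  a <- allometry(tiller_height = 80, total_mass = 10, leaf_mass = 2,
                 leaf_area = 100)
  expect_equal(a$LMA, 0.02)
  expect_equal(a$HM, 8)
  expect_equal(allometry(80, 12.5, 2.5, 100)$LTM, 0.25)
  expect_warning(bad <- allometry(80, 2, 2.5, 100), "LTM")
  expect_true(is.na(bad$LTM))
  expect_false(is.na(bad$LMA))
  expect_error(allometry(80, 10, 2, 0), "leaf_area")
})

test_that("class edges follow the linear and exponential schemes", {
  we <- wind_class_edges(2.4)
  expect_equal(we[1:3], c(0, 0.3, 0.6))
  expect_true(all(abs(diff(we) - 0.3) < 1e-12))

  qe <- qom_class_edges()
  expect_length(qe, 16)
  expect_equal(qe[1], exp(-11))
  expect_equal(qe[16], exp(-2))
  ratios <- qe[-1] / qe[-16]
  expect_lt(diff(range(ratios)), 1e-12)
})

test_that("bin_series assigns half-open classes and accumulates time", {
  b <- bin_series(c(0.45, 0.3, 0.299999, 0), wind_class_edges(1.2), rate = 100)
  expect_equal(b$class, c(2L, 2L, 1L, 1L))  # [0.3, 0.6) contains both 0.45 and 0.3

  # QOM of exactly zero is outside the exponential classes
  bq <- bin_series(c(0, 0.001, 1), qom_class_edges(), rate = 100)
  expect_true(is.na(bq$class[1]))
  expect_false(is.na(bq$class[2]))
  expect_true(is.na(bq$class[3]))  # at/above the last edge

  # a uniform series spends the whole record in its class
  u <- bin_series(rep(0.45, 300), wind_class_edges(1.2), rate = 100)
  expect_equal(sum(u$time_in_class), 3)
  expect_equal(u$time_in_class[2], 3)
  expect_error(bin_series(1:3, c(1, 1, 2), rate = 1), "increasing")
})

test_that("frequency_by_class divides counts by time and masks singletons", {
  f <- frequency_by_class(rep(1L, 10), time_in_class = c(5, 2))
  expect_equal(f$frequency[1], 2)
  f2 <- frequency_by_class(c(1L, 1L, 2L), time_in_class = c(5, 2))
  expect_true(is.na(f2$frequency[2]))  # one event: not reported
  expect_equal(f2$count[2], 1)         # but still counted

  # conservation: assigned counts plus outside events equal the total
  cls <- c(1L, NA, 2L, 2L, NA, 1L, 3L)
  f3 <- frequency_by_class(cls, time_in_class = c(1, 1, 1))
  expect_equal(sum(f3$count) + sum(is.na(cls)), length(cls))
  expect_error(frequency_by_class(c(1L, 1L), time_in_class = c(0, 1)),
               "zero time")
})

test_that("cultivar_indices z-scales both axes with a degenerate-SD guard", {
  d <- data.frame(cultivar = c("a", "b", "c"),
                  mean_qom = c(0.001, 0.002, 0.003),
                  mean_wind = c(1, 1, 1),
                  fleck_frequency = c(1, 1, 1))
  ix <- cultivar_indices(d)
  expect_equal(ix$motion_sensitivity, c(0.001, 0.002, 0.003))
  expect_equal(ix$motion_sensitivity_z, c(-1, 0, 1))
  expect_equal(mean(ix$light_modulation_efficiency_z), 0, tolerance = 1e-12)

  two <- cultivar_indices(data.frame(cultivar = c("a", "b"),
                                     mean_qom = c(2, 2), mean_wind = c(1, 1),
                                     fleck_frequency = c(3, 3)))
  expect_equal(two$motion_sensitivity_z, c(0, 0))  # SD 0 guard
  expect_error(cultivar_indices(d[1, ]), "at least 2")
  d$mean_wind[1] <- 0
  expect_error(cultivar_indices(d), "positive")
})

test_that("a cultivar with stronger wind-motion gain scores higher", {
  panel <- lapply(c(A = 0.6, B = 1.2), function(gain) {
    w <- gen_wind(wind_model_params(seed = 81), 120)
    m <- gen_motion(w, motion_model_params(wind_gain = gain, seed = 82))
    sim <- gen_ppfd(m, fleck_model_params(seed = 83))
    ev <- detect_windflecks(sim$series)
    c(mean_qom = mean(m$value), mean_wind = mean(w$value),
      fleck_frequency = summarize_flecks(ev)$frequency)
  })
  d <- cbind(data.frame(cultivar = names(panel)),
             as.data.frame(do.call(rbind, panel)))
  ix <- cultivar_indices(d)
  expect_gt(ix$motion_sensitivity_z[ix$cultivar == "B"],
            ix$motion_sensitivity_z[ix$cultivar == "A"])
})

test_that("variance_decomposition reproduces hand-computed limits", {
  # identical values across blocks within variety, variety means differing
  d1 <- data.frame(cultivar = rep(c("a", "b", "c"), each = 3),
                   block = rep(1:3, 3),
                   value = rep(c(10, 12, 14), each = 3))
  v1 <- variance_decomposition(d1)
  expect_equal(v1$H2, 1)
  expect_equal(v1$sigma2_r, 0)
  expect_equal(v1$sigma2_V, 4)

  # all variety means equal: nothing heritable
  d2 <- data.frame(cultivar = rep(c("a", "b", "c"), each = 3),
                   block = rep(1:3, 3),
                   value = rep(c(1, 2, 3), times = 3))
  expect_equal(variance_decomposition(d2)$H2, 0)

  # variety means {10, 12, 14} with pooled within-variance 1:
  # sigma2_V = 4 - 1/3, H2 = (11/3) / 4 = 11/12
  dev <- c(-1, 0, 1)  # pooled sample variance: sum(dev^2)*3 / (3*(3-1)) = 1
  d3 <- data.frame(cultivar = rep(c("a", "b", "c"), each = 3),
                   block = rep(1:3, 3),
                   value = rep(c(10, 12, 14), each = 3) + rep(dev, 3))
  v3 <- variance_decomposition(d3)
  expect_equal(v3$sigma2_r, 1)
  expect_equal(v3$H2, 11 / 12)
  expect_error(variance_decomposition(d3[d3$cultivar == "a", ]),
               "at least 2")
})

test_that("H2 is bounded, shift-invariant and scale-invariant", {
  for (seed in c(91, 92, 93)) {
    d <- gen_trait_table(trait_sim_params(seed = seed))
    v <- variance_decomposition(d)
    expect_gte(v$H2, 0); expect_lte(v$H2, 1)
    expect_gte(v$repeatability, 0); expect_lte(v$repeatability, 1)

    d_shift <- transform(d, value = value + 1000)
    d_scale <- transform(d, value = value * 7)
    expect_equal(variance_decomposition(d_shift)$H2, v$H2)
    expect_equal(variance_decomposition(d_scale)$H2, v$H2)
    expect_equal(variance_decomposition(d_scale)$sigma2_V, 49 * v$sigma2_V)
  }
})

test_that("heritability() evaluates the component-ratio formula", {
  expect_equal(heritability(4, 1, 3), 4 / (4 + 1 / 3))
  expect_equal(heritability(0, 2, 3), 0)
  expect_equal(heritability(2, 0, 3), 1)
  expect_equal(heritability(0, 0, 3), 0)
  expect_error(heritability(-1, 1, 3), "non-negative")
})

test_that("technical replicates are averaged before decomposition", {
  d <- data.frame(cultivar = rep(c("a", "b"), each = 6),
                  block = rep(rep(1:2, each = 3), 2),
                  value = c(9, 10, 11, 12, 13, 14, 19, 20, 21, 22, 23, 24))
  v <- variance_decomposition(d)
  # cell means: a = (10, 13), b = (20, 23) -> variety means 11.5, 21.5
  expect_equal(v$sigma2_r, (1.5^2 * 4) / 2)
  expect_equal(v$sigma2_V, var(c(11.5, 21.5)) - v$sigma2_r / 2)
})
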