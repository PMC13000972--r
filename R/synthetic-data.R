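#' Parameters for the synthetic wind generator
#'
#' Wind is modelled as a mean-reverting AR(1) process with superimposed
#' Poisson gusts (exponentially decaying pulses), clipped at zero. The paper
#' trail for field wind records only gives an observed range (roughly 0.3-2.1
#' m s^-1), so the defaults are chosen to cover 0-2.4 m s^-1 with gusty
#' clustering rather than to reproduce any particular site.
#'
#' @param mean_speed Long-run mean wind speed (m s^-1).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`; larger values give
#'   slower eddies.
#' @param gust_rate Expected gust arrivals per second.
#' @param gust_amplitude Mean gust amplitude (m s^-1); amplitudes are drawn
#'   exponentially and decay with a 3 s time constant.
#' @param noise_sd Innovation standard deviation of the AR(1) component
#'   (m s^-1).
#' @param seed Integer seed; every generator is a pure function of its seed.
#' @return A `wfl_wind_params` list.
#' @export
wind_model_params <- function(mean_speed = 1.0, ar_coefficient = 0.8,
                              gust_rate = 0.05, gust_amplitude = 0.6,
                              noise_sd = 0.15, seed = 1L) {
  stopifnot(mean_speed >= 0, noise_sd >= 0, gust_rate >= 0,
            gust_amplitude >= 0)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("`ar_coefficient` must be in [0, 1)", call. = FALSE)
  structure(list(mean_speed = mean_speed, ar_coefficient = ar_coefficient,
                 gust_rate = gust_rate, gust_amplitude = gust_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "wfl_wind_params")
}

#' Generate a synthetic wind-speed record
#'
#' @param params A [wind_model_params()] object.
#' @param duration Record length in seconds (>= 1).
#' @return A [wfl_series()] at 1 s^-1 with `floor(duration)` non-negative
#'   samples; identical seeds give bit-identical records.
#' @export
gen_wind <- function(params, duration) {
  stopifnot(inherits(params, "wfl_wind_params"))
  if (!is.numeric(duration) || duration < 1)
    stop("`duration` must be at least 1 s", call. = FALSE)
  n <- floor(duration)
  p <- params
  tau <- 3  # gust decay time constant, s
  v <- withr::with_seed(p$seed, {
    if (p$noise_sd > 0) {
      e <- stats::rnorm(n, 0, p$noise_sd)
      x0 <- stats::rnorm(1, 0, p$noise_sd / sqrt(1 - p$ar_coefficient^2))
      x <- as.numeric(stats::filter(e, p$ar_coefficient,
                                    method = "recursive",
                                    init = x0))
    } else x <- numeric(n)
    g <- numeric(n)
    if (p$gust_rate > 0 && p$gust_amplitude > 0) {
      n_g <- stats::rpois(1, p$gust_rate * n)
      if (n_g > 0) {
        t0 <- sort(stats::runif(n_g, 0, n))
        amp <- stats::rexp(n_g, rate = 1 / p$gust_amplitude)
        tt <- seq_len(n) - 1
        for (i in seq_len(n_g)) {
          j <- tt >= t0[i]
          g[j] <- g[j] + amp[i] * exp(-(tt[j] - t0[i]) / tau)
        }
      }
    }
    comp <- p$gust_rate * p$gust_amplitude * tau
    pmax(p$mean_speed + x + g - comp, 0)
  })
  wfl_series(seq_len(n) - 1, v, rate = 1)
}

#' Parameters for the synthetic motion generator
#'
#' Canopy motion responds exponentially to wind speed, as observed across most
#' wheat cultivars: QOM(t) = a * exp(b * wind(t - lag)), corrupted by a
#' mean-preserving lognormal multiplier with coefficient of variation
#' `noise_cv` (keeping QOM strictly positive).
#'
#' @param base_motion Motionless-air QOM level `a` (QOM units, > 0).
#' @param wind_gain Exponential gain `b` per m s^-1.
#' @param lag Mechanical response lag in seconds.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @export
motion_model_params <- function(base_motion = 0.0015, wind_gain = 1.0,
                                lag = 0.2, noise_cv = 0.3, seed = 1L) {
  stopifnot(base_motion > 0, noise_cv >= 0)
  structure(list(base_motion = base_motion, wind_gain = wind_gain,
                 lag = lag, noise_cv = noise_cv, seed = as.integer(seed)),
            class = "wfl_motion_params")
}

#' Generate a synthetic quantity-of-motion record from a wind record
#'
#' The wind record is extended by zero-order hold (the same convention the
#' synchronization stage uses), delayed by the mechanical `lag`, and mapped
#' through the exponential wind-motion response.
#'
#' @param wind A [wfl_series()] wind record (nominally 1 s^-1).
#' @param params A [motion_model_params()] object.
#' @param rate Output sampling rate, nominally 30 s^-1 (video frame rate).
#' @return A [wfl_series()] of strictly positive QOM values with attribute
#'   `true_lag` (seconds).
#' @export
gen_motion <- function(wind, params, rate = 30) {
  stopifnot(inherits(params, "wfl_motion_params"))
  wind <- as_wfl_series(wind)
  if (nrow(wind) == 0L) stop("`wind` must be non-empty", call. = FALSE)
  wind_rate <- series_rate(wind)
  duration <- nrow(wind) / wind_rate
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  idx <- floor((t - params$lag) * wind_rate) + 1L
  if (any(idx > nrow(wind)))
    stop("negative `lag` reaches beyond the end of the wind record",
         call. = FALSE)
  idx <- pmax(idx, 1L)
  w <- wind$value[idx]
  qom <- params$base_motion * exp(params$wind_gain * w)
  if (params$noise_cv > 0) {
    sdlog <- sqrt(log1p(params$noise_cv^2))
    mult <- withr::with_seed(params$seed,
                             exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)))
    qom <- qom * mult
  }
  out <- wfl_series(t, qom, rate)
  attr(out, "true_lag") <- params$lag
  out
}

#' Parameters for the synthetic windfleck-bearing PPFD generator
#'
#' Windflecks arrive as an inhomogeneous point process whose instantaneous
#' rate is proportional to the quantity of motion; each event superimposes a
#' triangular pulse (analytically convenient: duration, intensity and
#' integrated increase all have closed forms) on a constant shaded baseline.
#' Default pulse durations are lognormal with a 95% interval of about
#' 0.05-0.44 s, matching the regime of field-measured windflecks.
#'
#' @param baseline_ppfd Shade baseline (umol m^-2 s^-1, > 0).
#' @param rate_gain Event rate per unit QOM (flecks s^-1 per QOM unit).
#' @param amplitude_dist `c(meanlog, sdlog)` of lognormal pulse amplitudes
#'   (umol m^-2 s^-1).
#' @param duration_dist `c(meanlog, sdlog)` of lognormal pulse base durations
#'   (s).
#' @param sensor_noise_sd Gaussian sensor noise SD (umol m^-2 s^-1).
#' @param seed Integer seed.
#' @export
fleck_model_params <- function(baseline_ppfd = 200, rate_gain = 350,
                               amplitude_dist = c(log(120), 0.6),
                               duration_dist = c(log(0.148), 0.555),
                               sensor_noise_sd = 1.5, seed = 1L) {
  stopifnot(baseline_ppfd > 0, rate_gain >= 0, sensor_noise_sd >= 0,
            length(amplitude_dist) == 2, length(duration_dist) == 2,
            amplitude_dist[2] >= 0, duration_dist[2] >= 0)
  structure(list(baseline_ppfd = baseline_ppfd, rate_gain = rate_gain,
                 amplitude_dist = amplitude_dist,
                 duration_dist = duration_dist,
                 sensor_noise_sd = sensor_noise_sd, seed = as.integer(seed)),
            class = "wfl_fleck_params")
}

#' Generate a synthetic PPFD record with known windfleck ground truth
#'
#' @param motion A [wfl_series()] QOM record (nominally 30 s^-1).
#' @param params A [fleck_model_params()] object.
#' @param rate Output sampling rate, nominally 100 s^-1.
#' @return List with `series` (a [wfl_series()] of PPFD at `rate`) and
#'   `events`, a data frame of true events (`start_s`, `peak_s`, `end_s`,
#'   `amplitude`, `duration_s`) sorted by start time. Pulses are centred on
#'   the drawn event time so the event process adds no systematic lag
#'   relative to motion.
#' @export
gen_ppfd <- function(motion, params, rate = 100) {
  stopifnot(inherits(params, "wfl_fleck_params"))
  motion <- as_wfl_series(motion)
  if (nrow(motion) == 0L) stop("`motion` must be non-empty", call. = FALSE)
  m_rate <- series_rate(motion)
  duration <- nrow(motion) / m_rate
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  qom <- stats::approx(motion$time, motion$value, xout = t, rule = 2)$y
  p <- params
  res <- withr::with_seed(p$seed, {
    prob <- pmin(p$rate_gain * qom / rate, 1)
    hit <- which(stats::runif(n) < prob)
    k <- length(hit)
    amp <- dur <- numeric(0)
    if (k > 0) {
      amp <- stats::rlnorm(k, p$amplitude_dist[1], p$amplitude_dist[2])
      dur <- stats::rlnorm(k, p$duration_dist[1], p$duration_dist[2])
    }
    noise <- if (p$sensor_noise_sd > 0) stats::rnorm(n, 0, p$sensor_noise_sd)
             else numeric(n)
    list(hit = hit, amp = amp, dur = dur, noise = noise)
  })
  ppfd <- rep(p$baseline_ppfd, n) + res$noise
  k <- length(res$hit)
  tp <- t[res$hit]
  for (i in seq_len(k)) {
    half <- res$dur[i] / 2
    j0 <- max(1L, ceiling((tp[i] - half) * rate) + 1L)
    j1 <- min(n, floor((tp[i] + half) * rate) + 1L)
    if (j1 >= j0) {
      jj <- j0:j1
      ppfd[jj] <- ppfd[jj] + res$amp[i] * pmax(1 - abs(t[jj] - tp[i]) / half, 0)
    }
  }
  events <- data.frame(start_s = tp - res$dur / 2, peak_s = tp,
                       end_s = tp + res$dur / 2, amplitude = res$amp,
                       duration_s = res$dur)
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  list(series = wfl_series(t, pmax(ppfd, 0), rate), events = events)
}

#' Generate a synthetic video frame sequence tracking a motion signal
#'
#' A smooth, horizontally periodic texture fills the interior of each frame
#' and is displaced frame-to-frame by an amount proportional to the motion
#' signal (sub-pixel displacements are exact because the texture is a finite
#' sum of sinusoids). A static textured border surrounds the interior and is
#' suitable for reference zones. All channel values lie in `[0, 1]`.
#'
#' @param motion A [wfl_series()] motion record; `length(motion) + 1` frames
#'   are produced and the displacement between frames `i` and `i + 1` is
#'   `displacement_gain * motion$value[i]` pixels.
#' @param image_size `c(height, width)` in pixels, each >= 32.
#' @param texture_scale Characteristic texture length in pixels; must be
#'   smaller than the image dimensions.
#' @param seed Integer seed.
#' @param displacement_gain Pixels of displacement per QOM unit.
#' @param border Static border width in pixels.
#' @return A [frame_sequence()] at the motion record's rate.
#' @export
gen_frames <- function(motion, image_size = c(64, 64), texture_scale = 8,
                       seed = 1L, displacement_gain = 300, border = 8) {
  motion <- as_wfl_series(motion)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (H < 32L || W < 32L)
    stop("`image_size` must be at least 32 x 32", call. = FALSE)
  if (texture_scale >= min(H, W))
    stop("`texture_scale` must be smaller than the image dimensions",
         call. = FALSE)
  rate <- series_rate(motion, 30)
  n_frames <- nrow(motion) + 1L
  rows <- (border + 1L):(H - border)
  cols <- (border + 1L):(W - border)
  Hi <- length(rows); Wi <- length(cols)

  K <- 40L
  tex <- withr::with_seed(seed, {
    list(
      base = array(stats::runif(H * W * 3, 0.2, 0.8), dim = c(H, W, 3)),
      kx = matrix(sample(seq_len(max(1L, floor(Wi / texture_scale))),
                         K * 3, replace = TRUE), K, 3),
      ky = matrix(sample(0:max(1L, floor(Hi / texture_scale)),
                         K * 3, replace = TRUE), K, 3),
      phase = matrix(stats::runif(K * 3, 0, 2 * pi), K, 3),
      amp = matrix(stats::runif(K * 3, 0.5, 1), K, 3)
    )
  })
  # normalize each channel so the summed field maps into [0.05, 0.95]
  amp <- sweep(tex$amp, 2, colSums(tex$amp), "/") * 0.45

  field <- function(shift, ch) {
    f <- matrix(0, Hi, Wi)
    for (k in seq_len(K)) {
      ph_col <- 2 * pi * tex$kx[k, ch] * ((cols + shift) / Wi)
      ph_row <- 2 * pi * tex$ky[k, ch] * (rows / Hi)
      f <- f + amp[k, ch] * sin(outer(ph_row, ph_col, "+") + tex$phase[k, ch])
    }
    0.5 + f
  }

  pos <- c(0, cumsum(displacement_gain * motion$value))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- tex$base
    for (ch in 1:3) fr[rows, cols, ch] <- field(pos[i], ch)
    frames[[i]] <- pmin(pmax(fr, 0), 1)
  }
  frame_sequence(frames, rate = rate)
}

#' Parameters for the synthetic trait-table generator
#'
#' Trait values follow the additive randomized-block model
#' `value = grand_mean + variety + block + residual` with independent normal
#' effects, so the true broad-sense heritability
#' `H2 = var_variety / (var_variety + var_residual / n_blocks)` is known.
#'
#' @param n_varieties,n_blocks Design size (each >= 2).
#' @param grand_mean Trait grand mean.
#' @param var_variety,var_block,var_residual Variance components (>= 0).
#' @param seed Integer seed.
#' @export
trait_sim_params <- function(n_varieties = 10, n_blocks = 3, grand_mean = 100,
                             var_variety = 4, var_block = 1,
                             var_residual = 1, seed = 1L) {
  if (any(c(var_variety, var_block, var_residual) < 0))
    stop("variance components must be non-negative", call. = FALSE)
  stopifnot(n_varieties >= 2, n_blocks >= 2)
  structure(list(n_varieties = as.integer(n_varieties),
                 n_blocks = as.integer(n_blocks), grand_mean = grand_mean,
                 var_variety = var_variety, var_block = var_block,
                 var_residual = var_residual, seed = as.integer(seed)),
            class = "wfl_trait_params")
}

#' Generate a synthetic trait table with known variance components
#'
#' @param params A [trait_sim_params()] object.
#' @return Data frame with one row per variety x block (`cultivar`, `block`,
#'   `value`) and attributes `true_H2` and `true_effects`.
#' @export
gen_trait_table <- function(params) {
  stopifnot(inherits(params, "wfl_trait_params"))
  p <- params
  d <- expand.grid(cultivar = sprintf("V%02d", seq_len(p$n_varieties)),
                   block = sprintf("B%d", seq_len(p$n_blocks)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff <- withr::with_seed(p$seed, list(
    variety = stats::rnorm(p$n_varieties, 0, sqrt(p$var_variety)),
    block = stats::rnorm(p$n_blocks, 0, sqrt(p$var_block)),
    resid = stats::rnorm(nrow(d), 0, sqrt(p$var_residual))
  ))
  vi <- as.integer(factor(d$cultivar))
  bi <- as.integer(factor(d$block))
  d$value <- p$grand_mean + eff$variety[vi] + eff$block[bi] + eff$resid
  attr(d, "true_H2") <- heritability(p$var_variety, p$var_residual,
                                     p$n_blocks)
  attr(d, "true_effects") <- eff
  d
}
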