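#' Resample a series to a higher rate by linear interpolation
#'
#' Used to bring the 30 s^-1 quantity-of-motion record onto the 100 s^-1 clock
#' of the irradiance record. Values are linearly interpolated at the new
#' timestamps; beyond the original record the end values are held.
#'
#' @param series A [wfl_series()], data frame, or numeric vector.
#' @param from_rate Original sampling rate (samples s^-1); taken from the
#'   series attribute when omitted.
#' @param to_rate Target sampling rate, default 100 s^-1.
#' @return A [wfl_series()] sampled at `to_rate` spanning the original window.
#' @export
resample_linear <- function(series, from_rate = NULL, to_rate = 100) {
  s <- as_wfl_series(series, from_rate)
  from_rate <- series_rate(s, from_rate)
  if (from_rate > to_rate)
    stop("`from_rate` must not exceed `to_rate`", call. = FALSE)
  if (nrow(s) < 2L)
    stop("need at least 2 samples to interpolate", call. = FALSE)
  t_new <- seq(s$time[1], s$time[nrow(s)], by = 1 / to_rate)
  v <- stats::approx(s$time, s$value, xout = t_new, rule = 2)$y
  wfl_series(t_new, v, to_rate)
}

#' Resample a series to a higher rate by step extension
#'
#' Each original value is repeated without interpolation, stamped from the
#' start of its sampling interval. This mirrors how a 1 s^-1 wind record is
#' extended to the common 100 s^-1 clock (giving the familiar bar-like trace).
#'
#' @inheritParams resample_linear
#' @return A [wfl_series()] at `to_rate`; taking every
#'   `to_rate/from_rate`-th sample recovers the input.
#' @export
resample_step <- function(series, from_rate = 1, to_rate = 100) {
  s <- as_wfl_series(series, from_rate)
  from_rate <- series_rate(s, from_rate)
  k <- to_rate / from_rate
  if (abs(k - round(k)) > 1e-9)
    stop("`from_rate` must divide `to_rate`", call. = FALSE)
  k <- as.integer(round(k))
  v <- rep(s$value, each = k)
  t0 <- if (nrow(s)) s$time[1] else 0
  t_new <- t0 + (seq_along(v) - 1L) / to_rate
  wfl_series(t_new, v, to_rate)
}

#' Lagged Pearson cross-correlation of two equal-length series
#'
#' Computes the Pearson correlation of the overlapping segments of `a` and `b`
#' at every integer lag in `[-max_lag, max_lag]`. A positive lag means `b` is
#' delayed relative to `a`: if `b` reproduces `a` shifted right by `k` samples,
#' the correlation peaks at lag `k`. Lags whose overlap has zero variance in
#' either segment are reported as `NA`.
#'
#' The sufficient statistics (lagged cross-products and running sums) are
#' computed with an FFT and prefix sums, so the cost is
#' O(n log n + max_lag) rather than O(n * max_lag).
#'
#' @param a,b Numeric vectors or [wfl_series()] of equal length
#'   (at least `2 * max_lag + 2`).
#' @param max_lag Maximum lag in samples (default 500, i.e. 5 s at 100 s^-1).
#' @return An object of class `wfl_xcorr`: list with `lag` (samples, signed),
#'   `value` (correlations in `[-1, 1]`), and `max_lag`.
#' @export
cross_correlation <- function(a, b, max_lag = 500) {
  a <- if (inherits(a, "wfl_series") || is.data.frame(a)) as_wfl_series(a)$value else as.numeric(a)
  b <- if (inherits(b, "wfl_series") || is.data.frame(b)) as_wfl_series(b)$value else as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("`a` and `b` must have equal length", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0) stop("`max_lag` must be non-negative", call. = FALSE)
  if (n < 2L * max_lag + 2L)
    stop("series too short for requested `max_lag`", call. = FALSE)

  # lagged cross-products via zero-padded FFT (linear, not circular)
  N <- stats::nextn(n + max_lag + 1L)
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / N

  A1 <- cumsum(a); A2 <- cumsum(a^2)
  B1 <- cumsum(b); B2 <- cumsum(b^2)
  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(k) {
    if (k >= 0) {
      m <- n - k
      sxy <- cc[k + 1L]
      sa <- A1[m];        sa2 <- A2[m]
      sb <- B1[n] - if (k) B1[k] else 0
      sb2 <- B2[n] - if (k) B2[k] else 0
    } else {
      j <- -k
      m <- n - j
      sxy <- cc[N - j + 1L]
      sa <- A1[n] - A1[j]; sa2 <- A2[n] - A2[j]
      sb <- B1[m];         sb2 <- B2[m]
    }
    va <- sa2 - sa^2 / m
    vb <- sb2 - sb^2 / m
    scale_a <- max(sa2, 1)
    scale_b <- max(sb2, 1)
    if (va <= 1e-12 * scale_a || vb <= 1e-12 * scale_b) return(NA_real_)
    (sxy - sa * sb / m) / sqrt(va * vb)
  }, numeric(1))
  vals <- pmin(pmax(vals, -1), 1)
  structure(list(lag = lags, value = vals, max_lag = max_lag),
            class = "wfl_xcorr")
}

#' @export
print.wfl_xcorr <- function(x, ...) {
  i <- which.max(abs(x$value))
  cat(sprintf("<wfl_xcorr> lags %d..%d; peak |r| = %.3f at lag %d\n",
              -x$max_lag, x$max_lag, abs(x$value[i]), x$lag[i]))
  invisible(x)
}

#' @export
plot.wfl_xcorr <- function(x, ..., xlab = "lag (samples)",
                           ylab = "Pearson r", type = "l") {
  graphics::plot(x$lag, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Select the analysis zone by cross-correlation with the PPFD record
#'
#' Among a caller-supplied set of candidate zones (geometric proximity to the
#' light diffuser is resolved upstream by the user), returns the zone whose
#' interpolated QOM series has the largest absolute cross-correlation with the
#' PPFD series at any lag. Ties are broken by the lexicographically lowest
#' zone id.
#'
#' @param ppfd Numeric vector or [wfl_series()] at the common rate.
#' @param qom_by_zone Named list of numeric vectors (or a matrix with named
#'   columns), one per zone, each the same length as `ppfd`.
#' @param candidate_zones Character or integer ids naming entries of
#'   `qom_by_zone`.
#' @param max_lag Maximum lag in samples passed to [cross_correlation()].
#' @return List with `zone` (the selected id), `xcorr` (its `wfl_xcorr`), and
#'   `score` (the peak absolute correlation).
#' @export
select_zone <- function(ppfd, qom_by_zone, candidate_zones, max_lag = 500) {
  if (is.matrix(qom_by_zone))
    qom_by_zone <- stats::setNames(
      lapply(seq_len(ncol(qom_by_zone)), function(j) qom_by_zone[, j]),
      colnames(qom_by_zone))
  if (length(candidate_zones) == 0L)
    stop("`candidate_zones` must be non-empty", call. = FALSE)
  candidate_zones <- as.character(candidate_zones)
  missing_z <- setdiff(candidate_zones, names(qom_by_zone))
  if (length(missing_z))
    stop("unknown zone id(s): ", paste(missing_z, collapse = ", "),
         call. = FALSE)
  candidate_zones <- sort(candidate_zones)
  best <- NULL
  for (z in candidate_zones) {
    xc <- cross_correlation(ppfd, qom_by_zone[[z]], max_lag)
    sc <- suppressWarnings(max(abs(xc$value), na.rm = TRUE))
    if (!is.finite(sc)) sc <- -Inf
    if (is.null(best) || sc > best$score)
      best <- list(zone = z, xcorr = xc, score = sc)
  }
  best
}

#' Estimate the wind-record clock shift from two cross-correlations
#'
#' The shift between the wind record and the (already mutually aligned) PPFD
#' and QOM records is taken as the lag maximizing the product of the
#' PPFD-wind and QOM-wind cross-correlations, restricted to lags where the
#' QOM-wind correlation is positive (more wind producing less motion is
#' physically implausible and such lags are ignored).
#'
#' @param xc_ppfd_wind,xc_qom_wind `wfl_xcorr` objects on the same lag grid.
#' @return The estimated lag in samples (positive: wind delayed). Errors with
#'   condition class `wfl_no_valid_shift` when the QOM-wind correlation is
#'   nowhere positive.
#' @export
estimate_wind_shift <- function(xc_ppfd_wind, xc_qom_wind) {
  if (!identical(xc_ppfd_wind$lag, xc_qom_wind$lag))
    stop("cross-correlations are on different lag grids", call. = FALSE)
  ok <- !is.na(xc_qom_wind$value) & xc_qom_wind$value > 0 &
    !is.na(xc_ppfd_wind$value)
  if (!any(ok))
    stop(structure(
      class = c("wfl_no_valid_shift", "error", "condition"),
      list(message = "no lag with positive QOM-wind correlation; cannot estimate shift",
           call = sys.call(-1))))
  prod <- xc_ppfd_wind$value * xc_qom_wind$value
  prod[!ok] <- -Inf
  xc_qom_wind$lag[which.max(prod)]
}
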