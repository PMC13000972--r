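#' Convert spectral irradiance to PPFD
#'
#' Photosynthetic photon flux density is the photon irradiance integrated over
#' 400-700 nm: `PPFD = 1e6 * integral( E(lambda) * lambda / (h c N_A) )` with
#' the trapezoidal rule on the native wavelength grid (the integration range
#' is cut at exactly 400 and 700 nm, interpolating the end values).
#'
#' @param wavelength Wavelengths in nm, strictly increasing, covering
#'   400-700 nm.
#' @param irradiance Spectral irradiance in W m^-2 nm^-1 at `wavelength`.
#' @return PPFD in umol m^-2 s^-1.
#' @examples
#' # a flat 1 W m^-2 nm^-1 spectrum over 400-700 nm gives ~1379 umol m^-2 s^-1
#' ppfd_from_spectrum(seq(350, 750, by = 1), rep(1, 401))
#' @export
ppfd_from_spectrum <- function(wavelength, irradiance) {
  if (length(wavelength) != length(irradiance))
    stop("`wavelength` and `irradiance` must have equal length", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("`wavelength` must be strictly increasing", call. = FALSE)
  if (min(wavelength) > 400 + 1e-9 || max(wavelength) < 700 - 1e-9)
    stop("wavelength grid must cover 400-700 nm", call. = FALSE)
  grid <- sort(unique(c(400, 700, wavelength[wavelength >= 400 & wavelength <= 700])))
  e <- stats::approx(wavelength, irradiance, xout = grid)$y
  h <- 6.62607015e-34; c0 <- 2.99792458e8; n_a <- 6.02214076e23
  photons <- e * grid * 1e-9 / (h * c0 * n_a)  # mol m^-2 s^-1 nm^-1
  1e6 * pracma::trapz(grid, photons)
}

# --- turning points -------------------------------------------------------

# collapse a series into runs of equal consecutive values and classify
# direction changes; boundary runs are included as pseudo-extrema so events
# truncated by the record ends can still be delimited. Returns parallel
# vectors (kept atomic: the pruning loop deletes entries repeatedly).
extrema_runs <- function(values) {
  r <- rle(values)
  m <- length(r$values)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  if (m < 2L)
    return(list(type = character(0), first = integer(0),
                last = integer(0), value = numeric(0)))
  dirs <- sign(diff(r$values))  # never zero between runs
  type <- character(m)
  type[1] <- if (dirs[1] > 0) "min" else "max"
  type[m] <- if (dirs[m - 1] > 0) "max" else "min"
  keep <- rep(TRUE, m)
  if (m > 2L) {
    interior <- 2:(m - 1L)
    turning <- dirs[interior - 1L] != dirs[interior]
    keep[interior] <- turning
    type[interior][turning] <-
      ifelse(dirs[interior - 1L][turning] > 0, "max", "min")
  }
  list(type = type[keep], first = first[keep], last = last[keep],
       value = r$values[keep])
}

#' Locate the turning points of a series
#'
#' Indices where the rate of change (first difference) crosses zero, i.e.
#' where the series switches from increasing to decreasing or vice versa.
#' Runs of equal values (plateaus) contribute a single turning point placed at
#' the first index of the run. The result strictly alternates between minima
#' and maxima; a monotone series has no interior turning points.
#'
#' @param series A [wfl_series()], data frame, or numeric vector of length
#'   >= 3.
#' @return Data frame with `index` (1-based position in the series) and
#'   `type` (`"min"`/`"max"`).
#' @export
find_turning_points <- function(series) {
  x <- if (is.numeric(series)) as.numeric(series) else as_wfl_series(series)$value
  if (length(x) < 3L) stop("series must have at least 3 samples", call. = FALSE)
  e <- extrema_runs(x)
  # interior turning points only: drop the boundary pseudo-extrema
  keep <- e$first > 1L & e$last < length(x)
  data.frame(index = e$first[keep], type = e$type[keep],
             stringsAsFactors = FALSE)
}

# --- event pruning --------------------------------------------------------

# amplitude test for one adjacent extremum pair; baseline is the min-side
# value. A transition fails when its rise is below the absolute threshold or
# below the relative threshold times the baseline.
transition_fails <- function(v_lo, amp, rel, abs_th) {
  amp < abs_th | amp < rel * v_lo
}

# iterative smallest-first pruning of sub-threshold oscillations on an
# alternating extrema table (columns type/first/last/value): while any
# adjacent transition fails, delete the smallest-amplitude failing pair so
# its neighbours merge into a single transition, then recompute. Deleting the
# smaller side of a noise dip first keeps the enveloping extremum, and
# removing one min-max pair preserves strict alternation.
prune_extrema <- function(e, rel, abs_th) {
  repeat {
    m <- length(e$value)
    if (m < 2L) return(e)
    amp <- abs(diff(e$value))
    lo <- pmin(e$value[-m], e$value[-1])
    fails <- transition_fails(lo, amp, rel, abs_th)
    if (!any(fails)) return(e)
    j <- which(fails)[which.min(amp[fails])]
    keep <- -c(j, j + 1L)
    e <- list(type = e$type[keep], first = e$first[keep],
              last = e$last[keep], value = e$value[keep])
  }
}

# detect events on one gap-free segment; returns a data.frame of row indices
segment_events <- function(values, rel, abs_th) {
  e <- prune_extrema(extrema_runs(values), rel, abs_th)
  m <- length(e$value)
  i <- if (m >= 3L) which(e$type == "max" & seq_len(m) > 1L & seq_len(m) < m)
       else integer(0)
  data.frame(
    start = e$last[i - 1L],   # last sample of the left minimum plateau
    peak = e$first[i],
    end = e$first[i + 1L],    # first sample of the right minimum plateau
    baseline = e$value[i - 1L],
    peak_value = e$value[i])
}

# trapezoidal integral of (series - chord) over [i0, i1], clipped at zero
excess_integral <- function(time, values, i0, i1) {
  idx <- i0:i1
  chord <- values[i0] + (values[i1] - values[i0]) *
    (time[idx] - time[i0]) / (time[i1] - time[i0])
  max(pracma::trapz(time[idx], values[idx] - chord), 0)
}

#' Detect windflecks in a high-frequency PPFD series
#'
#' Candidate events are (minimum, maximum, next minimum) triples of turning
#' points. Oscillations whose rise fails either amplitude criterion — an
#' increase of less than `abs_threshold` umol m^-2 s^-1 or less than
#' `rel_threshold` times the event baseline — are eliminated by iterative
#' smallest-first pruning with neighbour merging, so every retained windfleck
#' passes both criteria. The event baseline is the PPFD at the start turning
#' point and the intensity is peak minus baseline.
#'
#' Records with gaps of two or more sample intervals are split at the gaps
#' and processed per segment; any other deviation from uniform sampling is an
#' error.
#'
#' @param series A [wfl_series()] (nominally 100 s^-1 PPFD), data frame, or
#'   numeric vector (then sampled at `rate`).
#' @param rel_threshold Relative amplitude threshold (default 0.05, i.e. 5%
#'   of the baseline).
#' @param abs_threshold Absolute amplitude threshold
#'   (default 5 umol m^-2 s^-1).
#' @param rate Sampling rate, needed only for bare numeric input.
#' @return An object of classes `wfl_events`/`data.frame`, one row per event:
#'   `start_s`, `peak_s`, `end_s`, `baseline`, `peak_ppfd`, `intensity`,
#'   `duration_s`, `integrated_increase` (umol m^-2, area between the trace
#'   and the start-end chord, clipped at zero). Attribute `total_time` holds
#'   the record length in seconds.
#' @export
detect_windflecks <- function(series, rel_threshold = 0.05,
                              abs_threshold = 5, rate = NULL) {
  if (rel_threshold < 0 || abs_threshold < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  s <- as_wfl_series(series, rate)
  time <- s$time; values <- s$value
  n <- length(values)
  empty <- structure(
    data.frame(start_s = numeric(0), peak_s = numeric(0), end_s = numeric(0),
               baseline = numeric(0), peak_ppfd = numeric(0),
               intensity = numeric(0), duration_s = numeric(0),
               integrated_increase = numeric(0)),
    total_time = if (n > 1) time[n] - time[1] + diff(time)[1] else 0,
    class = c("wfl_events", "data.frame"))
  if (n < 3L) return(empty)

  d <- diff(time)
  dt <- min(d)
  steps <- d / dt
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("series is not uniformly sampled", call. = FALSE)
  breaks <- which(round(steps) >= 2)  # gaps of >= 2 sample intervals
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, n)

  rows <- list()
  for (k in seq_along(seg_start)) {
    i0 <- seg_start[k]; i1 <- seg_end[k]
    if (i1 - i0 + 1L < 3L) next
    v <- values[i0:i1]
    ev <- segment_events(v, rel_threshold, abs_threshold)
    if (!nrow(ev)) next
    ev[c("start", "peak", "end")] <- ev[c("start", "peak", "end")] + i0 - 1L
    rows[[length(rows) + 1L]] <- ev
  }
  if (!length(rows)) return(empty)
  ev <- do.call(rbind, rows)
  out <- data.frame(
    start_s = time[ev$start],
    peak_s = time[ev$peak],
    end_s = time[ev$end],
    baseline = ev$baseline,
    peak_ppfd = ev$peak_value,
    intensity = ev$peak_value - ev$baseline,
    duration_s = time[ev$end] - time[ev$start],
    integrated_increase = vapply(seq_len(nrow(ev)), function(i)
      excess_integral(time, values, ev$start[i], ev$end[i]), numeric(1)))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total_time = time[n] - time[1] + dt,
            class = c("wfl_events", "data.frame"))
}

#' @export
print.wfl_events <- function(x, ...) {
  cat(sprintf("<wfl_events> %d windflecks over %.2f s\n", nrow(x),
              attr(x, "total_time")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Integrated PPFD increase of one windfleck
#'
#' The trapezoidal integral of the PPFD trace between the event start and end
#' minus the integral of the straight line joining the start and end points,
#' clipped at zero.
#'
#' @param event One-row data frame (or list) with `start_s` and `end_s`.
#' @param series The PPFD series the event was detected in.
#' @param rate Sampling rate for bare numeric input.
#' @return Integrated increase in umol m^-2.
#' @export
integrated_increase <- function(event, series, rate = NULL) {
  s <- as_wfl_series(series, rate)
  i0 <- which.min(abs(s$time - event$start_s))
  i1 <- which.min(abs(s$time - event$end_s))
  if (abs(s$time[i0] - event$start_s) > 1e-6 ||
      abs(s$time[i1] - event$end_s) > 1e-6)
    stop("event boundaries do not lie on the series grid", call. = FALSE)
  if (i1 <= i0) stop("event end must follow its start", call. = FALSE)
  excess_integral(s$time, s$value, i0, i1)
}

#' Summarize a set of windfleck events
#'
#' @param events A `wfl_events` data frame (or any data frame with `start_s`
#'   and `end_s`).
#' @param total_time Record length in seconds (> 0); defaults to the
#'   `total_time` attribute of `events`.
#' @return A `wfl_fleck_summary` list: `n_events`, `total_time`, `frequency`
#'   (s^-1), `frequency_per_100s` (the units of field summary tables), and
#'   `mean_time_between` (s, the mean gap between one event's end and the
#'   next one's start; `NA` with fewer than 2 events).
#' @export
summarize_flecks <- function(events, total_time = attr(events, "total_time")) {
  if (is.null(total_time) || !is.numeric(total_time) || total_time <= 0)
    stop("`total_time` must be positive", call. = FALSE)
  n <- nrow(events)
  mtb <- if (n >= 2L) {
    o <- order(events$start_s)
    mean(events$start_s[o][-1] - events$end_s[o][-n])
  } else NA_real_
  structure(list(n_events = n, total_time = total_time,
                 frequency = n / total_time,
                 frequency_per_100s = 100 * n / total_time,
                 mean_time_between = mtb),
            class = "wfl_fleck_summary")
}

#' @export
print.wfl_fleck_summary <- function(x, ...) {
  cat(sprintf(paste0("<wfl_fleck_summary> %d events in %.1f s: ",
                     "%.3f s^-1 (%.1f per 100 s), mean gap %s s\n"),
              x$n_events, x$total_time, x$frequency, x$frequency_per_100s,
              if (is.na(x$mean_time_between)) "NA"
              else sprintf("%.3f", x$mean_time_between)))
  invisible(x)
}
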