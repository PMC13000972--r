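#' Natural frequency of a tiller from its oscillation time
#'
#' A displaced-and-released tiller is timed over three full oscillations; the
#' natural frequency is the reciprocal of one oscillation period,
#' `N = 3 / T`.
#'
#' @param oscillation_time Time `T` in seconds for three oscillations (> 0);
#'   vectorized.
#' @return Natural frequency in s^-1.
#' @export
natural_frequency <- function(oscillation_time) {
  if (any(!is.finite(oscillation_time)) || any(oscillation_time <= 0))
    stop("`oscillation_time` must be positive", call. = FALSE)
  3 / oscillation_time
}

#' Leaf and tiller allometry ratios
#'
#' Computes leaf mass per area `LMA = LM / LA` (g cm^-2), the height-to-mass
#' ratio `HM = H / TM` (cm g^-1), and the leaf-to-stem mass ratio
#' `LTM = LM / (TM - LM)` (g g^-1). Rows with `TM <= LM` get `NA` for LTM
#' (with a warning); LMA and HM are still returned.
#'
#' @param tiller_height Tiller height `H` in cm.
#' @param total_mass Total above-ground dry mass `TM` in g (> 0).
#' @param leaf_mass Leaf dry mass `LM` in g.
#' @param leaf_area Total leaf area `LA` in cm^2 (> 0).
#' @return Data frame with columns `LMA`, `HM`, `LTM`.
#' @export
allometry <- function(tiller_height, total_mass, leaf_mass, leaf_area) {
  if (any(leaf_area <= 0)) stop("`leaf_area` must be positive", call. = FALSE)
  if (any(total_mass <= 0)) stop("`total_mass` must be positive", call. = FALSE)
  ltm <- leaf_mass / (total_mass - leaf_mass)
  bad <- total_mass <= leaf_mass
  if (any(bad)) {
    warning("total mass <= leaf mass for ", sum(bad),
            " record(s); LTM set to NA", call. = FALSE)
    ltm[bad] <- NA_real_
  }
  data.frame(LMA = leaf_mass / leaf_area,
             HM = tiller_height / total_mass,
             LTM = ltm)
}

#' Broad-sense heritability from variance components
#'
#' `H2 = sigma2_V / (sigma2_V + sigma2_r / n)`: the variance among variety
#' means over that variance plus the residual variance scaled by the number
#' of biological replicates (averaging across replicates shrinks the
#' environmental contribution).
#'
#' @param sigma2_V Variance among variety means (>= 0).
#' @param sigma2_r Residual variance (>= 0).
#' @param n_blocks Number of biological replicates (blocks).
#' @return Heritability in `[0, 1]` (0 when both components are zero).
#' @export
heritability <- function(sigma2_V, sigma2_r, n_blocks) {
  if (any(sigma2_V < 0) || any(sigma2_r < 0))
    stop("variance components must be non-negative", call. = FALSE)
  denom <- sigma2_V + sigma2_r / n_blocks
  ifelse(denom > 0, sigma2_V / denom, 0)
}

#' Class edges for wind-speed and QOM binning
#'
#' Wind speeds are grouped in linear classes of 0.3 m s^-1 starting at zero;
#' quantities of motion in 15 exponentially growing classes whose 16 edges
#' run from `exp(-11)` (~1.67e-5) to `exp(-2)` (~0.135), equalizing the
#' number of observations across the heavily right-skewed QOM scale.
#'
#' @param max_speed Largest wind speed the edges must cover (m s^-1).
#' @param step Class width, default 0.3 m s^-1.
#' @return Numeric vector of strictly increasing class edges; classes are
#'   half-open `[lo, hi)`.
#' @export
wind_class_edges <- function(max_speed = 2.4, step = 0.3) {
  seq(0, step * ceiling(max_speed / step + 1e-9), by = step)
}

#' @param log_range Range of the exponent, default `c(-11, -2)`.
#' @param n_classes Number of classes, default 15 (hence 16 edges).
#' @rdname wind_class_edges
#' @export
qom_class_edges <- function(log_range = c(-11, -2), n_classes = 15) {
  exp(seq(log_range[1], log_range[2], length.out = n_classes + 1))
}

#' Assign series samples to half-open classes and accumulate time in class
#'
#' Each sample is assigned to the class `[edges[k], edges[k+1])` containing
#' it, or to "outside" (`NA`) when below the first or at/above the last edge;
#' a QOM of exactly zero therefore falls outside the exponential classes.
#' Time in class is the sample count times the sampling interval.
#'
#' @param series A [wfl_series()] or numeric vector.
#' @param edges Strictly increasing class edges.
#' @param rate Sampling rate for bare numeric input.
#' @return A `wfl_binning` list: `class` (integer per sample, `NA` outside),
#'   `n_classes`, `edges`, `time_in_class` (seconds per class), `dt`.
#' @export
bin_series <- function(series, edges, rate = NULL) {
  if (any(diff(edges) <= 0))
    stop("`edges` must be strictly increasing", call. = FALSE)
  s <- as_wfl_series(series, rate)
  dt <- 1 / series_rate(s, rate)
  k <- findInterval(s$value, edges)
  k[k < 1L | k >= length(edges)] <- NA_integer_
  nc <- length(edges) - 1L
  structure(list(class = k, n_classes = nc, edges = edges,
                 time_in_class = tabulate(k, nbins = nc) * dt, dt = dt),
            class = "wfl_binning")
}

#' @export
print.wfl_binning <- function(x, ...) {
  cat(sprintf("<wfl_binning> %d classes; %d of %d samples assigned (%.1f s)\n",
              x$n_classes, sum(!is.na(x$class)), length(x$class),
              sum(x$time_in_class)))
  invisible(x)
}

#' Assign windfleck events to classes of a synchronized series
#'
#' A windfleck is assigned the class of the mean synchronized series value
#' (wind speed or QOM) over its start-end interval, which is robust to
#' sample-level jitter in the event boundaries.
#'
#' @param events A `wfl_events` data frame.
#' @param series The synchronized driver series (same clock as the PPFD the
#'   events came from).
#' @param edges Class edges as in [bin_series()].
#' @param rate Sampling rate for bare numeric input.
#' @return Integer class per event (`NA` when the mean falls outside).
#' @export
assign_event_class <- function(events, series, edges, rate = NULL) {
  s <- as_wfl_series(series, rate)
  if (!nrow(events)) return(integer(0))
  mv <- vapply(seq_len(nrow(events)), function(i) {
    j <- s$time >= events$start_s[i] & s$time <= events$end_s[i]
    if (!any(j)) return(NA_real_)
    mean(s$value[j])
  }, numeric(1))
  k <- findInterval(mv, edges)
  k[is.na(mv) | k < 1L | k >= length(edges)] <- NA_integer_
  k
}

#' Windfleck frequency per driver class
#'
#' The frequency in each class is the number of events assigned to the class
#' divided by the time the synchronized driver spent in that class. Classes
#' with fewer than `min_events` events are reported as missing (`NA`), as one
#' event gives no meaningful rate estimate.
#'
#' @param event_classes Integer class per event (from
#'   [assign_event_class()]); `NA` counts as outside.
#' @param time_in_class Seconds per class (from [bin_series()]).
#' @param min_events Minimum events for a class to be reported (default 2).
#' @param edges Optional class edges, echoed into the output.
#' @return Data frame with one row per class: `class`, `lo`, `hi`, `count`,
#'   `time_s`, `frequency` (s^-1).
#' @export
frequency_by_class <- function(event_classes, time_in_class, min_events = 2,
                               edges = NULL) {
  nc <- length(time_in_class)
  counts <- tabulate(event_classes[!is.na(event_classes)], nbins = nc)
  if (any(counts > 0 & time_in_class <= 0))
    stop("events assigned to a class with zero time in class", call. = FALSE)
  freq <- ifelse(time_in_class > 0, counts / time_in_class, NA_real_)
  freq[counts < min_events] <- NA_real_
  out <- data.frame(class = seq_len(nc), count = counts,
                    time_s = time_in_class, frequency = freq)
  if (!is.null(edges)) {
    out$lo <- edges[seq_len(nc)]
    out$hi <- edges[seq_len(nc) + 1L]
    out <- out[c("class", "lo", "hi", "count", "time_s", "frequency")]
  }
  out
}

#' Cultivar-level motion and light-modulation indices
#'
#' Motion sensitivity is the ratio of a cultivar's mean QOM to its mean wind
#' speed (its propensity to move per unit wind); light modulation efficiency
#' is the ratio of windfleck frequency to mean QOM (its ability to turn
#' motion into light fluctuations). Both axes are centred and scaled across
#' the cultivar set, so 0 is the panel average and 1 is one SD above it. A
#' degenerate axis (zero SD) reports 0 for every cultivar.
#'
#' @param cultivars Data frame with columns `cultivar`, `mean_qom`,
#'   `mean_wind`, `fleck_frequency` (one row per cultivar, >= 2 rows,
#'   positive means).
#' @return Data frame with the raw ratios (`motion_sensitivity`,
#'   `light_modulation_efficiency`) and their z-scaled versions (`*_z`).
#' @export
cultivar_indices <- function(cultivars) {
  need <- c("cultivar", "mean_qom", "mean_wind", "fleck_frequency")
  if (!all(need %in% names(cultivars)))
    stop("`cultivars` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(cultivars) < 2L) stop("need at least 2 cultivars", call. = FALSE)
  if (any(cultivars$mean_qom <= 0) || any(cultivars$mean_wind <= 0))
    stop("mean QOM and mean wind must be positive", call. = FALSE)
  zscale <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  ms <- cultivars$mean_qom / cultivars$mean_wind
  lme <- cultivars$fleck_frequency / cultivars$mean_qom
  data.frame(cultivar = cultivars$cultivar,
             motion_sensitivity = ms,
             light_modulation_efficiency = lme,
             motion_sensitivity_z = zscale(ms),
             light_modulation_efficiency_z = zscale(lme))
}

#' Variance decomposition, repeatability and broad-sense heritability
#'
#' Technical replicates are first averaged to variety x block cell means.
#' The residual variance `sigma2_r` is the pooled variance of cell means
#' about their variety mean; the variance among variety means is corrected
#' for the residual contribution of averaging over blocks,
#' `sigma2_V = max(var(variety means) - sigma2_r / n_blocks, 0)`
#' (method of moments), so that `H2 = sigma2_V / (sigma2_V + sigma2_r / n)`
#' recovers the true ratio in expectation. The block variance component is
#' the variance of block means corrected by `sigma2_r / n_varieties`, floored
#' at zero; repeatability is the proportion of total variance explained by
#' blocks.
#'
#' @param data Data frame with one row per observation.
#' @param value,variety,block Column names (defaults `"value"`, `"cultivar"`,
#'   `"block"`).
#' @return A `wfl_vardecomp` list: `sigma2_V`, `sigma2_r`, `sigma2_block`,
#'   `n_varieties`, `n_blocks`, `repeatability`, `H2`.
#' @export
variance_decomposition <- function(data, value = "value",
                                   variety = "cultivar", block = "block") {
  if (!all(c(value, variety, block) %in% names(data)))
    stop("missing column(s) in `data`", call. = FALSE)
  v <- factor(data[[variety]]); b <- factor(data[[block]])
  y <- data[[value]]
  if (nlevels(v) < 2L || nlevels(b) < 2L)
    stop("need at least 2 varieties and 2 blocks", call. = FALSE)
  # technical replicates -> variety x block cell means
  cell <- tapply(y, list(v, b), mean)
  V <- nrow(cell); B <- ncol(cell)
  vm <- rowMeans(cell, na.rm = TRUE)
  bm <- colMeans(cell, na.rm = TRUE)
  dev <- sweep(cell, 1, vm)
  df_r <- sum(!is.na(cell)) - V
  if (df_r < 1L) stop("no residual degrees of freedom", call. = FALSE)
  s2r <- sum(dev^2, na.rm = TRUE) / df_r
  s2v <- max(stats::var(vm) - s2r / B, 0)
  s2b <- max(stats::var(bm) - s2r / V, 0)
  tot <- s2b + s2v + s2r
  structure(list(
    sigma2_V = s2v, sigma2_r = s2r, sigma2_block = s2b,
    n_varieties = V, n_blocks = B,
    repeatability = if (tot > 0) s2b / tot else 0,
    H2 = heritability(s2v, s2r, B)),
    class = "wfl_vardecomp")
}

#' @export
print.wfl_vardecomp <- function(x, ...) {
  cat(sprintf(paste0("<wfl_vardecomp> %d varieties x %d blocks\n",
                     "  sigma2_V = %.4g, sigma2_r = %.4g, sigma2_block = %.4g\n",
                     "  H2 = %.3f, repeatability = %.3f\n"),
              x$n_varieties, x$n_blocks, x$sigma2_V, x$sigma2_r,
              x$sigma2_block, x$H2, x$repeatability))
  invisible(x)
}
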