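#' Construct a regularly indexed time series
#'
#' Light-weight container used throughout the package for wind speed, quantity
#' of motion (QOM), and photosynthetic photon flux density (PPFD) records: a
#' data frame with columns `time` (seconds) and `value`, carrying the nominal
#' sampling rate as an attribute. Timestamps must be strictly increasing; gaps
#' are permitted (the fleck detector splits records at gaps), but most
#' operations require uniform spacing.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param value Numeric vector of the same length.
#' @param rate Nominal sampling rate in samples per second. If `NULL`, inferred
#'   as the reciprocal of the median timestamp spacing.
#' @return An object of class `wfl_series` (also a `data.frame`).
#' @examples
#' s <- wfl_series(time = 0:9, value = rnorm(10), rate = 1)
#' @export
wfl_series <- function(time, value, rate = NULL) {
  if (!is.numeric(time) || !is.numeric(value))
    stop("`time` and `value` must be numeric", call. = FALSE)
  if (length(time) != length(value))
    stop("`time` and `value` must have equal length", call. = FALSE)
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (is.null(rate)) {
    if (length(time) < 2L)
      stop("`rate` must be given for series of length < 2", call. = FALSE)
    rate <- 1 / stats::median(diff(time))
  }
  structure(
    data.frame(time = as.numeric(time), value = as.numeric(value)),
    rate = as.numeric(rate),
    class = c("wfl_series", "data.frame")
  )
}

#' @export
print.wfl_series <- function(x, ...) {
  cat(sprintf("<wfl_series> %d samples at %g s^-1, t = [%g, %g] s\n",
              nrow(x), attr(x, "rate"),
              if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA))
  utils::str(x$value)
  invisible(x)
}

#' @export
plot.wfl_series <- function(x, ..., xlab = "time (s)", ylab = "value",
                            type = "l") {
  graphics::plot(x$time, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# coerce numeric vectors / data frames to the (time, value, rate) triple
as_wfl_series <- function(x, rate = NULL) {
  if (inherits(x, "wfl_series")) return(x)
  if (is.data.frame(x)) {
    tc <- intersect(c("time", "time_s"), names(x))[1]
    vc <- setdiff(names(x), tc)[1]
    if (is.na(tc)) stop("data frame needs a `time` or `time_s` column",
                        call. = FALSE)
    return(wfl_series(x[[tc]], x[[vc]], rate))
  }
  if (is.numeric(x)) {
    if (is.null(rate)) stop("`rate` needed to interpret a bare numeric vector",
                            call. = FALSE)
    return(wfl_series(seq_along(x) / rate - 1 / rate, x, rate))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a series", call. = FALSE)
}

series_rate <- function(x, rate = NULL) {
  if (!is.null(rate)) return(rate)
  r <- attr(x, "rate")
  if (is.null(r)) stop("sampling rate unknown; pass `rate`", call. = FALSE)
  r
}

# uniform-spacing check used by the detector and the synchronizer
check_uniform <- function(time, tol = 1e-9) {
  if (length(time) < 2L) return(invisible(TRUE))
  d <- diff(time)
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * max(1, dt) + tol))
    stop("series is not uniformly sampled", call. = FALSE)
  invisible(TRUE)
}

#' Read and write series CSV files
#'
#' Series are exchanged as two-column CSV files with header `time_s,value`.
#'
#' @param path File path.
#' @param rate Optional nominal sampling rate; inferred from timestamps if
#'   omitted.
#' @return `read_series_csv` returns a [wfl_series()]; `write_series_csv`
#'   returns `path` invisibly.
#' @export
read_series_csv <- function(path, rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns `time_s` and `value` in ", path, call. = FALSE)
  wfl_series(d$time_s, d$value, rate)
}

#' @param x A [wfl_series()] or a data frame with `time`/`time_s` and `value`.
#' @rdname read_series_csv
#' @export
write_series_csv <- function(x, path) {
  x <- as_wfl_series(x)
  utils::write.csv(data.frame(time_s = x$time, value = x$value),
                   path, row.names = FALSE)
  invisible(path)
}
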