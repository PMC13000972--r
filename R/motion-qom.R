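#' Construct a frame sequence
#'
#' @param frames List of `H x W x 3` numeric arrays with channel values in
#'   `[0, 1]` (RGB), all the same shape.
#' @param rate Nominal frame rate (frames s^-1), default 30.
#' @param timestamps Optional strictly increasing timestamps in seconds;
#'   defaults to `(0:(n-1))/rate`.
#' @return An object of class `wfl_frames`.
#' @export
frame_sequence <- function(frames, rate = 30, timestamps = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of arrays", call. = FALSE)
  d <- dim(frames[[1]])
  if (length(d) != 3L || d[3] != 3L)
    stop("each frame must be an H x W x 3 array", call. = FALSE)
  for (f in frames) {
    if (!identical(dim(f), d))
      stop("all frames must have the same shape", call. = FALSE)
    if (min(f) < -1e-9 || max(f) > 1 + 1e-9)
      stop("channel values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / rate
  if (length(timestamps) != length(frames) ||
      (length(timestamps) > 1 && any(diff(timestamps) <= 0)))
    stop("`timestamps` must be strictly increasing, one per frame",
         call. = FALSE)
  structure(list(frames = frames, time = timestamps, rate = rate,
                 dim = d[1:2]),
            class = "wfl_frames")
}

#' @export
print.wfl_frames <- function(x, ...) {
  cat(sprintf("<wfl_frames> %d frames of %d x %d px at %g fps\n",
              length(x$frames), x$dim[1], x$dim[2], x$rate))
  invisible(x)
}

#' Read a lexicographically ordered PNG stack as a frame sequence
#'
#' @param paths Character vector of PNG file paths (sorted before reading) or
#'   a single directory containing `.png` files.
#' @inheritParams frame_sequence
#' @export
read_frames_png <- function(paths, rate = 30) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.png$", full.names = TRUE)
  paths <- sort(paths)
  if (!length(paths)) stop("no PNG files found", call. = FALSE)
  frames <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  frame_sequence(frames, rate = rate)
}

#' Define the analysis zone grid over a plot polygon
#'
#' The plot area is divided into an `nx` x `ny` cell grid (16 x 9 by default,
#' giving nearly square cells on a 2 x 1 m plot) over the polygon's bounding
#' box; cells are grouped into analysis zones by `zone_map`. Reference zones
#' are static image regions outside the plot (bare soil) used to estimate and
#' subtract camera noise.
#'
#' Pixel coordinates are 0-based, row-major, origin top-left; the pixel at
#' 0-based row `i`, column `j` has centre `(x, y) = (j + 0.5, i + 0.5)` and a
#' pixel belongs to the polygon when its centre does.
#'
#' @param image_dim `c(height, width)` in pixels.
#' @param plot_polygon Two-column matrix of polygon vertices `(x, y)` in
#'   0-based pixel coordinates; `NULL` means the full frame.
#' @param nx,ny Number of grid columns and rows (default 16 x 9).
#' @param zone_map Named list mapping zone ids to vectors of cell ids in
#'   `1:(nx*ny)` (cells numbered row-major). Defaults to 23 contiguous groups
#'   of cells; the true grouping is scene metadata that the user supplies.
#' @param reference_zones List of rectangles `c(row0, row1, col0, col1)` in
#'   0-based half-open pixel coordinates (rows `row0 <= i < row1`).
#' @param n_zones Number of zones for the default `zone_map`.
#' @return An object of class `wfl_zonegrid` with named lists `zones` and
#'   `reference` of linear pixel indices.
#' @export
zone_grid <- function(image_dim, plot_polygon = NULL, nx = 16, ny = 9,
                      zone_map = NULL, reference_zones = list(),
                      n_zones = 23) {
  H <- as.integer(image_dim[1]); W <- as.integer(image_dim[2])
  if (is.null(plot_polygon))
    plot_polygon <- cbind(x = c(0, W, W, 0), y = c(0, 0, H, H))
  plot_polygon <- as.matrix(plot_polygon)
  if (ncol(plot_polygon) != 2L || nrow(plot_polygon) < 3L)
    stop("`plot_polygon` must be a matrix of at least 3 (x, y) vertices",
         call. = FALSE)

  # pixel centres, 0-based coordinates
  cx <- rep(seq_len(W) - 0.5, each = H)
  cy <- rep(seq_len(H) - 0.5, times = W)
  inside <- mgcv::in.out(rbind(plot_polygon, plot_polygon[1, ]),
                         cbind(cx, cy))

  xr <- range(plot_polygon[, 1]); yr <- range(plot_polygon[, 2])
  xb <- seq(xr[1], xr[2], length.out = nx + 1L)
  yb <- seq(yr[1], yr[2], length.out = ny + 1L)
  ix <- pmin(pmax(findInterval(cx, xb, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(cy, yb, rightmost.closed = TRUE), 1L), ny)
  cell <- (iy - 1L) * nx + ix
  cell[!inside] <- NA_integer_

  if (is.null(zone_map)) {
    grp <- sort(rep_len(seq_len(n_zones), nx * ny))
    zone_map <- split(seq_len(nx * ny), sprintf("Z%02d", grp))
  }
  all_cells <- unlist(zone_map)
  if (any(all_cells < 1L | all_cells > nx * ny))
    stop("`zone_map` references a cell outside the ", nx, " x ", ny, " grid",
         call. = FALSE)
  if (anyDuplicated(all_cells))
    stop("`zone_map` assigns a cell to more than one zone", call. = FALSE)

  zones <- lapply(zone_map, function(cells) which(cell %in% cells))
  zones <- zones[vapply(zones, length, 1L) > 0L]
  if (!length(zones)) stop("no zone contains any pixel", call. = FALSE)

  reference <- lapply(reference_zones, function(r) {
    if (length(r) != 4L) stop("reference zones are c(row0,row1,col0,col1)",
                              call. = FALSE)
    rr <- (r[1] + 1L):r[2]; cc <- (r[3] + 1L):r[4]
    if (any(rr < 1L | rr > H | cc < 1L | cc > W))
      stop("reference zone outside the image", call. = FALSE)
    as.integer(outer(rr, (cc - 1L) * H, "+"))
  })
  if (length(reference)) {
    pz <- unlist(zones)
    if (any(unlist(reference) %in% pz))
      stop("reference zones must be disjoint from plot zones", call. = FALSE)
  }
  structure(list(dim = c(H, W), nx = nx, ny = ny, zones = zones,
                 reference = reference, polygon = plot_polygon),
            class = "wfl_zonegrid")
}

#' @export
print.wfl_zonegrid <- function(x, ...) {
  cat(sprintf("<wfl_zonegrid> %d x %d px, %d x %d cells, %d zones, %d reference zones\n",
              x$dim[1], x$dim[2], x$nx, x$ny, length(x$zones),
              length(x$reference)))
  invisible(x)
}

qom_statistics <- c("mean_square", "mean_abs", "centered_variance")

# per-channel aggregate of |frame_b - frame_a| over one pixel set
qom_pair <- function(frame_a, frame_b, zone, statistic) {
  npx <- dim(frame_a)[1] * dim(frame_a)[2]
  total <- 0
  for (ch in 1:3) {
    off <- (ch - 1L) * npx
    d <- abs(frame_b[zone + off] - frame_a[zone + off])
    total <- total + switch(statistic,
      mean_square = mean(d^2),
      mean_abs = mean(d),
      centered_variance = mean((d - mean(d))^2))
  }
  total
}

#' Quantity of motion between two frames over one zone
#'
#' For each RGB channel the per-pixel absolute difference is computed within
#' the zone and aggregated; the three channel aggregates are summed into a
#' single quantity of motion (QOM). With the default statistic (mean of
#' squared absolute differences, an uncentered second moment) QOM is 0 when
#' nothing changes and 3 for a uniform shift between pure white and pure
#' black; `mean_abs` shares those anchors, while `centered_variance` (the
#' within-zone variance of the absolute differences) is 0 for any spatially
#' uniform change.
#'
#' @param frame_a,frame_b `H x W x 3` arrays with values in `[0, 1]`.
#' @param zone Integer vector of linear pixel indices into the `H x W` plane,
#'   or a logical `H x W` mask.
#' @param statistic Within-zone aggregation of the absolute differences.
#' @return A single QOM value; in `[0, 3]` under `mean_square` and `mean_abs`.
#' @export
frame_qom <- function(frame_a, frame_b,
                      zone = seq_len(prod(dim(frame_a)[1:2])),
                      statistic = qom_statistics) {
  statistic <- match.arg(statistic)
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have the same shape", call. = FALSE)
  if (is.logical(zone)) zone <- which(zone)
  zone <- as.integer(zone)
  npx <- dim(frame_a)[1] * dim(frame_a)[2]
  if (length(zone) == 0L) stop("`zone` must be non-empty", call. = FALSE)
  if (any(zone < 1L | zone > npx))
    stop("`zone` indices outside the frame", call. = FALSE)
  qom_pair(frame_a, frame_b, zone, statistic)
}

#' Per-zone quantity-of-motion series from a frame sequence
#'
#' Each frame `n` is compared with frame `n + 1`; the QOM of every analysis
#' zone and the mean QOM over the reference zones are returned per pair.
#' Timestamps are placed at the midpoint of each frame pair.
#'
#' @param frames A [frame_sequence()].
#' @param grid A [zone_grid()] matching the frame dimensions.
#' @inheritParams frame_qom
#' @return An object of class `wfl_qom`: list with `time` (pair midpoints),
#'   `qom` (matrix, one column per zone), `reference` (numeric vector or
#'   `NULL` when the grid has no reference zones), and `rate`.
#' @export
qom_series <- function(frames, grid, statistic = qom_statistics) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(frames, "wfl_frames"), inherits(grid, "wfl_zonegrid"))
  if (!identical(as.integer(frames$dim), as.integer(grid$dim)))
    stop("zone grid does not match the frame dimensions", call. = FALSE)
  n <- length(frames$frames)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  nz <- length(grid$zones)
  qom <- matrix(NA_real_, n - 1L, nz,
                dimnames = list(NULL, names(grid$zones)))
  ref <- if (length(grid$reference)) numeric(n - 1L) else NULL
  for (i in seq_len(n - 1L)) {
    fa <- frames$frames[[i]]; fb <- frames$frames[[i + 1L]]
    qom[i, ] <- vapply(grid$zones, function(z) qom_pair(fa, fb, z, statistic),
                       numeric(1))
    if (!is.null(ref))
      ref[i] <- mean(vapply(grid$reference,
                            function(z) qom_pair(fa, fb, z, statistic),
                            numeric(1)))
  }
  structure(list(time = (frames$time[-n] + frames$time[-1]) / 2,
                 qom = qom, reference = ref, rate = frames$rate,
                 statistic = statistic),
            class = "wfl_qom")
}

#' @export
print.wfl_qom <- function(x, ...) {
  cat(sprintf("<wfl_qom> %d frame pairs, %d zones%s (statistic: %s)\n",
              length(x$time), ncol(x$qom),
              if (is.null(x$reference)) "" else ", reference-corrected series available",
              x$statistic))
  invisible(x)
}

#' Subtract the reference-zone QOM from a zone's QOM series
#'
#' The mean QOM over the static reference zones estimates sensor/compression
#' noise and is subtracted elementwise from each analysis zone. Negative
#' results are floored at zero by default because downstream analyses
#' log-transform QOM.
#'
#' @param zone_series,reference_series Numeric vectors or [wfl_series()] of
#'   equal length (and equal timestamps when both carry them).
#' @param floor_at_zero Set negative corrected values to 0 (default `TRUE`).
#' @return Corrected series of the same type as `zone_series`, with attribute
#'   `corrected = TRUE`.
#' @export
subtract_reference <- function(zone_series, reference_series,
                               floor_at_zero = TRUE) {
  zs <- if (inherits(zone_series, "wfl_series")) zone_series$value
        else as.numeric(zone_series)
  rs <- if (inherits(reference_series, "wfl_series")) reference_series$value
        else as.numeric(reference_series)
  if (length(zs) != length(rs))
    stop("zone and reference series must have equal length", call. = FALSE)
  if (inherits(zone_series, "wfl_series") &&
      inherits(reference_series, "wfl_series") &&
      any(abs(zone_series$time - reference_series$time) > 1e-9))
    stop("zone and reference series timestamps differ", call. = FALSE)
  out <- zs - rs
  if (floor_at_zero) out <- pmax(out, 0)
  if (inherits(zone_series, "wfl_series")) {
    res <- wfl_series(zone_series$time, out, attr(zone_series, "rate"))
  } else res <- out
  attr(res, "corrected") <- TRUE
  res
}

#' Write a QOM object as a long-format CSV
#'
#' Columns: `time_s`, `zone_id`, `qom_raw`, `qom_corrected` (reference mean
#' subtracted, floored at zero; equal to `qom_raw` when the grid has no
#' reference zones).
#'
#' @param x A `wfl_qom` object from [qom_series()].
#' @param path Output CSV path.
#' @export
write_qom_csv <- function(x, path) {
  stopifnot(inherits(x, "wfl_qom"))
  nz <- ncol(x$qom)
  long <- data.frame(
    time_s = rep(x$time, nz),
    zone_id = rep(colnames(x$qom), each = length(x$time)),
    qom_raw = as.vector(x$qom))
  corr <- if (is.null(x$reference)) x$qom
          else pmax(sweep(x$qom, 1, x$reference), 0)
  long$qom_corrected <- as.vector(corr)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
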