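# Independent brute-force implementations used as oracles, plus small
# fixture builders. These deliberately share no code with the package
# internals: the extrema scan is an explicit index walk and the pruning loop
# re-finds the smallest failing transition by linear search each round.

# -- brute-force windfleck detector ---------------------------------------

oracle_extrema <- function(x) {
  n <- length(x)
  runs_first <- integer(0); runs_last <- integer(0); runs_val <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    runs_first <- c(runs_first, i); runs_last <- c(runs_last, j)
    runs_val <- c(runs_val, x[i])
    i <- j + 1L
  }
  m <- length(runs_val)
  out <- list()
  if (m < 2L) return(out)
  for (k in seq_len(m)) {
    type <- NA_character_
    if (k == 1L) {
      type <- if (runs_val[2] > runs_val[1]) "min" else "max"
    } else if (k == m) {
      type <- if (runs_val[m - 1L] > runs_val[m]) "min" else "max"
    } else if (runs_val[k] < runs_val[k - 1L] && runs_val[k] < runs_val[k + 1L]) {
      type <- "min"
    } else if (runs_val[k] > runs_val[k - 1L] && runs_val[k] > runs_val[k + 1L]) {
      type <- "max"
    }
    if (!is.na(type))
      out[[length(out) + 1L]] <- list(type = type, first = runs_first[k],
                                      last = runs_last[k], value = runs_val[k])
  }
  out
}

oracle_detect <- function(time, x, rel = 0.05, abs_th = 5) {
  ext <- oracle_extrema(x)
  repeat {
    if (length(ext) < 2L) break
    worst <- 0L; worst_amp <- Inf
    for (i in seq_len(length(ext) - 1L)) {
      amp <- abs(ext[[i + 1L]]$value - ext[[i]]$value)
      lo <- min(ext[[i + 1L]]$value, ext[[i]]$value)
      failing <- amp < abs_th || amp < rel * lo
      if (failing && amp < worst_amp) { worst <- i; worst_amp <- amp }
    }
    if (worst == 0L) break
    ext <- ext[-c(worst, worst + 1L)]
  }
  rows <- list()
  if (length(ext) >= 3L) {
    for (i in 2:(length(ext) - 1L)) {
      if (ext[[i]]$type != "max") next
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = time[ext[[i - 1L]]$last],
        peak_s = time[ext[[i]]$first],
        end_s = time[ext[[i + 1L]]$first],
        baseline = ext[[i - 1L]]$value,
        intensity = ext[[i]]$value - ext[[i - 1L]]$value)
    }
  }
  if (!length(rows))
    return(data.frame(start_s = numeric(0), peak_s = numeric(0),
                      end_s = numeric(0), baseline = numeric(0),
                      intensity = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- naive per-lag Pearson cross-correlation ------------------------------

naive_xcorr <- function(a, b, max_lag) {
  n <- length(a)
  vapply((-max_lag):max_lag, function(k) {
    if (k >= 0) { aa <- a[seq_len(n - k)]; bb <- b[(1 + k):n] }
    else { aa <- a[(1 - k):n]; bb <- b[seq_len(n + k)] }
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) return(NA_real_)
    stats::cor(aa, bb)
  }, numeric(1))
}

# -- fixtures --------------------------------------------------------------

# flat baseline with a symmetric triangular pulse, built on an exact integer
# grid (no floating-point run breaks): rise over `half_n` samples, fall over
# `half_n` samples, at 100 s^-1
triangle_series <- function(baseline = 100, height = 100, half_n = 10,
                            n = 301, peak_at = 151, rate = 100) {
  v <- rep(baseline, n)
  up <- seq_len(half_n)
  v[peak_at - half_n + up] <- baseline + height * up / half_n
  v[peak_at + up] <- baseline + height * (half_n - up) / half_n
  wfl_series((seq_len(n) - 1) / rate, v, rate)
}

# bounded random-walk PPFD-like series on a unit grid
random_walk_series <- function(n = 500, seed = 1, start = 100, step_sd = 2,
                               rate = 100) {
  v <- pmax(start + cumsum(withr::with_seed(seed, stats::rnorm(n, 0, step_sd))), 0)
  wfl_series((seq_len(n) - 1) / rate, v, rate)
}

# uniform-noise frame pair: identical geometry, independent noise
noise_frames <- function(n_frames = 6, H = 48, W = 48, sd = 0.02, seed = 1) {
  base <- array(0.5, c(H, W, 3))
  withr::with_seed(seed, lapply(seq_len(n_frames), function(i) {
    pmin(pmax(base + array(stats::runif(H * W * 3, -sd, sd), c(H, W, 3)), 0), 1)
  }))
}
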