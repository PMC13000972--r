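default_config <- function() {
  list(
    seed = 1L,
    duration_s = 120,
    thresholds = list(rel = 0.05, abs = 5),
    sync = list(max_lag_s = 5),
    binning = list(wind_step = 0.3, qom_log_range = c(-11, -2),
                   n_qom_classes = 15),
    cultivars = list(list(id = "A")),
    output = list(dir = "windfleck-out")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) && nm != "cultivars") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' Configurations are nested key-value (YAML) files; omitted keys fall back
#' to package defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A named configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks stream rates, threshold positivity, binning-edge monotonicity,
#' zone-map consistency, and that every referenced input path exists or a
#' synthetic generation block is present. Violations are returned, not
#' raised.
#'
#' @param config A configuration list as from [read_config()].
#' @return Character vector of named violations; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  th <- config$thresholds
  if (!is.null(th)) {
    if (!is.numeric(th$rel) || th$rel < 0) say("thresholds.rel: must be >= 0")
    if (!is.numeric(th$abs) || th$abs < 0) say("thresholds.abs: must be >= 0")
  }
  if (!is.null(config$sync$max_lag_s) && config$sync$max_lag_s <= 0)
    say("sync.max_lag_s: must be positive")
  b <- config$binning
  if (!is.null(b)) {
    if (!is.null(b$wind_step) && b$wind_step <= 0)
      say("binning.wind_step: must be positive")
    if (!is.null(b$qom_log_range) && diff(range(b$qom_log_range)) <= 0)
      say("binning.qom_log_range: must span a positive range")
    if (!is.null(b$n_qom_classes) && b$n_qom_classes < 1)
      say("binning.n_qom_classes: must be >= 1")
  }
  rates <- config$rates
  if (!is.null(rates)) {
    if (!is.null(rates$ppfd) && rates$ppfd != 100)
      say("rates.ppfd: must be 100 s^-1")
    if (!is.null(rates$qom) && rates$qom != 30)
      say("rates.qom: must be 30 s^-1")
    if (!is.null(rates$wind) && rates$wind != 1)
      say("rates.wind: must be 1 s^-1")
  }
  if (is.null(config$seed) || !is.numeric(config$seed))
    say("seed: must be an integer")
  zm <- config$zone_map
  if (!is.null(zm)) {
    cells <- unlist(zm)
    nx <- config$grid$nx %||% 16; ny <- config$grid$ny %||% 9
    if (any(cells < 1 | cells > nx * ny))
      say("zone_map: references a cell outside the %d x %d grid", nx, ny)
    if (anyDuplicated(cells)) say("zone_map: duplicated cell assignment")
  }
  for (i in seq_along(config$cultivars)) {
    cu <- config$cultivars[[i]]
    for (key in c("wind_csv", "ppfd_csv", "qom_csv")) {
      if (!is.null(cu[[key]]) && !file.exists(cu[[key]]))
        say("cultivars[%d].%s: file not found: %s", i, key, cu[[key]])
    }
  }
  if (!is.null(config$traits_csv) && !file.exists(config$traits_csv))
    say("traits_csv: file not found: %s", config$traits_csv)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic polynomial fingerprint of the (ascii-serialized) configuration
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 0
  for (x in bytes) h <- (h * 257 + x + 1) %% 2147483647
  sprintf("%08x", h)
}

run_one_cultivar <- function(cu, cfg, seed, out_dir, log) {
  id <- cu$id %||% "A"
  th <- cfg$thresholds; max_lag <- round(cfg$sync$max_lag_s * 100)

  # --- acquire the three streams (synthetic unless CSVs are given) --------
  if (!is.null(cu$wind_csv)) {
    wind <- read_series_csv(cu$wind_csv, rate = 1)
  } else {
    wp <- do.call(wind_model_params,
                  c(cu$wind %||% list(), list(seed = seed)))
    wind <- gen_wind(wp, cfg$duration_s)
  }
  frames_cfg <- cu$frames %||% list(enabled = FALSE)
  if (!is.null(cu$qom_csv)) {
    qom30 <- read_series_csv(cu$qom_csv, rate = 30)
  } else {
    mp <- do.call(motion_model_params,
                  c(cu$motion %||% list(), list(seed = seed + 1L)))
    qom30 <- gen_motion(wind, mp, rate = 30)
    if (isTRUE(frames_cfg$enabled)) {
      fr <- gen_frames(qom30,
                       image_size = frames_cfg$image_size %||% c(64, 64),
                       texture_scale = frames_cfg$texture_scale %||% 8,
                       seed = seed + 2L)
      border <- frames_cfg$border %||% 8
      H <- fr$dim[1]; W <- fr$dim[2]
      grid <- zone_grid(
        c(H, W),
        plot_polygon = cbind(x = c(border, W - border, W - border, border),
                             y = c(border, border, H - border, H - border)),
        reference_zones = list(c(0, border, 0, W)),
        n_zones = frames_cfg$n_zones %||% 4)
      q <- qom_series(fr, grid)
      zid <- colnames(q$qom)[1]
      corrected <- subtract_reference(q$qom[, 1], q$reference)
      qom30 <- wfl_series(q$time, corrected, fr$rate)
      log("qom", sprintf("[%s] measured QOM from %d frames (zone %s)",
                         id, length(fr$frames), zid))
    }
  }
  if (!is.null(cu$ppfd_csv)) {
    ppfd <- read_series_csv(cu$ppfd_csv, rate = 100)
    truth <- NULL
  } else {
    fp <- do.call(fleck_model_params,
                  c(cu$ppfd %||% list(), list(seed = seed + 3L)))
    sim <- gen_ppfd(qom30, fp, rate = 100)
    ppfd <- sim$series
    truth <- sim$events
  }

  # --- common 100 s^-1 clock + shift estimation ---------------------------
  qom100 <- resample_linear(qom30, to_rate = 100)
  wind100 <- resample_step(wind, to_rate = 100)
  n <- min(nrow(ppfd), nrow(qom100), nrow(wind100))
  pv <- ppfd$value[seq_len(n)]
  qv <- qom100$value[seq_len(n)]
  wv <- wind100$value[seq_len(n)]
  max_lag <- min(max_lag, (n - 2L) %/% 2L)  # short records cap the window
  xc_pq <- cross_correlation(pv, qv, max_lag)
  qom_shift <- xc_pq$lag[which.max(abs(xc_pq$value))]
  xc_pw <- cross_correlation(pv, wv, max_lag)
  xc_qw <- cross_correlation(qv, wv, max_lag)
  wind_shift <- tryCatch(estimate_wind_shift(xc_pw, xc_qw),
                         wfl_no_valid_shift = function(e) NA_integer_)
  log("sync", sprintf("[%s] wind shift %s samples, PPFD-QOM shift %d samples",
                      id, wind_shift, qom_shift))

  # --- flecks -------------------------------------------------------------
  ev <- detect_windflecks(ppfd, th$rel, th$abs)
  summ <- summarize_flecks(ev)

  # --- binning ------------------------------------------------------------
  w_edges <- wind_class_edges(max(wv), cfg$binning$wind_step)
  q_edges <- qom_class_edges(cfg$binning$qom_log_range,
                             cfg$binning$n_qom_classes)
  bw <- bin_series(wv, w_edges, rate = 100)
  bq <- bin_series(qv, q_edges, rate = 100)
  ppfd_t <- ppfd$time[seq_len(n)]
  evw <- assign_event_class(ev, wfl_series(ppfd_t, wv, 100), w_edges)
  evq <- assign_event_class(ev, wfl_series(ppfd_t, qv, 100), q_edges)
  # an event whose interval mean falls in a class no sample occupies (the
  # mean of a step series can land between occupied classes) is unclassable
  evw[!is.na(evw) & bw$time_in_class[evw] <= 0] <- NA_integer_
  evq[!is.na(evq) & bq$time_in_class[evq] <= 0] <- NA_integer_
  fw <- frequency_by_class(evw, bw$time_in_class, edges = w_edges)
  fq <- frequency_by_class(evq, bq$time_in_class, edges = q_edges)
  fw$scheme <- "wind_linear"; fq$scheme <- "qom_exponential"

  # --- outputs ------------------------------------------------------------
  pre <- file.path(out_dir, paste0(id, "_"))
  write_series_csv(qom30, paste0(pre, "qom.csv"))
  utils::write.csv(as.data.frame(ev), paste0(pre, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(cultivar = id, n_events = summ$n_events,
               total_time_s = summ$total_time, frequency = summ$frequency,
               frequency_per_100s = summ$frequency_per_100s,
               mean_time_between_s = summ$mean_time_between),
    paste0(pre, "fleck_summary.csv"), row.names = FALSE)
  utils::write.csv(rbind(fw, fq), paste0(pre, "class_frequency.csv"),
                   row.names = FALSE)

  list(id = id, n = n,
       mean_qom = mean(qv), mean_wind = mean(wv),
       fleck_frequency = summ$frequency,
       wind_shift = wind_shift, qom_shift = qom_shift,
       xc_peak_pw = suppressWarnings(max(abs(xc_pw$value), na.rm = TRUE)),
       n_events = summ$n_events,
       n_true_events = if (is.null(truth)) NA_integer_ else nrow(truth))
}

#' Run the full windfleck analysis pipeline
#'
#' Orchestrates the chain for each configured cultivar: acquire or simulate
#' the wind, motion and PPFD streams (optionally measuring motion from
#' simulated video frames), synchronize them on a common 100 s^-1 clock,
#' estimate the wind-record shift, detect and summarize windflecks, bin
#' events by wind-speed and QOM class, and (for multi-cultivar panels)
#' compute the motion-sensitivity and light-modulation-efficiency indices.
#' All outputs are CSV tables plus a plain-text key-value run report; the
#' run is deterministic for a fixed configuration and seed.
#'
#' @param config Configuration list (see [read_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$output$dir`.
#' @param seed Overrides `config$seed` when given.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-cultivar summaries, the cultivar
#'   index table (`NULL` for a single cultivar), and the run-report path.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config)
         else merge_config(default_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- seed
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  out_dir <- out_dir %||% cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, msg) if (!quiet) message("[", stage, "] ", msg)

  results <- list()
  for (i in seq_along(cfg$cultivars)) {
    cu <- cfg$cultivars[[i]]
    seed_i <- as.integer(cfg$seed) + 100L * i
    results[[i]] <- run_one_cultivar(cu, cfg, seed_i, out_dir, log)
  }

  indices <- NULL
  if (length(results) >= 2L) {
    panel <- data.frame(
      cultivar = vapply(results, `[[`, "", "id"),
      mean_qom = vapply(results, `[[`, 0, "mean_qom"),
      mean_wind = vapply(results, `[[`, 0, "mean_wind"),
      fleck_frequency = vapply(results, `[[`, 0, "fleck_frequency"))
    indices <- cultivar_indices(panel)
    utils::write.csv(indices, file.path(out_dir, "cultivar_indices.csv"),
                     row.names = FALSE)
  }

  if (!is.null(cfg$traits) || !is.null(cfg$traits_csv)) {
    traits <- if (!is.null(cfg$traits_csv)) utils::read.csv(cfg$traits_csv)
              else gen_trait_table(do.call(
                trait_sim_params,
                c(cfg$traits, list(seed = as.integer(cfg$seed) + 7L))))
    vd <- variance_decomposition(traits)
    utils::write.csv(
      data.frame(trait = "value", sigma2_V = vd$sigma2_V,
                 sigma2_r = vd$sigma2_r, sigma2_block = vd$sigma2_block,
                 repeatability = vd$repeatability, H2 = vd$H2),
      file.path(out_dir, "variance_decomposition.csv"), row.names = FALSE)
    log("traits", sprintf("H2 = %.3f, repeatability = %.3f",
                          vd$H2, vd$repeatability))
  }

  report <- file.path(out_dir, "run_report.txt")
  lines <- c(
    sprintf("pipeline_version: %s",
            as.character(utils::packageVersion("windfleckr"))),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("config_hash: %s", config_hash(cfg)),
    sprintf("n_cultivars: %d", length(results)),
    unlist(lapply(results, function(r) c(
      sprintf("cultivar.%s.n_samples: %d", r$id, r$n),
      sprintf("cultivar.%s.mean_wind: %.6g", r$id, r$mean_wind),
      sprintf("cultivar.%s.mean_qom: %.6g", r$id, r$mean_qom),
      sprintf("cultivar.%s.n_events: %d", r$id, r$n_events),
      sprintf("cultivar.%s.wind_shift_samples: %s", r$id, r$wind_shift),
      sprintf("cultivar.%s.ppfd_qom_shift_samples: %d", r$id, r$qom_shift)))))
  writeLines(lines, report)
  log("report", report)
  invisible(list(cultivars = results, indices = indices, report = report,
                 out_dir = out_dir))
}
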