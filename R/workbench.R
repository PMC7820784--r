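CONFIG_KEYS <- c("profile", "n_free", "k", "rewire_prob", "g_max",
                 "stickiness", "hh", "transfer", "noise_mean", "noise_sd",
                 "noise_dist", "dt", "duration", "burn_in", "V0",
                 "firing_threshold", "topology_seed", "weight_seed",
                 "noise_seed")

#' Load / write a simulation configuration
#'
#' Reads a YAML (or JSON) configuration file and fills every unspecified
#' field with the documented default, yielding a validated [sim_config()].
#' Recognized keys are the [sim_config()] arguments plus `profile`
#' (`"classic"` or `"textbook"`, selecting the [hh_params()] preset) and the
#' nested maps `hh:` and `transfer:` for individual overrides. Unknown keys
#' and invalid values produce errors naming the offending field. An empty
#' file yields the full default configuration. `write_config()` serializes a
#' config so that `load_config(write_config(cfg))` reproduces it.
#'
#' @param path config file path.
#' @return `load_config`: a `critnet_config`; `write_config`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  profile <- raw$profile %||% "classic"
  hh_args <- raw$hh %||% list()
  bad_hh <- setdiff(names(hh_args),
                    c("C", "g_Na", "g_K", "g_leak", "V_Na", "V_K", "V_leak"))
  if (length(bad_hh))
    stop("unknown hh key(s): ", paste(bad_hh, collapse = ", "))
  hh <- do.call(hh_params, c(hh_args, list(profile = profile)))
  tr_args <- raw$transfer %||% list()
  bad_tr <- setdiff(names(tr_args), c("theta_syn", "sigma_syn", "i_scale"))
  if (length(bad_tr))
    stop("unknown transfer key(s): ", paste(bad_tr, collapse = ", "))
  transfer <- do.call(transfer_params, tr_args)
  args <- raw[setdiff(names(raw), c("profile", "hh", "transfer"))]
  cfg <- tryCatch(
    do.call(sim_config, c(args, list(hh = hh, transfer = transfer))),
    error = function(e) stop("invalid config: ", conditionMessage(e),
                             call. = FALSE))
  cfg$profile <- profile
  cfg
}

#' @rdname load_config
#' @param config a `critnet_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$hh <- unclass(out$hh)
  out$transfer <- unclass(out$transfer)
  out$profile <- config$profile %||% "classic"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full experiment pipeline
#'
#' Chains simulate -> rasterize -> simultaneous-firing histogram -> fits ->
#' phase classification -> synthetic EEG -> Welch PSD -> high-frequency
#' slope -> Morlet scalogram, and (when `output_dir` is given) writes the
#' traces, raster, histogram, scalogram and a JSON report. When a `raster`
#' is supplied the simulation and signal stages are skipped and only the
#' criticality analysis runs (the analysis-only path for externally supplied
#' rasters). The scalogram is computed on the EEG decimated to 1 kHz; its
#' CSV is column-pooled to at most 1024 time bins.
#'
#' @param config a [sim_config()] (ignored for the raster path except for
#'   classification thresholds).
#' @param output_dir directory for exported artifacts (created if needed);
#'   NULL keeps everything in memory.
#' @param raster optional `critnet_raster` to analyse instead of simulating.
#' @param scalogram compute the wavelet scalogram stage (default TRUE).
#' @return object of class `critnet_report`: `config`, `phase`
#'   (`critnet_phase`), `mean_cluster_size`, `psd_slope`, `psd_fit_band`,
#'   `histogram`, `files` (named paths, possibly empty), `schema_version`.
#'   For simulation runs the `traces`, `eeg` and `psd` objects are attached.
#' @export
run_experiment <- function(config, output_dir = NULL, raster = NULL,
                           scalogram = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- character()
  traces <- eeg <- psd <- scal <- NULL
  if (is.null(raster)) {
    traces <- stage("simulate", run_network(config))
    raster <- stage("rasterize",
                    rasterize(traces, config$firing_threshold, "level"))
    eeg <- stage("eeg", synthetic_eeg(traces))
    psd <- stage("psd", compute_psd(eeg, segment_sec = welch_segment(eeg)))
    if (scalogram) {
      dec <- max(1L, round(1 / eeg$dt))  # decimate to ~1 kHz
      eeg_1k <- structure(list(values = eeg$values[seq(1, length(eeg$values),
                                                       by = dec)],
                               dt = eeg$dt * dec), class = "critnet_eeg")
      scal <- stage("scalogram",
                    compute_scalogram(eeg_1k,
                                      f_max = min(500, 500 / (eeg$dt * dec))))
    }
  }
  hist <- stage("histogram", firing_histogram(raster))
  phase <- stage("classify", classify_phase(hist))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(output_dir, f)
    if (!is.null(traces)) {
      export_traces(traces, "csv", p("traces.csv"))
      files["traces"] <- p("traces.csv")
      export_traces(eeg, "csv", p("eeg.csv"))
      files["eeg"] <- p("eeg.csv")
      export_traces(eeg, "edf", p("eeg.edf"))
      files["eeg_edf"] <- p("eeg.edf")
      utils::write.csv(data.frame(frequency_hz = psd$frequencies,
                                  power = psd$power),
                       p("psd.csv"), row.names = FALSE)
      files["psd"] <- p("psd.csv")
      if (!is.null(scal)) {
        write_scalogram_csv(scal, p("scalogram.csv"))
        files["scalogram"] <- p("scalogram.csv")
      }
    }
    write_raster(raster, p("raster.csv"))
    files["raster"] <- p("raster.csv")
    utils::write.csv(data.frame(k = as.integer(names(hist$counts)),
                                steps = as.integer(hist$counts)),
                     p("histogram.csv"), row.names = FALSE)
    files["histogram"] <- p("histogram.csv")
  }

  report <- structure(
    list(config = config, phase = phase,
         mean_cluster_size = phase$mean_cluster_size,
         psd_slope = if (!is.null(psd)) psd$slope else NA_real_,
         psd_fit_band = if (!is.null(psd)) psd$fit_band else NULL,
         histogram = hist, files = files,
         traces = traces, eeg = eeg, psd = psd, scalogram = scal,
         schema_version = "1.0"),
    class = "critnet_report")
  if (!is.null(output_dir)) {
    write_report_json(report, file.path(output_dir, "report.json"))
    report$files["report"] <- file.path(output_dir, "report.json")
  }
  report
}

#' @export
print.critnet_report <- function(x, ...) {
  cat("experiment report (schema ", x$schema_version, ")\n", sep = "")
  print(x$phase)
  if (is.finite(x$psd_slope))
    cat(sprintf("  PSD slope %.3g over %g-%g Hz\n", x$psd_slope,
                x$psd_fit_band[1], x$psd_fit_band[2]))
  if (length(x$files))
    cat("  files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}

# Welch segment length: 1 s for analysis-length runs, half the series for
# shorter ones so at least two segments always exist
welch_segment <- function(eeg) {
  min(1, length(eeg$values) * eeg$dt / 2000)
}

fit_json <- function(f) {
  if (!inherits(f, "critnet_fit")) return(list(error = as.character(f)))
  list(model = f$model, tau = f$tau, s0 = f$s0, goodness = f$goodness,
       fit_range = f$fit_range, flags = f$flags)
}

write_report_json <- function(report, path) {
  cfg <- unclass(report$config)
  cfg$hh <- unclass(cfg$hh); cfg$transfer <- unclass(cfg$transfer)
  doc <- list(
    schema_version = report$schema_version,
    config = cfg,
    phase = list(label = report$phase$label,
                 activity_fraction = report$phase$activity_fraction,
                 ictal_mass = report$phase$ictal_mass,
                 low_confidence = report$phase$low_confidence,
                 fits = lapply(report$phase$fits, fit_json)),
    mean_cluster_size = report$mean_cluster_size,
    psd_slope = report$psd_slope,
    psd_fit_band = report$psd_fit_band,
    files = as.list(report$files))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

write_scalogram_csv <- function(scal, path, max_cols = 1024L) {
  m <- scal$magnitude
  if (ncol(m) > max_cols) {
    grp <- ceiling(seq_len(ncol(m)) / (ncol(m) / max_cols))
    m <- t(apply(m, 1, function(r) tapply(r, grp, mean)))
  }
  out <- cbind(frequency_hz = scal$frequencies, m)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export traces or EEG to CSV or EDF
#'
#' CSV traces have a `time_ms` column followed by one column per node
#' (`node_<id>`); an EEG exports as `time_ms, eeg_mv`. EDF export writes a
#' standard 16-bit European Data Format file with one channel per node (or
#' one EEG channel), sample rate `1/dt`, physical range taken from the data
#' (widened by +/-1 mV for constant signals).
#'
#' @param x a `critnet_traces` or `critnet_eeg`.
#' @param format `"csv"` or `"edf"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_traces <- function(x, format = c("csv", "edf"), path) {
  format <- match.arg(format)
  if (inherits(x, "critnet_traces")) {
    signals <- x$voltages
    labels <- sprintf("node_%d", seq_len(nrow(signals)) - 1L)
    dt <- x$dt
  } else if (inherits(x, "critnet_eeg")) {
    signals <- matrix(x$values, nrow = 1)
    labels <- "eeg"
    dt <- x$dt
  } else stop("x must be critnet_traces or critnet_eeg")
  if (format == "csv") {
    df <- data.frame(time_ms = (seq_len(ncol(signals)) - 1) * dt)
    for (i in seq_along(labels)) df[[labels[i]]] <- signals[i, ]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_edf(signals, dt, labels, path)
  }
  invisible(path)
}

#' Sweep a parameter and summarize phases
#'
#' Runs [parameter_sweep()] on a frozen network, analyses every run, and
#' reports a summary table of phase label, mean cluster size and PSD slope
#' per swept value, plus the value maximizing the percolation mean cluster
#' size (`NA` when every run is silent).
#'
#' @param base a [sim_config()].
#' @param axis,values as in [parameter_sweep()].
#' @param output_dir optional directory; per-value artifacts go into
#'   subdirectories `value_<v>` and the summary into `sweep_summary.csv`.
#' @param scalogram forwarded to [run_experiment()] (default FALSE: sweeps
#'   rarely need per-run scalograms).
#' @return list of class `critnet_sweep`: `summary` (data.frame with
#'   `value`, `label`, `mean_cluster_size`, `psd_slope`), `argmax_value`,
#'   `reports`.
#' @export
run_sweep <- function(base, axis, values, output_dir = NULL,
                      scalogram = FALSE) {
  runs <- parameter_sweep(base, axis, values)
  reports <- lapply(runs, function(r) {
    cfg <- r$traces$config
    od <- if (!is.null(output_dir))
      file.path(output_dir, sprintf("value_%g", r$value))
    raster <- rasterize(r$traces, cfg$firing_threshold, "level")
    hist <- firing_histogram(raster)
    phase <- classify_phase(hist)
    eeg <- synthetic_eeg(r$traces)
    psd <- compute_psd(eeg, segment_sec = welch_segment(eeg))
    rep <- structure(
      list(config = cfg, phase = phase,
           mean_cluster_size = phase$mean_cluster_size,
           psd_slope = psd$slope, psd_fit_band = psd$fit_band,
           histogram = hist, files = character(),
           traces = NULL, eeg = eeg, psd = psd, scalogram = NULL,
           schema_version = "1.0"),
      class = "critnet_report")
    if (!is.null(od)) {
      dir.create(od, showWarnings = FALSE, recursive = TRUE)
      write_report_json(rep, file.path(od, "report.json"))
    }
    rep
  })
  summary <- data.frame(
    value = values,
    label = vapply(reports, function(r) r$phase$label, character(1)),
    mean_cluster_size = vapply(reports, function(r)
      r$mean_cluster_size %||% NA_real_, numeric(1)),
    psd_slope = vapply(reports, function(r) r$psd_slope, numeric(1)))
  mcs <- summary$mean_cluster_size
  argmax <- if (all(is.na(mcs))) NA_real_ else values[which.max(mcs)]
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(output_dir, "sweep_summary.csv"),
                     row.names = FALSE)
  }
  structure(list(summary = summary, argmax_value = argmax,
                 axis = axis, reports = reports),
            class = "critnet_sweep")
}

#' @export
print.critnet_sweep <- function(x, ...) {
  cat(sprintf("sweep over %s (%d values); mean-cluster-size argmax: %s\n",
              x$axis, nrow(x$summary), format(x$argmax_value)))
  print(x$summary)
  invisible(x)
}
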