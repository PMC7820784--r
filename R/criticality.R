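#' Convert voltage traces to a firing raster
#'
#' Thresholds the free neurons' voltages (the clamped driver is excluded —
#' its voltage is exogenous noise, not activity). In `"level"` mode a cell is
#' TRUE whenever `V >= threshold`; in `"onset"` mode only at upward
#' crossings (a step whose voltage is at/above threshold while the previous
#' step was below; the first step counts if already suprathreshold). The
#' burn-in interval is dropped.
#'
#' @param traces a `critnet_traces` from [run_network()].
#' @param threshold firing threshold, mV; values outside the physiological
#'   sanity band \[-20, 40\] mV trigger a warning.
#' @param mode `"level"` or `"onset"`.
#' @param burn_in ms to drop from the start (default: the run's configured
#'   burn-in).
#' @return object of class `critnet_raster`: logical `firing` matrix
#'   (free neurons x kept steps), `dt`, `threshold`, `mode`.
#' @export
rasterize <- function(traces, threshold = 0, mode = c("level", "onset"),
                      burn_in = NULL) {
  mode <- match.arg(mode)
  if (threshold < -20 || threshold > 40)
    warning("firing threshold ", threshold,
            " mV is outside the physiological band [-20, 40] mV")
  if (is.null(burn_in)) burn_in <- traces$config$burn_in
  n_steps <- ncol(traces$voltages)
  drop <- round(burn_in / traces$dt)
  if (drop >= n_steps) stop("burn_in must be shorter than the trace")
  V <- traces$voltages[-(traces$clamped_node + 1L), (drop + 1L):n_steps,
                       drop = FALSE]
  above <- V >= threshold
  firing <- if (mode == "level") above else {
    prev <- cbind(FALSE, above[, -ncol(above), drop = FALSE])
    above & !prev
  }
  structure(list(firing = firing, dt = traces$dt, threshold = threshold,
                 mode = mode),
            class = "critnet_raster")
}

#' Histogram of simultaneously firing neurons
#'
#' Counts, for each possible number k = 0..N of simultaneously firing
#' neurons, how many time steps have exactly k raster columns TRUE. The
#' counts always sum to the number of time steps.
#'
#' @param raster a `critnet_raster` (or any logical matrix neurons x steps).
#' @return object of class `critnet_hist`: integer `counts` named "0".."N",
#'   `n_neurons`, `n_steps`.
#' @export
firing_histogram <- function(raster) {
  firing <- if (inherits(raster, "critnet_raster")) raster$firing else raster
  if (length(firing) == 0) stop("empty raster")
  N <- nrow(firing)
  k <- colSums(firing)
  counts <- tabulate(k + 1L, nbins = N + 1L)
  names(counts) <- 0:N
  structure(list(counts = counts, n_neurons = N, n_steps = ncol(firing)),
            class = "critnet_hist")
}

#' @export
print.critnet_hist <- function(x, ...) {
  cat(sprintf("firing histogram: %d neurons, %d steps, active fraction %.3g\n",
              x$n_neurons, x$n_steps, 1 - x$counts[["0"]] / x$n_steps))
  invisible(x)
}

# usable (k, log count) points for fitting: k >= 1, count > 0, within range
fit_points <- function(hist, fit_range) {
  k <- as.integer(names(hist$counts))
  keep <- k >= max(1L, fit_range[1]) & k <= fit_range[2] & hist$counts > 0
  list(k = k[keep], logc = log(hist$counts[keep]))
}

new_fit <- function(model, tau = NA_real_, s0 = NA_real_, goodness = NA_real_,
                    fit_range = c(NA, NA), flags = character()) {
  structure(list(model = model, tau = tau, s0 = s0, goodness = goodness,
                 fit_range = fit_range, flags = flags),
            class = "critnet_fit")
}

#' @export
print.critnet_fit <- function(x, ...) {
  cat(sprintf("%s fit: tau = %s, s0 = %s, goodness = %.4g%s\n", x$model,
              format(x$tau, digits = 4), format(x$s0, digits = 4),
              x$goodness,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Fit the subcritical exponential form
#'
#' Least-squares line through log counts vs k over the usable bins (k >= 1,
#' nonzero count, inside `fit_range`), modelling the subcritical regime
#' \eqn{n(k) \propto e^{-k/s_0}}; `s0 = -1/slope`. A non-negative slope is
#' flagged `"degenerate"` with `s0 = Inf`.
#'
#' @param hist a `critnet_hist`.
#' @param fit_range inclusive `c(k_min, k_max)` bin range (default all).
#' @return a `critnet_fit` with `s0`, `goodness` (sum of squared
#'   log-residuals), and flags.
#' @export
fit_exponential <- function(hist, fit_range = c(1, hist$n_neurons)) {
  p <- fit_points(hist, fit_range)
  if (length(p$k) < 3)
    stop("insufficient data: need >= 3 usable bins, have ", length(p$k))
  fit <- stats::lm(p$logc ~ p$k)
  slope <- stats::coef(fit)[[2]]
  flags <- character()
  s0 <- if (slope < -1e-12) -1 / slope else { flags <- "degenerate"; Inf }
  new_fit("exponential", s0 = s0, goodness = sum(stats::resid(fit)^2),
          fit_range = fit_range, flags = flags)
}

#' Fit the critical power-law form
#'
#' Least-squares line through log counts vs log k over the usable bins,
#' modelling the scale-free critical regime \eqn{n(k) \propto k^{-\tau}};
#' `tau = -slope`.
#'
#' @inheritParams fit_exponential
#' @return a `critnet_fit` with `tau` and `goodness`.
#' @export
fit_power_law <- function(hist, fit_range = c(1, hist$n_neurons)) {
  p <- fit_points(hist, fit_range)
  if (length(p$k) < 3)
    stop("insufficient data: need >= 3 usable bins, have ", length(p$k))
  fit <- stats::lm(p$logc ~ log(p$k))
  new_fit("power", tau = -stats::coef(fit)[[2]],
          goodness = sum(stats::resid(fit)^2), fit_range = fit_range)
}

#' Fit the truncated power law
#'
#' Nonlinear least squares on
#' \eqn{\log n(k) = a - \tau \log k - k/s_0}, the percolation-theory cluster
#' form whose cutoff `s0` diverges at criticality. Initialized from the two
#' single-model fits. An `s0` estimate beyond the largest usable bin (or of
#' the wrong sign) is flagged `"cutoff_unidentifiable"`; non-convergence is
#' returned as a flagged result, not an error.
#'
#' @inheritParams fit_exponential
#' @return a `critnet_fit` with `tau`, `s0`, `goodness`, flags.
#' @export
fit_truncated_power_law <- function(hist, fit_range = c(1, hist$n_neurons)) {
  p <- fit_points(hist, fit_range)
  if (length(p$k) < 4)
    stop("insufficient data: need >= 4 usable bins, have ", length(p$k))
  pw <- fit_power_law(hist, fit_range)
  ex <- fit_exponential(hist, fit_range)
  start <- list(a = max(p$logc), tau = max(pw$tau, 0),
                r = if (is.finite(ex$s0)) 1 / ex$s0 else 1e-3)
  dat <- data.frame(k = p$k, logc = p$logc)
  fit <- tryCatch(
    minpack.lm::nlsLM(logc ~ a - tau * log(k) - r * k, data = dat,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_fit("truncated_power", fit_range = fit_range,
                   flags = c("no_convergence", conditionMessage(fit))))
  cf <- stats::coef(fit)
  flags <- character()
  s0 <- if (cf[["r"]] > 0) 1 / cf[["r"]] else Inf
  if (!is.finite(s0) || s0 > max(p$k)) flags <- "cutoff_unidentifiable"
  new_fit("truncated_power", tau = cf[["tau"]], s0 = s0,
          goodness = sum(stats::resid(fit)^2), fit_range = fit_range,
          flags = flags)
}

#' Percolation mean cluster size
#'
#' \eqn{S = \sum_{k \ge 1} k^2 n_k / \sum_{k \ge 1} k\, n_k} over the
#' simultaneous-firing histogram — the percolation-theory mean cluster size,
#' which grows toward divergence as the network approaches criticality.
#'
#' @param hist a `critnet_hist`.
#' @return `S >= 1`, or `NA` (with a warning) for an all-silent histogram.
#' @export
mean_cluster_size <- function(hist) {
  k <- as.integer(names(hist$counts))
  active <- k >= 1
  denom <- sum(k[active] * hist$counts[active])
  if (denom == 0) {
    warning("all-silent histogram: mean cluster size undefined")
    return(NA_real_)
  }
  sum(k[active]^2 * hist$counts[active]) / denom
}

#' Classify the network phase
#'
#' Applies the decision rule: (1) `silent` when the fraction of time steps
#' with any firing is below `f_silent`; (2) `ictal` when the fraction of
#' *active* steps with at least `ceil(sync_frac * N)` neurons firing
#' simultaneously exceeds `f_ictal` (the all-or-nothing synchronization
#' signature); otherwise (3) `power` when the power-law fit has smaller
#' summed squared log-residuals than the exponential fit on the k >= 1 bins,
#' `exponential` otherwise (ties -> exponential, conservative toward
#' subcritical). All three fits are attempted and reported regardless of the
#' label.
#'
#' @param hist a `critnet_hist`.
#' @param f_silent activity-fraction floor below which the run is silent.
#' @param f_ictal synchronized-mass threshold for the ictal label.
#' @param sync_frac fraction of N defining "synchronized" (default 0.8).
#' @param fit_range bin range passed to the fitters.
#' @return object of class `critnet_phase`: `label`, `fits` (list of the
#'   three `critnet_fit`s or error messages), `mean_cluster_size`,
#'   `activity_fraction`, `ictal_mass`, `low_confidence` (TRUE under 1000
#'   steps).
#' @export
classify_phase <- function(hist, f_silent = 0.01, f_ictal = 0.5,
                           sync_frac = 0.8,
                           fit_range = c(1, hist$n_neurons)) {
  k <- as.integer(names(hist$counts))
  n_active <- sum(hist$counts[k >= 1])
  activity_fraction <- n_active / hist$n_steps
  k_sync <- ceiling(sync_frac * hist$n_neurons)
  ictal_mass <- if (n_active > 0)
    sum(hist$counts[k >= k_sync]) / n_active else 0

  try_fit <- function(f) tryCatch(f(hist, fit_range), error = conditionMessage)
  fits <- list(exponential = try_fit(fit_exponential),
               power = try_fit(fit_power_law),
               truncated_power = try_fit(fit_truncated_power_law))

  label <- if (activity_fraction < f_silent) "silent"
  else if (ictal_mass > f_ictal) "ictal"
  else if (inherits(fits$power, "critnet_fit") &&
           inherits(fits$exponential, "critnet_fit") &&
           fits$power$goodness < fits$exponential$goodness) "power"
  else "exponential"

  structure(
    list(label = label, fits = fits,
         mean_cluster_size = if (n_active > 0)
           mean_cluster_size(hist) else NA_real_,
         activity_fraction = activity_fraction, ictal_mass = ictal_mass,
         low_confidence = hist$n_steps < 1000),
    class = "critnet_phase")
}

#' @export
print.critnet_phase <- function(x, ...) {
  cat(sprintf("phase: %s (activity %.3g, ictal mass %.3g, mean cluster size %s)%s\n",
              x$label, x$activity_fraction, x$ictal_mass,
              format(x$mean_cluster_size, digits = 4),
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Synthesize a raster with a known firing-count law
#'
#' Draws, for every time step, the number k of simultaneously firing neurons
#' from a prescribed distribution and then marks k distinct neurons chosen
#' uniformly. Used as the generator half of generator/fitter closure tests
#' and as a simulation-free input to the analysis pipeline.
#'
#' Laws (all normalized over their support):
#' * `silent` — k = 0 always.
#' * `exponential` — active steps draw k on 1..N with P(k) proportional to
#'   `exp(-k/s0)`.
#' * `power` — active steps draw k on 1..N with P(k) proportional to
#'   `k^-tau`.
#' * `ictal` — active steps are fully synchronized (k = N) with probability
#'   `sync_prob`, else k is uniform on 1..N.
#'
#' @param law one of `"silent"`, `"exponential"`, `"power"`, `"ictal"`.
#' @param params list: `s0` (exponential), `tau` (power), `sync_prob`
#'   (ictal); optional `p_active`, the fraction of non-silent steps
#'   (default 0.5; ignored for `silent`).
#' @param n_neurons,n_steps raster dimensions.
#' @param seed integer seed.
#' @return a `critnet_raster` (with `dt = 1` and the generating law recorded
#'   in `mode`).
#' @export
synthesize_raster <- function(law = c("silent", "exponential", "power",
                                      "ictal"),
                              params = list(), n_neurons, n_steps, seed) {
  law <- match.arg(law)
  p_active <- params$p_active %||% 0.5
  if (p_active < 0 || p_active > 1) stop("p_active must lie in [0, 1]")
  N <- as.integer(n_neurons)
  kk <- seq_len(N)
  pk <- switch(law,
    silent = NULL,
    exponential = {
      if (is.null(params$s0) || params$s0 <= 0)
        stop("exponential law needs params$s0 > 0")
      exp(-kk / params$s0)
    },
    power = {
      if (is.null(params$tau)) stop("power law needs params$tau")
      kk^(-params$tau)
    },
    ictal = {
      sp <- params$sync_prob
      if (is.null(sp) || sp < 0 || sp > 1)
        stop("ictal law needs params$sync_prob in [0, 1]")
      p <- rep((1 - sp) / N, N)
      p[N] <- p[N] + sp
      p
    })
  firing <- local_seed(seed, {
    k <- integer(n_steps)
    if (law != "silent") {
      active <- stats::runif(n_steps) < p_active
      k[active] <- sample(kk, sum(active), replace = TRUE,
                          prob = pk / sum(pk))
    }
    out <- matrix(FALSE, N, n_steps)
    for (t in which(k > 0)) out[sample.int(N, k[t]), t] <- TRUE
    out
  })
  structure(list(firing = firing, dt = 1, threshold = NA_real_, mode = law),
            class = "critnet_raster")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a raster as dense 0/1 CSV
#'
#' One row per neuron, one column per time step, with a single header line
#' `# neurons <N> steps <T> dt <dt> threshold <thr> mode <mode>`.
#'
#' @param raster a `critnet_raster`.
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` a
#'   `critnet_raster`.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# neurons %d steps %d dt %g threshold %s mode %s",
                     nrow(raster$firing), ncol(raster$firing), raster$dt,
                     format(raster$threshold), raster$mode), con)
  utils::write.table(raster$firing * 1L, con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# neurons", hdr)) stop("missing raster header line")
  tok <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
  val <- function(name) tok[which(tok == name) + 1L]
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 1))
  if (any(!m %in% c(0, 1))) stop("raster cells must be 0 or 1")
  dimnames(m) <- NULL
  structure(list(firing = m == 1, dt = as.numeric(val("dt")),
                 threshold = suppressWarnings(as.numeric(val("threshold"))),
                 mode = val("mode")),
            class = "critnet_raster")
}
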