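#' Synaptic transfer-function parameters
#'
#' Presynaptic voltage is mapped to a normalized drive through
#' \eqn{f(V) = \tfrac12\left(1 + \tanh\frac{V - \theta_{syn}}{\sigma_{syn}}\right)},
#' so a neuron contributes essentially nothing at rest and its full weight
#' near the spike peak. `i_scale` converts the weighted sum of drives into
#' injected current.
#'
#' @param theta_syn half-activation voltage, mV (default 0, the spike-peak
#'   region).
#' @param sigma_syn slope width, mV (> 0, default 5).
#' @param i_scale current per unit summed weight (>= 0, default 1).
#' @return list of class `critnet_transfer`.
#' @export
transfer_params <- function(theta_syn = 0, sigma_syn = 5, i_scale = 1) {
  if (!is.finite(sigma_syn) || sigma_syn <= 0) stop("sigma_syn must be > 0")
  if (!is.finite(i_scale) || i_scale < 0) stop("i_scale must be >= 0")
  structure(list(theta_syn = theta_syn, sigma_syn = sigma_syn,
                 i_scale = i_scale), class = "critnet_transfer")
}

#' Total synaptic current from presynaptic voltages
#'
#' \eqn{I = i_{scale} \sum_i w_i f(V_i)} with `f` the tanh transfer of
#' [transfer_params()]. The result is non-negative and bounded by
#' `i_scale * sum(weights)`.
#'
#' @param presyn_voltages presynaptic voltages, mV.
#' @param incoming_weights synaptic weights, same length.
#' @param transfer a [transfer_params()] object.
#' @return scalar normalized current.
#' @export
synaptic_drive <- function(presyn_voltages, incoming_weights, transfer) {
  if (length(presyn_voltages) != length(incoming_weights))
    stop("presyn_voltages and incoming_weights must have the same length")
  f <- 0.5 * (1 + tanh((presyn_voltages - transfer$theta_syn) /
                         transfer$sigma_syn))
  transfer$i_scale * sum(incoming_weights * f)
}

#' White-noise clamp series for the driver node
#'
#' Independent draws per time step, seeded, with a flat expected spectrum up
#' to Nyquist: Gaussian with the given mean/sd, or uniform on
#' `mean ± sd * sqrt(3)` (matching mean and sd) when `dist = "uniform"`.
#'
#' @param mean,sd clamp mean and standard deviation, mV (`sd >= 0`).
#' @param n_steps number of samples (> 0).
#' @param seed integer seed.
#' @param dist `"gaussian"` (default) or `"uniform"`.
#' @return numeric vector of length `n_steps`.
#' @export
noise_clamp_series <- function(mean, sd, n_steps, seed,
                               dist = c("gaussian", "uniform")) {
  dist <- match.arg(dist)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  if (n_steps < 1) stop("n_steps must be > 0")
  local_seed(seed, switch(dist,
    gaussian = stats::rnorm(n_steps, mean, sd),
    uniform  = stats::runif(n_steps, mean - sd * sqrt(3), mean + sd * sqrt(3))))
}

#' Simulation configuration
#'
#' Collects every knob of a network run: the small-world generation
#' parameters, HH membrane constants, stickiness, synaptic transfer, the
#' white-noise clamp, integration settings and the three seeds (topology,
#' weights, noise) that make a run exactly reproducible. The driver node is
#' always the last node (0-based index `n_free`).
#'
#' @param n_free number of free (integrated) neurons; total nodes is
#'   `n_free + 1` including the clamped driver.
#' @param k,rewire_prob Watts-Strogatz ring degree and rewiring probability.
#' @param g_max maximum synaptic weight (weights are uniform on \[0, g_max\]).
#' @param stickiness sodium-inactivation stickiness s (> 0); 1 is the
#'   physiological value, larger is slower inactivation.
#' @param hh a [hh_params()] set.
#' @param transfer a [transfer_params()] set.
#' @param noise_mean,noise_sd driver clamp mean and sd, mV.
#' @param noise_dist `"gaussian"` or `"uniform"`.
#' @param dt integration step, ms.
#' @param duration total simulated time, ms (must exceed `burn_in`).
#' @param burn_in initial interval dropped by downstream analysis, ms.
#' @param V0 initial voltage of free neurons, mV.
#' @param firing_threshold raster threshold, mV.
#' @param topology_seed,weight_seed,noise_seed integer seeds.
#' @return list of class `critnet_config`.
#' @export
sim_config <- function(n_free = 12, k = 4, rewire_prob = 0.3,
                       g_max = 2.5, stickiness = 1,
                       hh = hh_params(), transfer = transfer_params(),
                       noise_mean = -60, noise_sd = 25,
                       noise_dist = "gaussian",
                       dt = 0.1, duration = 10000, burn_in = 500,
                       V0 = -64, firing_threshold = 0,
                       topology_seed = 1L, weight_seed = 1L,
                       noise_seed = 1L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(duration) || !is.finite(burn_in) ||
      burn_in < 0 || duration <= burn_in)
    stop("need duration > burn_in >= 0")
  if (!is.finite(stickiness) || stickiness <= 0)
    stop("stickiness must be > 0")
  if (!is.finite(g_max) || g_max < 0) stop("g_max must be >= 0")
  structure(
    list(n_free = as.integer(n_free), k = as.integer(k),
         rewire_prob = rewire_prob, g_max = g_max, stickiness = stickiness,
         hh = hh, transfer = transfer,
         noise_mean = noise_mean, noise_sd = noise_sd,
         noise_dist = noise_dist,
         dt = dt, duration = duration, burn_in = burn_in, V0 = V0,
         firing_threshold = firing_threshold,
         topology_seed = as.integer(topology_seed),
         weight_seed = as.integer(weight_seed),
         noise_seed = as.integer(noise_seed)),
    class = "critnet_config")
}

#' @export
print.critnet_config <- function(x, ...) {
  cat(sprintf(paste0("network run config: %d free neurons + driver, k = %d,",
                     " p = %g, g_max = %g, s = %g\n"),
              x$n_free, x$k, x$rewire_prob, x$g_max, x$stickiness))
  cat(sprintf("  %g ms at dt = %g ms (burn-in %g ms), noise N(%g, %g^2)\n",
              x$duration, x$dt, x$burn_in, x$noise_mean, x$noise_sd))
  cat(sprintf("  seeds: topology %d, weights %d, noise %d\n",
              x$topology_seed, x$weight_seed, x$noise_seed))
  invisible(x)
}

# build the connectome a config describes (driver = last node)
config_connectome <- function(config) {
  top <- generate_small_world(config$n_free + 1L, config$k,
                              config$rewire_prob, config$topology_seed)
  assign_weights(top, config$g_max, config$weight_seed)
}

#' Integrate the full network
#'
#' Runs the per-step loop: the driver node's voltage is overwritten from the
#' seeded white-noise series, every free neuron receives the tanh-transfer
#' synaptic current of its in-edges, and its gates and membrane voltage
#' advance by one forward-Euler step. Gates start at their steady state for
#' `V0`. The returned matrix includes the burn-in interval; analysis
#' functions drop it downstream.
#'
#' @param config a [sim_config()].
#' @param connectome optional pre-built [assign_weights()] connectome (for
#'   frozen-network sweeps); defaults to the one the config's seeds generate.
#' @return object of class `critnet_traces`: `voltages`
#'   (`n_nodes x n_steps`, mV), `dt`, `clamped_node` (0-based), `config`.
#' @export
run_network <- function(config, connectome = NULL) {
  stopifnot(inherits(config, "critnet_config"))
  if (is.null(connectome)) connectome <- config_connectome(config)
  n <- connectome$topology$n_nodes
  clamped <- n - 1L
  n_steps <- round(config$duration / config$dt)
  noise <- noise_clamp_series(config$noise_mean, config$noise_sd, n_steps,
                              config$noise_seed, config$noise_dist)
  z <- steady_state(config$V0, config$stickiness)
  hh <- config$hh; tr <- config$transfer
  V <- .run_network_cpp(weight_matrix(connectome), clamped, noise,
                        rep(config$V0, n), rep(z$m_inf, n), rep(z$n_inf, n),
                        rep(z$h_inf, n),
                        hh$C, hh$g_Na, hh$g_K, hh$g_leak,
                        hh$V_Na, hh$V_K, hh$V_leak,
                        config$stickiness, tr$theta_syn, tr$sigma_syn,
                        tr$i_scale, config$dt)
  structure(list(voltages = V, dt = config$dt, clamped_node = clamped,
                 config = config),
            class = "critnet_traces")
}

#' @export
print.critnet_traces <- function(x, ...) {
  cat(sprintf("voltage traces: %d nodes x %d steps (dt = %g ms, driver node %d)\n",
              nrow(x$voltages), ncol(x$voltages), x$dt, x$clamped_node))
  invisible(x)
}

#' Sweep one parameter on a frozen network
#'
#' Reruns the simulation for each value of one control axis while the
#' topology, weights and noise seeds stay fixed, so only the swept parameter
#' differs between runs.
#'
#' @param base a [sim_config()] supplying everything but the swept value.
#' @param axis one of `"stickiness"`, `"g_max"`, `"firing_threshold"`,
#'   `"noise_sd"`.
#' @param values numeric vector of parameter values.
#' @return list of `list(value =, traces =)` in the order of `values`.
#' @export
parameter_sweep <- function(base, axis, values) {
  axes <- c("stickiness", "g_max", "firing_threshold", "noise_sd")
  if (!axis %in% axes)
    stop("unknown sweep axis '", axis, "'; must be one of: ",
         paste(axes, collapse = ", "))
  topology <- generate_small_world(base$n_free + 1L, base$k,
                                   base$rewire_prob, base$topology_seed)
  lapply(values, function(v) {
    cfg <- base
    cfg[[axis]] <- v
    conn <- assign_weights(topology, cfg$g_max, cfg$weight_seed)
    list(value = v, traces = run_network(cfg, connectome = conn))
  })
}
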