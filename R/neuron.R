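#' Hodgkin-Huxley membrane parameters
#'
#' Parameter set for the conductance-based membrane equation
#' \deqn{C \frac{dV}{dt} = -m^3 h\, g_{Na}(V - V_{Na}) - n^4 g_K (V - V_K)
#'   - g_{leak}(V - V_{leak}) + I_{inject}}
#' in normalized conductance/current units with voltages in mV and time in
#' ms. Two profiles are provided: `"classic"`, the reduced-conductance set
#' this package is built around (C = 1, g_Na = 20, g_K = 12, g_leak = 0.05,
#' V_Na = 50, V_K = -90, V_leak = -60), and `"textbook"`, the canonical
#' squid-axon constants (C = 1, g_Na = 120, g_K = 36, g_leak = 0.3,
#' V_Na = 50, V_K = -77, V_leak = -54.4) offered as an approximate
#' alternative parameterization.
#'
#' @param C membrane capacitance (normalized, > 0).
#' @param g_Na,g_K,g_leak maximal conductances (normalized, >= 0).
#' @param V_Na,V_K,V_leak reversal potentials, mV.
#' @param profile convenience preset; explicit arguments override it.
#' @return a named list of class `critnet_hh`.
#' @export
hh_params <- function(C = NULL, g_Na = NULL, g_K = NULL, g_leak = NULL,
                      V_Na = NULL, V_K = NULL, V_leak = NULL,
                      profile = c("classic", "textbook")) {
  profile <- match.arg(profile)
  base <- switch(profile,
    classic  = list(C = 1, g_Na = 20, g_K = 12, g_leak = 0.05,
                    V_Na = 50, V_K = -90, V_leak = -60),
    textbook = list(C = 1, g_Na = 120, g_K = 36, g_leak = 0.3,
                    V_Na = 50, V_K = -77, V_leak = -54.4))
  override <- list(C = C, g_Na = g_Na, g_K = g_K, g_leak = g_leak,
                   V_Na = V_Na, V_K = V_K, V_leak = V_leak)
  for (nm in names(override))
    if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  if (base$C <= 0) stop("C must be > 0")
  if (any(unlist(base[c("g_Na", "g_K", "g_leak")]) < 0))
    stop("conductances must be >= 0")
  structure(base, class = "critnet_hh")
}

# x / (1 - exp(-x)), stable through the removable singularity at x = 0
.vtrap <- function(x) {
  out <- ifelse(abs(x) < 1e-6, 1 / (1 - x / 2), x / (-expm1(-x)))
  out
}

#' Voltage-dependent gating rate constants
#'
#' Evaluates the six opening/closing rates (ms^-1) of the m (Na+ activation),
#' n (K+ activation) and h (Na+ inactivation) gates at membrane voltage `V`:
#' \deqn{\alpha_m = \frac{0.1(V+40)}{1 - e^{-0.1(V+40)}},\quad
#'   \beta_m = 4 e^{-0.05(V+65)}}
#' \deqn{\alpha_n = \frac{0.01(V+55)}{1 - e^{-0.1(V+55)}},\quad
#'   \beta_n = 0.25 e^{-0.0125(V+65)}}
#' \deqn{\alpha_h = 0.07 e^{-0.05(V+65)} / s,\quad
#'   \beta_h = \frac{1}{e^{-0.1(V+35)} + 1} / s}
#' The stickiness `s` rescales only the h-gate kinetics: both rates are
#' divided by `s`, so the inactivation time constant is stretched from
#' \eqn{\tau_h} to \eqn{s \tau_h} while the steady state \eqn{h_\infty}
#' is unchanged. `s > 1` means slower ("stickier") sodium inactivation.
#' The removable singularities of \eqn{\alpha_m} (V = -40) and
#' \eqn{\alpha_n} (V = -55) are evaluated by their series limit.
#'
#' @param V membrane voltage, mV (finite; vectorized).
#' @param s stickiness, dimensionless, > 0.
#' @return list with components `alpha_m`, `beta_m`, `alpha_n`, `beta_n`,
#'   `alpha_h`, `beta_h` (each the length of `V`) and `s`.
#' @examples
#' r <- rate_constants(-65, s = 1)
#' r$alpha_m  # ~0.2236
#' @export
rate_constants <- function(V, s = 1) {
  if (any(!is.finite(V))) stop("V must be finite")
  if (!is.finite(s) || s <= 0) stop("stickiness s must be > 0")
  list(
    alpha_m = .vtrap(0.1 * (V + 40)),
    beta_m  = 4 * exp(-0.05 * (V + 65)),
    alpha_n = 0.1 * .vtrap(0.1 * (V + 55)),
    beta_n  = 0.25 * exp(-0.0125 * (V + 65)),
    alpha_h = 0.07 * exp(-0.05 * (V + 65)) / s,
    beta_h  = 1 / (exp(-0.1 * (V + 35)) + 1) / s,
    s = s)
}

#' Gating steady states and time constants
#'
#' For each gate z in {m, n, h}: \eqn{z_\infty = \alpha_z/(\alpha_z+\beta_z)}
#' and \eqn{\tau_z = 1/(\alpha_z+\beta_z)} (ms). Because stickiness divides
#' both h rates, \eqn{\tau_h(s) = s\,\tau_h(1)} and \eqn{h_\infty} does not
#' depend on `s`.
#'
#' @inheritParams rate_constants
#' @return list with `m_inf`, `n_inf`, `h_inf`, `tau_m`, `tau_n`, `tau_h`.
#' @export
steady_state <- function(V, s = 1) {
  r <- rate_constants(V, s)
  list(m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
       n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
       h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
       tau_m = 1 / (r$alpha_m + r$beta_m),
       tau_n = 1 / (r$alpha_n + r$beta_n),
       tau_h = 1 / (r$alpha_h + r$beta_h))
}

#' One forward-Euler step of the gating ODEs
#'
#' Advances each gate by \eqn{z' = z + dt\,(\alpha_z (1-z) - \beta_z z)} and
#' clamps the result to \[0, 1\] (forward Euler can overshoot at coarse dt).
#'
#' @param state list with numeric `m`, `n`, `h` (each in \[0,1\], vectorized).
#' @param rates output of [rate_constants()] at the current voltage(s).
#' @param dt time step, ms (> 0).
#' @return list with updated `m`, `n`, `h`.
#' @export
gating_step <- function(state, rates, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  step1 <- function(z, a, b) pmin(1, pmax(0, z + dt * (a * (1 - z) - b * z)))
  list(m = step1(state$m, rates$alpha_m, rates$beta_m),
       n = step1(state$n, rates$alpha_n, rates$beta_n),
       h = step1(state$h, rates$alpha_h, rates$beta_h))
}

#' One forward-Euler step of the membrane equation
#'
#' \eqn{V' = V + \frac{dt}{C}\left(-m^3 h\,g_{Na}(V-V_{Na}) - n^4 g_K(V-V_K)
#' - g_{leak}(V-V_{leak}) + I_{inject}\right)}; positive `I_inject`
#' depolarizes.
#'
#' @param state list with `V`, `m`, `n`, `h` (vectorized).
#' @param params a [hh_params()] set.
#' @param I_inject injected/synaptic current, normalized units.
#' @param dt time step, ms (> 0).
#' @return updated voltage(s), mV.
#' @export
membrane_step <- function(state, params, I_inject = 0, dt = 0.1) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  dV <- -state$m^3 * state$h * params$g_Na * (state$V - params$V_Na) -
    state$n^4 * params$g_K * (state$V - params$V_K) -
    params$g_leak * (state$V - params$V_leak) + I_inject
  V <- state$V + dt / params$C * dV
  if (any(!is.finite(V)))
    stop("membrane_step: non-finite voltage (numerical blow-up) at index ",
         which(!is.finite(V))[1])
  V
}

#' Simulate one isolated neuron under a current protocol
#'
#' Gates are initialized at their steady-state values for `V0`; each sample
#' applies one [gating_step()] followed by one [membrane_step()] with the
#' corresponding protocol current.
#'
#' @param params a [hh_params()] set.
#' @param s stickiness (> 0).
#' @param I_protocol numeric vector of injected currents, one per step.
#' @param dt time step, ms.
#' @param V0 initial voltage, mV (default -64).
#' @return numeric voltage trace, one value per protocol sample (the voltage
#'   after each step).
#' @export
simulate_single_neuron <- function(params, s = 1, I_protocol, dt = 0.1,
                                   V0 = -64) {
  if (length(I_protocol) < 1) stop("I_protocol must be nonempty")
  z <- steady_state(V0, s)
  st <- list(V = V0, m = z$m_inf, n = z$n_inf, h = z$h_inf)
  out <- numeric(length(I_protocol))
  for (i in seq_along(I_protocol)) {
    r <- rate_constants(st$V, s)
    g <- gating_step(st, r, dt)
    st$m <- g$m; st$n <- g$n; st$h <- g$h
    st$V <- membrane_step(st, params, I_protocol[i], dt)
    out[i] <- st$V
  }
  out
}
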