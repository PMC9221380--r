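#' Calcium-gated AHP activation
#'
#' Saturating gate `r = ca / (ca + kd)` of the after-hyperpolarisation
#' potassium conductance; the AHP current is
#' `I_AHP = g_ahp * r * (V - V_K)`.
#'
#' @param ca cytosolic calcium, uM (>= 0); vectorised.
#' @param kd half-saturation, uM.
#' @return activation in \[0, 1\].
#' @export
ahp_gate <- function(ca, kd = 1) {
  if (any(ca < 0)) stop("calcium must be >= 0", call. = FALSE)
  ca / (ca + kd)
}

#' Voltage-dependent drive of the calcium steady state
#'
#' `(v_ca - v) / (1 + exp(-(v + 25)/2.5))` in mV: the sigmoidal
#' activation of voltage-gated calcium entry times the driving force.
#' Its maximum over voltage (132.58 mV for `v_ca` = 120 mV) defines the
#' calcium ceiling `M_Ca` (see [m_ca()]).
#'
#' @param v membrane voltage, mV; vectorised.
#' @param v_ca calcium reversal potential, mV.
#' @return drive in mV.
#' @export
ca_drive_factor <- function(v, v_ca = 120) {
  (v_ca - v) / (1 + exp(-(v + 25) / 2.5))
}

#' Calcium steady state at fixed voltage
#'
#' `(M_Ca / peak_drive) * ca_drive_factor(v)`: relaxation target of the
#' cytosolic calcium concentration; its maximum over voltage equals
#' `M_Ca` = 42.4 uM at the default parameters.
#'
#' @param v membrane voltage, mV; vectorised.
#' @param params an [lc_neuron_params()] object.
#' @return steady-state calcium, uM.
#' @export
calcium_steady_state <- function(v, params = lc_neuron_params()) {
  params$f_ca * params$k_ca * params$tau_ca *
    ca_drive_factor(v, params$v_ca)
}

#' Exact exponential calcium update
#'
#' One step of the linear relaxation
#' `ca_{i+1} = ca_inf + (ca_i - ca_inf) exp(-dt/tau_ca)` toward
#' [calcium_steady_state()] at the (frozen) voltage `v`. Being the exact
#' solution of the relaxation ODE, composing two half steps equals one
#' full step to machine precision.
#'
#' @param ca current calcium, uM.
#' @param v membrane voltage, mV.
#' @param dt time step, ms (> 0).
#' @param params an [lc_neuron_params()] object.
#' @return updated calcium, uM.
#' @export
calcium_update <- function(ca, v, dt, params = lc_neuron_params()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  ca_inf <- calcium_steady_state(v, params)
  ca_inf + (ca - ca_inf) * exp(-dt / params$tau_ca)
}

#' Initial state of one neuron
#'
#' State variables: somatic and dendritic voltage (mV), sodium
#' inactivation `h`, potassium activation `n` (both in \[0,1\]) and
#' cytosolic calcium (uM).
#'
#' @param v_s,v_d initial voltages, mV.
#' @param h,n initial gating values; defaults are their steady states
#'   at `v_s`.
#' @param ca initial calcium, uM.
#' @param params an [lc_neuron_params()] object.
#' @return named numeric vector of length 5.
#' @export
lc_initial_state <- function(params = lc_neuron_params(), v_s = -60,
                             v_d = -60, h = NULL, n = NULL, ca = 0.05) {
  if (ca < 0) stop("calcium must be >= 0", call. = FALSE)
  if (is.null(h)) h <- gate_inf(v_s, params$theta_h, params$sigma_h)
  if (is.null(n)) n <- gate_inf(v_s, params$theta_n, params$sigma_n)
  c(v_s = v_s, v_d = v_d, h = h, n = n, ca = ca)
}

gate_inf <- function(v, theta, sigma) 1 / (1 + exp(-(v - theta) / sigma))

tau_gate <- function(v, t0, t1, tv, ts) t0 + t1 / (1 + exp((v - tv) / ts))

#' Somatic membrane currents and voltage derivative
#'
#' Evaluates every somatic current at the given state and returns the
#' voltage rate of change
#' `dV_S/dt = (I_elec - I_Na - I_K - I_P - I_AHP - I_Ca - I_GIRK - I_dend - I_L + noise)/c_m`.
#' The GIRK current is `g_girk_total * (V_S - V_GIRK)` with the total
#' GIRK conductance supplied by the caller (see [girk_conductance()]).
#'
#' @param state a state vector from [lc_initial_state()].
#' @param params an [lc_neuron_params()] object.
#' @param i_elec electrode current density, uA/cm^2.
#' @param g_girk_total total GIRK conductance, mS/cm^2 (>= 0).
#' @param noise instantaneous noise current, uA/cm^2.
#' @return `dV_S/dt` in mV/ms, with the current decomposition as an
#'   attribute `"currents"`.
#' @export
soma_derivative <- function(state, params = lc_neuron_params(), i_elec = 0,
                            g_girk_total = 0, noise = 0) {
  if (any(!is.finite(state)))
    stop("non-finite state: numerical blow-up (try a smaller dt)",
         call. = FALSE)
  if (g_girk_total < 0) stop("g_girk_total must be >= 0", call. = FALSE)
  v <- state[["v_s"]]
  minf <- gate_inf(v, params$theta_m, params$sigma_m)
  pinf <- gate_inf(v, params$theta_p, params$sigma_p)
  cur <- c(
    i_na = params$g_na * minf^3 * state[["h"]] * (v - params$v_na),
    i_k = params$g_k * state[["n"]]^4 * (v - params$v_k),
    i_p = params$g_p * pinf * (v - params$v_na),
    i_ahp = params$g_ahp * ahp_gate(state[["ca"]], params$ahp_kd) *
      (v - params$v_k),
    i_ca = params$g_ca * (v - params$v_ca),
    i_girk = g_girk_total * (v - params$v_girk),
    i_dend = params$g_sd * (v - state[["v_d"]]),
    i_l = params$g_l * (v - params$v_l)
  )
  structure((i_elec - sum(cur) + noise) / params$cm, currents = cur)
}

#' Dendritic voltage derivative
#'
#' `dV_D/dt = -(I_soma + I_GJ + I_LD)/c_m` with `I_soma` the
#' dendrite-side soma coupling current and `I_LD` the dendritic leak.
#'
#' @param state a state vector from [lc_initial_state()].
#' @param params an [lc_neuron_params()] object.
#' @param i_gj gap-junction current from other dendrites, uA/cm^2.
#' @return `dV_D/dt` in mV/ms.
#' @export
dendrite_derivative <- function(state, params = lc_neuron_params(),
                                i_gj = 0) {
  if (any(!is.finite(state)))
    stop("non-finite state: numerical blow-up (try a smaller dt)",
         call. = FALSE)
  vd <- state[["v_d"]]
  i_soma <- params$g_ds * (vd - state[["v_s"]])
  i_ld <- params$g_ld * (vd - params$v_ld)
  -(i_soma + i_gj + i_ld) / params$cm
}

#' One integration step of a single neuron (reference implementation)
#'
#' Advances the state by `dt` using the scheme of the compiled
#' integrator: exponential-Euler updates for gating and calcium,
#' explicit Euler for the voltages. This pure-R stepper exists as a
#' readable reference and cross-check of the compiled core; use
#' [lc_simulate()] for anything longer than a few hundred milliseconds.
#'
#' @param state a state vector from [lc_initial_state()].
#' @param params an [lc_neuron_params()] object.
#' @param dt time step, ms.
#' @param i_elec electrode current density, uA/cm^2.
#' @param g_girk_total total GIRK conductance, mS/cm^2.
#' @param noise instantaneous noise current, uA/cm^2.
#' @param i_gj gap-junction current, uA/cm^2.
#' @return the advanced state vector.
#' @export
lc_step <- function(state, params = lc_neuron_params(), dt = 0.025,
                    i_elec = 0, g_girk_total = 0, noise = 0, i_gj = 0) {
  dvs <- soma_derivative(state, params, i_elec, g_girk_total, noise)
  dvd <- dendrite_derivative(state, params, i_gj)
  v <- state[["v_s"]]
  hinf <- gate_inf(v, params$theta_h, params$sigma_h)
  tauh <- tau_gate(v, params$tau_h0, params$tau_h1, params$tau_h_v,
                   params$tau_h_s)
  ninf <- gate_inf(v, params$theta_n, params$sigma_n)
  taun <- tau_gate(v, params$tau_n0, params$tau_n1, params$tau_n_v,
                   params$tau_n_s)
  out <- c(
    v_s = v + dt * as.numeric(dvs),
    v_d = state[["v_d"]] + dt * dvd,
    h = hinf + (state[["h"]] - hinf) * exp(-dt / tauh),
    n = ninf + (state[["n"]] - ninf) * exp(-dt / taun),
    ca = calcium_update(state[["ca"]], v, dt, params)
  )
  if (any(!is.finite(out)))
    stop("numerical blow-up during step (try a smaller dt)", call. = FALSE)
  out
}

#' Simulate a single LC neuron
#'
#' Convenience wrapper that runs the compiled network integrator with a
#' single unconnected neuron.
#'
#' @param params an [lc_neuron_params()] object.
#' @param protocol a [stimulus_protocol()] (empty for spontaneous
#'   activity).
#' @param duration_ms simulated time, ms.
#' @param dt integration step, ms.
#' @param record_dt trace sampling interval, ms.
#' @param noise logical; apply the white-noise current?
#' @param state0 initial state, from [lc_initial_state()].
#' @param seed optional integer seed applied before the run.
#' @return an `lc_sim` object; see [run_scenario()].
#' @examples
#' sim <- lc_simulate(duration_ms = 2000, seed = 1)
#' length(sim$spikes[[1]]) / 2   # spontaneous rate, Hz
#' @export
lc_simulate <- function(params = lc_neuron_params(),
                        protocol = stimulus_protocol(),
                        duration_ms = 5000, dt = 0.025, record_dt = 1,
                        noise = TRUE, state0 = lc_initial_state(params),
                        seed = NULL) {
  cfg <- network_config(neurons = list(params), protocols = list(protocol),
                        duration_ms = duration_ms, dt = dt,
                        record_dt = record_dt, noise = noise, seed = seed)
  run_scenario(cfg, state0 = matrix(state0, nrow = 1))
}
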