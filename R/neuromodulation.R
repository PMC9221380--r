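#' Calcium-dependent NE release fraction
#'
#' Weight of a quantal release triggered by a presynaptic action
#' potential, as a saturating function of cytosolic calcium at spike
#' time: `R_rel(ca) = 2 ca^k / (ca_high^k + ca^k)`. Equals 1 at
#' `ca = ca_high` (the 20-Hz calcium level) and saturates at 2; the
#' factor 2 is part of the model definition and is deliberately not
#' renormalised. Graded release: there is no hard threshold — low
#' resting calcium simply carries a small weight.
#'
#' @param ca_ap presynaptic calcium at spike time, uM (>= 0); vectorised.
#' @param params a [release_params()] object.
#' @return unitless release weight in \[0, 2).
#' @export
release_fraction <- function(ca_ap, params = release_params()) {
  if (any(ca_ap < 0)) stop("calcium must be >= 0", call. = FALSE)
  2 * ca_ap^params$k_rel /
    (params$ca_high^params$k_rel + ca_ap^params$k_rel)
}

#' GIRK open-probability kernel after one release event
#'
#' Normalised double exponential
#' `P_open(t) = B (exp(-(t - t_ap)/tau_slow) - exp(-(t - t_ap)/tau_fast))`
#' for `t >= t_ap` (0 before), with `B` such that the peak — reached at
#' `t_peak = tau_f tau_s / (tau_s - tau_f) log(tau_s/tau_f)` — equals 1.
#'
#' @param t time, ms; vectorised.
#' @param t_ap release (spike) time, ms.
#' @param params a [girk_params()] object.
#' @return open probability in \[0, 1\].
#' @export
girk_open_prob <- function(t, t_ap = 0, params = girk_params()) {
  s <- t - t_ap
  out <- ifelse(s <= 0, 0,
                params$B * (exp(-s / params$tau_slow) -
                              exp(-s / params$tau_fast)))
  pmax(out, 0)
}

#' Voltage rectification of the GIRK conductance
#'
#' `G_rect(V) = g_max / (1 + exp(slope (V - V_GIRK)))` in uS/mm^2:
#' half-maximal at the GIRK reversal, saturating at `g_max` with
#' hyperpolarisation.
#'
#' @param v postsynaptic membrane voltage, mV; vectorised.
#' @param params a [girk_params()] object.
#' @return conductance in uS/mm^2.
#' @export
girk_rectification <- function(v, params = girk_params()) {
  params$g_max / (1 + exp(params$slope * (v - params$v_girk)))
}

#' Total GIRK conductance from a train of release events
#'
#' Linear superposition over release events of the open-probability
#' kernel weighted by the per-event release fraction, rectified at the
#' postsynaptic voltage:
#' `g = G_rect(v) * sum_i P_open(t - t_i) R_rel(ca_i)`.
#'
#' @param v_post postsynaptic voltage, mV.
#' @param t evaluation time, ms; vectorised.
#' @param events a data frame of release events with columns `t_ap_ms`
#'   and `ca_ap_uM`, sorted by time.
#' @param params a [girk_params()] object.
#' @param release a [release_params()] object.
#' @return conductance in uS/mm^2 (>= 0).
#' @export
girk_conductance <- function(v_post, t, events, params = girk_params(),
                             release = release_params()) {
  if (nrow(events) == 0) return(rep(0, length(t)))
  if (is.unsorted(events$t_ap_ms))
    stop("release events must be sorted by time", call. = FALSE)
  w <- release_fraction(events$ca_ap_uM, release)
  psum <- vapply(t, function(ti)
    sum(w * girk_open_prob(ti, events$t_ap_ms, params)), numeric(1))
  girk_rectification(v_post, params) * psum
}

#' GIRK current onto a postsynaptic neuron
#'
#' `I_GIRK = (V_S - V_GIRK) * sum_j S_ij * g_j` where `g_j` is the
#' per-source rectified conductance from [girk_conductance()] and
#' `S_ij >= 0` the synaptic strengths. Hyperpolarising (positive,
#' outward) whenever `V_S > V_GIRK`.
#'
#' @param v_post postsynaptic somatic voltage, mV.
#' @param t evaluation time, ms (scalar).
#' @param events_by_source list (one element per source) of release
#'   event data frames as in [girk_conductance()].
#' @param s_row numeric vector of synaptic strengths, one per source.
#' @param params a [girk_params()] object.
#' @param release a [release_params()] object.
#' @return current in the conductance units times mV.
#' @export
girk_current <- function(v_post, t, events_by_source, s_row,
                         params = girk_params(),
                         release = release_params()) {
  if (any(s_row < 0)) stop("synaptic strengths must be >= 0", call. = FALSE)
  stopifnot(length(events_by_source) == length(s_row))
  g <- sum(vapply(seq_along(s_row), function(j) {
    if (s_row[j] == 0) return(0)
    s_row[j] * girk_conductance(v_post, t, events_by_source[[j]],
                                params, release)
  }, numeric(1)))
  (v_post - params$v_girk) * g
}
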