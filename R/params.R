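#' Parameters of the two-compartment LC neuron
#'
#' Builds the full parameter set of the conductance-based locus coeruleus
#' (LC) neuron: a somatic compartment carrying spike currents (transient
#' sodium, delayed-rectifier potassium, persistent sodium), a
#' calcium-gated after-hyperpolarisation (AHP) potassium current, leak,
#' the GIRK current driven by alpha2-receptor activation, and a passive
#' dendritic compartment coupled to the soma and (optionally) to other
#' dendrites through gap junctions.
#'
#' Units are the usual conductance-based system: mV, ms, uM,
#' mS/cm^2, uA/cm^2, uF/cm^2. The calcium subsystem follows the
#' voltage-dependent steady state
#' \deqn{[Ca]_\infty(V) = f_{Ca} k_{Ca} \tau_{Ca} \frac{V_{Ca}-V}{1+e^{-(V+25)/2.5}}}
#' with `f_ca` = 0.002 uM/(mV ms), `k_ca` = 2 and `tau_ca` = 80 ms, so that
#' its maximum over voltage equals `M_Ca` = `f_ca * k_ca * tau_ca * 132.58 mV`
#' = 42.4 uM (see [m_ca()]).
#'
#' The default maximal conductances and gating kinetics are
#' cortical-type Hodgkin-Huxley rate functions tuned so that the neuron
#' is an intrinsic pacemaker at 4.3 Hz, the frequency-current relation
#' is close to linear, and the cytosolic calcium plateau at 20 Hz firing
#' is 1.3 uM.
#'
#' @param ... named overrides for any parameter, e.g. `g_ahp = 3`.
#' @return an object of class `lc_neuron_params` (a named list).
#' @examples
#' p <- lc_neuron_params(g_p = 0.1)
#' p$g_p
#' @export
lc_neuron_params <- function(...) {
  p <- list(
    # passive / structural
    cm = 1,            # uF/cm^2
    area_cm2 = 0.027,  # nominal somatic normalisation area (current mapping)
    g_l = 0.04,        # somatic leak, mS/cm^2
    v_l = -50,         # mV
    g_ld = 0.05,       # dendritic leak
    v_ld = -60,
    g_sd = 0.08,       # soma -> dendrite coupling (on soma area)
    g_ds = 0.16,       # dendrite-side coupling (soma/dendrite area ratio 2)
    # spike currents
    g_na = 24, v_na = 55,
    g_k = 4.8, v_k = -90,
    g_p = 0.30,        # persistent sodium (pacemaker drive)
    g_ca = 0,          # electrical Ca current folded into calcium dynamics
    v_ca = 120,
    # AHP / calcium
    g_ahp = 0.95,
    ahp_kd = 1,        # uM half-saturation of the AHP gate
    f_ca = 0.002,      # uM/(mV ms)
    k_ca = 2,
    tau_ca = 80,       # ms
    # release and GIRK coupling
    ca_high = 1.3,     # uM
    k_rel = 1,
    v_girk = -90,      # defaults to potassium reversal
    girk_scale = 0.02, # 0.2 uS/mm^2 expressed in mS/cm^2
    rect_slope = 0.05, # 1/mV
    # gating kinetics (cortical-type)
    theta_m = -30, sigma_m = 9.5,
    theta_h = -45, sigma_h = -7,
    tau_h0 = 0.6, tau_h1 = 7.0, tau_h_v = -40.5, tau_h_s = 6,
    theta_n = -30, sigma_n = 10,
    tau_n0 = 1.6, tau_n1 = 4.5, tau_n_v = -27, tau_n_s = 15,
    theta_p = -56, sigma_p = 3,
    # noise and spike detection
    noise_amp = 0.25,  # uA/cm^2 (white, zero mean)
    spike_thresh = 0,  # mV upward crossing
    refractory = 2     # ms lockout
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(p))
    if (length(bad))
      stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(override)] <- override
  }
  validate_neuron_params(p)
  structure(p, class = "lc_neuron_params")
}

validate_neuron_params <- function(p) {
  conds <- c("g_na", "g_k", "g_p", "g_ahp", "g_l", "g_ld", "g_ca",
             "g_sd", "g_ds", "girk_scale")
  for (nm in conds)
    if (p[[nm]] < 0) stop("conductance '", nm, "' must be >= 0", call. = FALSE)
  if (p$tau_ca <= 0) stop("tau_ca must be > 0", call. = FALSE)
  if (p$cm <= 0) stop("cm must be > 0", call. = FALSE)
  # internal consistency of the calcium formulation: M_Ca must equal
  # f_ca * k_ca * tau_ca * (peak of the voltage drive) to within 0.1%
  mca <- m_ca(p)
  target <- p$f_ca * p$k_ca * p$tau_ca * ca_drive_peak(p$v_ca)
  if (abs(mca - target) > 1e-3 * target)
    stop("calcium parameters are internally inconsistent", call. = FALSE)
  invisible(p)
}

#' Derived calcium ceiling M_Ca
#'
#' The maximum over voltage of the calcium steady state,
#' `M_Ca = f_ca * k_ca * tau_ca * max_V drive(V)`; 42.4 uM at the
#' defaults.
#'
#' @param params an [lc_neuron_params()] object.
#' @return M_Ca in uM.
#' @export
m_ca <- function(params = lc_neuron_params()) {
  params$f_ca * params$k_ca * params$tau_ca * ca_drive_peak(params$v_ca)
}

#' @keywords internal
ca_drive_peak <- function(v_ca = 120) {
  stats::optimize(function(v) ca_drive_factor(v, v_ca),
                  interval = c(-60, v_ca), maximum = TRUE)$objective
}

#' Parameters of calcium-dependent NE release
#'
#' Quantal release is weighted by a saturating function of presynaptic
#' calcium at spike time, `R_rel(ca) = 2 ca^k / (ca_high^k + ca^k)`;
#' `ca_high` = 1.3 uM is the calcium level accumulated at 20 Hz firing
#' and the factor 2 makes the weight saturate at 2 (kept exactly as the
#' model defines it, without renormalisation). `c0_nM` is the initial
#' extracellular NE concentration after fusion of one vesicle.
#'
#' @param ca_high half-point calcium, uM.
#' @param k_rel Hill exponent (>= 1).
#' @param c0_nM quantal extracellular NE concentration, nM.
#' @return a `release_params` list.
#' @export
release_params <- function(ca_high = 1.3, k_rel = 1, c0_nM = 200) {
  if (ca_high <= 0 || c0_nM <= 0 || k_rel < 1)
    stop("require ca_high > 0, c0_nM > 0, k_rel >= 1", call. = FALSE)
  structure(list(ca_high = ca_high, k_rel = k_rel, c0_nM = c0_nM),
            class = "release_params")
}

#' Parameters of the synaptic GIRK conductance kernel
#'
#' The opening time course after one release event is a normalised
#' double exponential `P_open(t) = B (exp(-t/tau_slow) - exp(-t/tau_fast))`
#' with `B` chosen so the peak equals 1, and the instantaneous
#' conductance is rectified by
#' `G_rect(V) = g_max / (1 + exp(slope (V - v_girk)))`.
#'
#' @param tau_fast,tau_slow kernel time constants, ms (`tau_slow > tau_fast`).
#' @param g_max rectification scale, uS/mm^2.
#' @param slope rectification slope, 1/mV.
#' @param v_girk GIRK reversal potential, mV (potassium reversal by default).
#' @return a `girk_params` list with the derived normalisation `B` and
#'   peak time `t_peak`.
#' @export
girk_params <- function(tau_fast = 300, tau_slow = 350, g_max = 0.2,
                        slope = 0.05, v_girk = -90) {
  if (!(tau_slow > tau_fast) || tau_fast <= 0)
    stop("require tau_slow > tau_fast > 0", call. = FALSE)
  t_peak <- tau_fast * tau_slow / (tau_slow - tau_fast) *
    log(tau_slow / tau_fast)
  b <- 1 / (exp(-t_peak / tau_slow) - exp(-t_peak / tau_fast))
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow, g_max = g_max,
                 slope = slope, v_girk = v_girk, t_peak = t_peak, B = b),
            class = "girk_params")
}

#' Parameters of extracellular NE diffusion and alpha2 binding
#'
#' Point-source diffusion with first-order reuptake,
#' \deqn{C(r,t) = \frac{\alpha}{(4 \pi D t)^{3/2}} e^{-r^2/(4Dt) - k_{up} t},}
#' receptor binding kinetics with `kon` (1/(nM s)) and `koff` (1/s)
#' (`K_D = koff/kon` = 1.25 nM), and an alpha-function low-pass filter of
#' characteristic time `tau_filter` standing in for the kinetics of
#' transmitter binding and the downstream G-protein cascade.
#'
#' `alpha` is the released amount expressed as concentration x volume
#' (nM um^3). The default is a quantal-content calibration: one large
#' dense-core vesicle carrying `n_quantal = 2.4e6` NE molecules, i.e.
#' `alpha = n_quantal / N_A = 4.0e6 nM um^3`. Under this choice the
#' concentration transient reaches the amperometric ~200 nM scale about
#' 9 um from the source. `tau_fast_eff`, `tau_slow_eff` and
#' `attenuation` are the shipped constants of the fitted effective
#' diffusion-driven GIRK kernel at 25 um (see [fit_effective_kernel()]).
#'
#' @param d_um2_ms diffusion constant, um^2/ms (3.4e-6 cm^2/s).
#' @param k_up_ms reuptake rate, 1/ms (20 1/s).
#' @param n_quantal NE molecules per vesicle used for the default `alpha`.
#' @param alpha source amplitude, nM um^3; overrides `n_quantal` if given.
#' @param c0_nM quantal reference concentration, nM.
#' @param kon,koff binding constants, 1/(nM s) and 1/s.
#' @param tau_filter alpha-function filter time constant, ms.
#' @param tau_fast_eff,tau_slow_eff,attenuation shipped effective-kernel
#'   constants (ms, ms, unitless).
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(d_um2_ms = 0.34, k_up_ms = 0.02,
                             n_quantal = 2.4e6, alpha = NULL, c0_nM = 200,
                             kon = 1.0, koff = 1.25, tau_filter = 50,
                             tau_fast_eff = 1400, tau_slow_eff = 1450,
                             attenuation = 0.07) {
  if (is.null(alpha)) alpha <- n_quantal / 6.02214076e23 * 1e24 # nM um^3
  if (d_um2_ms <= 0 || k_up_ms < 0 || kon <= 0 || koff <= 0 ||
      tau_filter <= 0 || alpha <= 0)
    stop("diffusion parameters must be positive (k_up_ms >= 0)",
         call. = FALSE)
  if (!(tau_slow_eff > tau_fast_eff))
    stop("require tau_slow_eff > tau_fast_eff", call. = FALSE)
  structure(list(d_um2_ms = d_um2_ms, k_up_ms = k_up_ms, alpha = alpha,
                 c0_nM = c0_nM, kon = kon, koff = koff,
                 tau_filter = tau_filter, tau_fast_eff = tau_fast_eff,
                 tau_slow_eff = tau_slow_eff, attenuation = attenuation),
            class = "diffusion_params")
}

#' Stimulus protocol for the electrode current
#'
#' A table of non-overlapping current steps applied to the soma.
#'
#' @param onset_ms,duration_ms,amplitude vectors of equal length: step
#'   onsets (ms), durations (ms, > 0) and amplitudes (uA/cm^2).
#' @return a tibble of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(1000, 1000, 27)
#' @export
stimulus_protocol <- function(onset_ms = numeric(), duration_ms = numeric(),
                              amplitude = numeric()) {
  stopifnot(length(onset_ms) == length(duration_ms),
            length(onset_ms) == length(amplitude))
  if (any(duration_ms <= 0)) stop("step durations must be > 0", call. = FALSE)
  if (length(onset_ms) > 1) {
    o <- order(onset_ms)
    ends <- onset_ms[o] + duration_ms[o]
    if (any(onset_ms[o][-1] < ends[-length(ends)]))
      stop("stimulus steps must not overlap", call. = FALSE)
  }
  structure(tibble::tibble(onset_ms = as.numeric(onset_ms),
                           duration_ms = as.numeric(duration_ms),
                           amplitude = as.numeric(amplitude)),
            class = c("stimulus_protocol", "tbl_df", "tbl", "data.frame"))
}

#' Map an electrode current in nA to a somatic current density
#'
#' Stimulus amplitudes in the LC literature are given in nA; the model works in
#' current densities. The conversion uses the configured nominal somatic
#' area (1e-2 cm^2 by default), under which the 270 nA step of the
#' high-activity protocol maps to 27 uA/cm^2.
#'
#' @param nA current in nA.
#' @param params an [lc_neuron_params()] object (for `area_cm2`).
#' @return current density in uA/cm^2.
#' @export
current_nA_to_density <- function(nA, params = lc_neuron_params()) {
  (nA * 1e-3) / params$area_cm2
}

as_param_vector <- function(p) {
  nm <- setdiff(names(p), "area_cm2")
  v <- unlist(p[nm])
  v
}
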