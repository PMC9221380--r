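#' Extracellular NE concentration from a quantal point release
#'
#' Three-dimensional point-source Green's function with first-order
#' reuptake,
#' \deqn{C(r,t) = \frac{\alpha}{(4\pi D t)^{3/2}}
#'   \exp\!\left(-\frac{r^2}{4 D t} - k_{up} t\right),}
#' evaluated in nM with `r` in um and `t` in ms. With `k_up = 0` the
#' spatial integral of `C` equals `alpha` at every time (mass
#' conservation); with reuptake the total extracellular mass decays as
#' `exp(-k_up t)` exactly.
#'
#' @param r_um distance from the release site, um (>= 0); vectorised.
#' @param t_ms time since release, ms (> 0); vectorised.
#' @param params a [diffusion_params()] object.
#' @return concentration in nM.
#' @export
ne_concentration <- function(r_um, t_ms, params = diffusion_params()) {
  if (any(t_ms <= 0)) stop("t_ms must be > 0", call. = FALSE)
  if (any(r_um < 0)) stop("r_um must be >= 0", call. = FALSE)
  d <- params$d_um2_ms
  params$alpha * exp(-r_um^2 / (4 * d * t_ms) - params$k_up_ms * t_ms) /
    (4 * pi * d * t_ms)^1.5
}

#' Normalised attenuation map C(r, t) / C0
#'
#' Concentration from [ne_concentration()] on a distance x time grid,
#' normalised by the quantal reference concentration `c0_nM`.
#'
#' @param r_grid_um,t_grid_ms positive, sorted grids.
#' @param params a [diffusion_params()] object.
#' @return tibble with `r_um`, `t_ms`, `c_nM`, `c_over_c0`, of class
#'   `concentration_field`.
#' @export
attenuation_profile <- function(r_grid_um, t_grid_ms,
                                params = diffusion_params()) {
  if (is.unsorted(r_grid_um) || is.unsorted(t_grid_ms))
    stop("grids must be sorted increasingly", call. = FALSE)
  if (any(r_grid_um <= 0) || any(t_grid_ms <= 0))
    stop("grids must be positive", call. = FALSE)
  grid <- tidyr::expand_grid(r_um = r_grid_um, t_ms = t_grid_ms)
  grid$c_nM <- ne_concentration(grid$r_um, grid$t_ms, params)
  grid$c_over_c0 <- grid$c_nM / params$c0_nM
  structure(grid, class = c("concentration_field", class(grid)))
}

#' Alpha2-receptor binding along a concentration trajectory
#'
#' Integrates the first-order binding relaxation
#' `dx/dt = kon C (1 - x) - koff x`, i.e. relaxation toward
#' `x_eq(C) = C kon / (C kon + koff)` with rate `C kon + koff`, with the
#' local concentration frozen over each time step (exact exponential
#' update per step). For constant `C` this reproduces the closed-form
#' relaxation; `x` stays in \[0, 1\] for any non-negative input.
#'
#' @param conc a data frame with columns `t_ms` (uniform grid) and
#'   `c_nM` (>= 0), or a numeric vector of concentrations with `dt_ms`.
#' @param params a [diffusion_params()] object.
#' @param x0 initial bound fraction.
#' @param dt_ms grid spacing when `conc` is a bare numeric vector.
#' @return tibble with `t_ms`, `c_nM`, `x_bound`.
#' @export
receptor_binding <- function(conc, params = diffusion_params(), x0 = 0,
                             dt_ms = NULL) {
  if (is.numeric(conc)) {
    if (is.null(dt_ms)) stop("dt_ms required for a bare vector",
                             call. = FALSE)
    conc <- tibble::tibble(t_ms = seq_along(conc) * dt_ms, c_nM = conc)
  }
  if (any(conc$c_nM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  dt <- diff(conc$t_ms)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("time grid must be uniform", call. = FALSE)
  dt <- if (length(dt)) dt[1] else 1
  kon <- params$kon * 1e-3   # 1/(nM ms)
  koff <- params$koff * 1e-3 # 1/ms
  x <- numeric(nrow(conc))
  xc <- x0
  for (i in seq_len(nrow(conc))) {
    rate <- kon * conc$c_nM[i] + koff
    xeq <- kon * conc$c_nM[i] / rate
    xc <- xeq + (xc - xeq) * exp(-rate * dt)
    x[i] <- xc
  }
  tibble::tibble(t_ms = conc$t_ms, c_nM = conc$c_nM, x_bound = x)
}

#' Equilibrium receptor occupancy
#'
#' `x_eq(C) = C / (C + K_D)` with `K_D = koff / kon` (1.25 nM at the
#' defaults).
#'
#' @param c_nM concentration, nM; vectorised.
#' @param params a [diffusion_params()] object.
#' @return equilibrium bound fraction.
#' @export
binding_equilibrium <- function(c_nM, params = diffusion_params()) {
  kd <- params$koff / params$kon
  c_nM / (c_nM + kd)
}

#' Causal alpha-function low-pass filter
#'
#' Convolution with `g(t) = (t/tau) exp(-t/tau)`, normalised to unit
#' integral (unit gain for constant inputs); stands in for the kinetics
#' of transmitter binding/unbinding and the G-protein cascade between
#' receptor occupancy and channel opening.
#'
#' @param signal numeric vector on a uniform grid.
#' @param tau_ms filter time constant, ms.
#' @param dt_ms grid spacing, ms.
#' @return filtered signal (same length, causal).
#' @export
alpha_filter <- function(signal, tau_ms = 50, dt_ms = 1) {
  if (tau_ms <= 0 || dt_ms <= 0) stop("tau_ms, dt_ms must be > 0",
                                      call. = FALSE)
  tk <- seq(0, max(8 * tau_ms, 2 * dt_ms), by = dt_ms)
  kern <- (tk / tau_ms) * exp(-tk / tau_ms)
  kern <- kern / sum(kern)
  pad <- length(kern) - 1
  y <- stats::filter(c(rep(0, pad), signal), kern,
                     method = "convolution", sides = 1)
  as.numeric(y)[pad + seq_along(signal)]
}

#' Diffusion-driven GIRK drive from a single quantal release
#'
#' The full chain for one release at distance `r_um`: point-source
#' concentration, alpha2 binding kinetics, then the alpha-function
#' filter. The result is the normalised open-channel drive used to
#' derive the effective volume-transmission kernel.
#'
#' @param r_um distance, um.
#' @param params a [diffusion_params()] object.
#' @param t_max_ms trajectory length, ms.
#' @param dt_ms grid spacing, ms.
#' @return tibble with `t_ms`, `c_nM`, `x_bound`, `drive`.
#' @export
girk_drive_trajectory <- function(r_um, params = diffusion_params(),
                                  t_max_ms = 8000, dt_ms = 1) {
  tt <- seq(dt_ms, t_max_ms, by = dt_ms)
  cc <- ne_concentration(r_um, tt, params)
  b <- receptor_binding(tibble::tibble(t_ms = tt, c_nM = cc), params)
  b$drive <- alpha_filter(b$x_bound, params$tau_filter, dt_ms)
  b
}

#' Fit the effective double-exponential kernel to a GIRK drive
#'
#' Least-squares fit of `A B' (exp(-t/tau_s) - exp(-t/tau_f))`, where
#' `B'` normalises the double exponential to unit peak, so that `A` is
#' directly the kernel amplitude. When the drive comes from the
#' diffusion chain, `A` measured against the unit-peak synaptic kernel
#' is the attenuation factor of volume transmission.
#'
#' @param drive a data frame with columns `t_ms` and `drive` (e.g. from
#'   [girk_drive_trajectory()]), or a numeric vector with `dt_ms`.
#' @param dt_ms grid spacing when `drive` is a bare vector.
#' @param start optional named list with starting values `tau_f`,
#'   `tau_s`, `amp`.
#' @return an object of class `kernel_fit`: list with `tau_fast`,
#'   `tau_slow`, `attenuation`, `t_peak`, the `fit` object and the
#'   residual standard error.
#' @export
fit_effective_kernel <- function(drive, dt_ms = 1, start = NULL) {
  if (is.numeric(drive))
    drive <- tibble::tibble(t_ms = seq_along(drive) * dt_ms, drive = drive)
  df <- data.frame(t = drive$t_ms, y = drive$drive)
  pk <- which.max(df$y)
  if (!is.finite(df$y[pk]) || df$y[pk] <= 0)
    stop("drive trajectory has no positive peak to fit", call. = FALSE)
  if (is.null(start))
    start <- list(tau_f = df$t[pk] * 0.8, tau_s = df$t[pk] * 1.2,
                  amp = df$y[pk])
  model <- function(t, tau_f, tau_s, amp) {
    tp <- tau_f * tau_s / (tau_s - tau_f) * log(tau_s / tau_f)
    b <- 1 / (exp(-tp / tau_s) - exp(-tp / tau_f))
    amp * b * (exp(-t / tau_s) - exp(-t / tau_f))
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ model(t, tau_f, tau_s, amp), data = df, start = start,
    lower = c(tau_f = 1, tau_s = 1.0001, amp = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("effective-kernel fit did not converge: ",
         attr(fit, "condition")$message, call. = FALSE)
  cf <- stats::coef(fit)
  tau_f <- unname(min(cf["tau_f"], cf["tau_s"]))
  tau_s <- unname(max(cf["tau_f"], cf["tau_s"]))
  structure(list(tau_fast = tau_f, tau_slow = tau_s,
                 attenuation = unname(cf["amp"]),
                 t_peak = tau_f * tau_s / (tau_s - tau_f) *
                   log(tau_s / tau_f),
                 sigma = stats::sigma(fit), fit = fit),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(paste0("<kernel_fit> tau_fast = %.1f ms, tau_slow = %.1f ms, ",
                     "attenuation = %.4g (peak at %.0f ms)\n"),
              x$tau_fast, x$tau_slow, x$attenuation, x$t_peak))
  invisible(x)
}

#' Effective volume-transmission kernel at a given distance
#'
#' Returns the double-exponential kernel constants used for a volume
#' edge: either fitted at run time to the diffusion-driven drive at
#' `r_um` (`method = "fitted"`) or the shipped constants stored in the
#' parameter object (`method = "shipped"`, exact for the reference
#' 25 um distance).
#'
#' @param r_um source-target distance, um.
#' @param params a [diffusion_params()] object.
#' @param method `"fitted"` or `"shipped"`.
#' @return list with `tau_fast`, `tau_slow`, `attenuation`.
#' @export
volume_kernel <- function(r_um, params = diffusion_params(),
                          method = c("fitted", "shipped")) {
  method <- match.arg(method)
  if (method == "shipped")
    return(list(tau_fast = params$tau_fast_eff,
                tau_slow = params$tau_slow_eff,
                attenuation = params$attenuation))
  k <- fit_effective_kernel(girk_drive_trajectory(r_um, params))
  # near-degenerate fits are common (the two time constants trade off);
  # keep a strict ordering for the network integrator
  ts <- max(k$tau_slow, k$tau_fast + 1)
  list(tau_fast = k$tau_fast, tau_slow = ts, attenuation = k$attenuation)
}
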