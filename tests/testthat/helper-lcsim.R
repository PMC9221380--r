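# shared fixtures built in code

quiet_params <- function(...) lc_neuron_params(noise_amp = 0, ...)

# a short spontaneous run reused by several files
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lc_simulate(lc_neuron_params(), duration_ms = 3000,
                            record_dt = 0.1, noise = FALSE)
    cache
  }
})

# synthetic AP template train: `n` stereotyped spikes on a flat baseline
template_train <- function(n = 10, isi_ms = 100, dt_ms = 0.1,
                           baseline = -60) {
  t_end <- n * isi_ms + 100
  tt <- seq(0, t_end, by = dt_ms)
  v <- rep(baseline, length(tt))
  peaks <- (seq_len(n)) * isi_ms
  for (pk in peaks) {
    v <- v + 90 * exp(-((tt - pk) / 0.6)^2) -
      10 * exp(-pmax(tt - pk - 1, 0) / 30) * (tt > pk + 1)
  }
  list(trace = tibble::tibble(time_ms = tt, mV = v), peaks = peaks)
}

# exhaustive O(n^2) nearest-neighbour oracle
nn_oracle <- function(xyz) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dd < best) best <- dd
    }
    out[i] <- best
  }
  out
}

# radial finite-difference oracle for point-source diffusion with
# first-order loss: with u = r*C the PDE reduces to
# du/dt = D d2u/dr2 - k u, u(0, t) = 0
fd_concentration <- function(params, r_eval, t_eval, t0 = 20,
                             r_max = 200, dr = 0.2) {
  d <- params$d_um2_ms
  k <- params$k_up_ms
  rr <- seq(0, r_max, by = dr)
  u <- rr * ne_concentration(pmax(rr, 1e-9), t0, params)
  dt <- 0.4 * dr^2 / (2 * d)
  nt <- ceiling((max(t_eval) - t0) / dt)
  dt <- (max(t_eval) - t0) / nt
  out <- matrix(NA_real_, length(r_eval), length(t_eval))
  t_now <- t0
  lam <- d * dt / dr^2
  for (s in seq_len(nt)) {
    u_new <- u
    n <- length(u)
    u_new[2:(n - 1)] <- u[2:(n - 1)] +
      lam * (u[3:n] - 2 * u[2:(n - 1)] + u[1:(n - 2)]) -
      k * dt * u[2:(n - 1)]
    u_new[1] <- 0
    u_new[n] <- 0
    u <- u_new
    t_now <- t_now + dt
    hit <- which(abs(t_eval - t_now) < dt / 2)
    for (h in hit)
      out[, h] <- approx(rr, u, r_eval)$y / r_eval
  }
  out
}
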