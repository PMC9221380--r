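test_that("AHP gate is the saturating calcium function", {
  expect_equal(ahp_gate(0), 0)
  expect_equal(ahp_gate(1), 0.5)
  expect_equal(ahp_gate(1.3), 1.3 / 2.3, tolerance = 1e-10)
  expect_error(ahp_gate(-0.1), "calcium")
})

test_that("calcium drive factor has the documented shape and peak", {
  expect_equal(ca_drive_factor(-25, 120), 72.5)
  expect_lt(ca_drive_factor(-200, 120), 1e-20)
  pk <- optimize(ca_drive_factor, c(-60, 120), v_ca = 120,
                 maximum = TRUE)$objective
  expect_equal(pk, 132.6, tolerance = 0.1 / 132.6)
})

test_that("calcium steady state is scaled drive with ceiling M_Ca", {
  p <- lc_neuron_params()
  expect_lt(calcium_steady_state(-200, p), 1e-15)
  expect_equal(m_ca(p), 42.4, tolerance = 2e-3)
  # composition of the two worked examples
  expect_equal(calcium_steady_state(-25, p), m_ca(p) * 72.5 / 132.58,
               tolerance = 1e-3)
  # internal consistency invariant: f_ca * k_ca * tau_ca * peak = M_Ca
  expect_equal(p$f_ca * p$k_ca * p$tau_ca * 132.58, m_ca(p),
               tolerance = 1e-3)
})

test_that("calcium update is the exact linear relaxation", {
  p <- lc_neuron_params()
  s <- calcium_steady_state(-20, p)
  expect_equal(calcium_update(s, -20, 13.7, p), s)
  expect_equal(calcium_update(0, -20, p$tau_ca, p), s * (1 - exp(-1)))
  # two half steps equal one full step to machine precision
  one <- calcium_update(0.4, -30, 10, p)
  two <- calcium_update(calcium_update(0.4, -30, 5, p), -30, 5, p)
  expect_equal(two, one, tolerance = 1e-14)
  expect_error(calcium_update(0.4, -30, 0, p), "dt")
})

test_that("somatic derivative vanishes without currents and at reversal", {
  p0 <- quiet_params(g_na = 0, g_k = 0, g_p = 0, g_ahp = 0, g_l = 0,
                     g_sd = 0, g_ca = 0)
  st <- lc_initial_state(p0, v_s = -48, v_d = -48, ca = 0)
  expect_equal(as.numeric(soma_derivative(st, p0)), 0)
  # leak only, exactly at the leak reversal
  pl <- quiet_params(g_na = 0, g_k = 0, g_p = 0, g_ahp = 0, g_sd = 0)
  stl <- lc_initial_state(pl, v_s = pl$v_l, v_d = pl$v_l, ca = 0)
  expect_equal(as.numeric(soma_derivative(stl, pl)), 0)
  expect_error(soma_derivative(replace(st, 1, NaN), p0), "blow-up")
  expect_error(soma_derivative(st, p0, g_girk_total = -1), "g_girk")
})

test_that("dendritic derivative vanishes at rest and under symmetry", {
  p <- lc_neuron_params()
  st <- lc_initial_state(p, v_s = p$v_ld, v_d = p$v_ld)
  expect_equal(dendrite_derivative(st, p), 0)
  # two identical neurons coupled by a gap junction stay identical,
  # so the junctional current is zero for the whole trajectory
  cfg <- network_config(
    neurons = list(p, p),
    gap_junctions = tibble::tibble(a = 1L, b = 2L, g = 0.05),
    duration_ms = 1500, noise = FALSE)
  sim <- run_scenario(cfg)
  tr <- tidyr::pivot_wider(sim$trace[, c("time_ms", "neuron", "v_d")],
                           names_from = "neuron", values_from = "v_d")
  expect_equal(tr$`1`, tr$`2`, tolerance = 1e-12)
})

test_that("a conductance-free neuron is a fixed point of the stepper", {
  p0 <- quiet_params(g_na = 0, g_k = 0, g_p = 0, g_ahp = 0, g_l = 0,
                     g_ld = 0, g_sd = 0, g_ds = 0, g_ca = 0)
  st <- lc_initial_state(p0, v_s = -48, v_d = -48)
  st["ca"] <- calcium_steady_state(-48, p0)
  out <- lc_step(st, p0, dt = 0.1)
  expect_equal(out, st, tolerance = 1e-12)
})

test_that("the pure-R stepper reproduces the compiled integrator", {
  p <- lc_neuron_params()
  st <- lc_initial_state(p)
  for (i in 1:2000) st <- lc_step(st, p, dt = 0.025)
  sim <- lc_simulate(p, duration_ms = 50, record_dt = 50, noise = FALSE)
  tr <- sim$trace[sim$trace$time_ms == 50, ]
  expect_equal(st[["v_s"]], tr$v_s, tolerance = 1e-12)
  expect_equal(st[["v_d"]], tr$v_d, tolerance = 1e-12)
  expect_equal(st[["ca"]], tr$ca, tolerance = 1e-12)
})

test_that("gating variables and calcium stay in bounds on a trajectory", {
  p <- lc_neuron_params()
  st <- lc_initial_state(p)
  lo <- c(1, 1, 1)
  hi <- c(0, 0, 0)
  for (i in 1:4000) {
    st <- lc_step(st, p, dt = 0.05, i_elec = 5)
    v <- st[c("h", "n", "ca")]
    lo <- pmin(lo, v)
    hi <- pmax(hi, v)
  }
  expect_gte(min(lo), 0)
  expect_lte(max(hi[1:2]), 1)
  sim <- lc_simulate(p, duration_ms = 2000, noise = TRUE, seed = 1)
  expect_true(all(sim$final_state[, 3:4] >= 0 & sim$final_state[, 3:4] <= 1))
  expect_true(all(sim$trace$ca >= 0))
})

test_that("trajectories are deterministic and converge under dt refinement", {
  p <- lc_neuron_params()
  a <- lc_simulate(p, duration_ms = 2000, noise = FALSE, seed = 1)
  b <- lc_simulate(p, duration_ms = 2000, noise = FALSE, seed = 99)
  expect_identical(a$spikes, b$spikes)
  c1 <- lc_simulate(p, duration_ms = 2000, noise = TRUE, seed = 7)
  c2 <- lc_simulate(p, duration_ms = 2000, noise = TRUE, seed = 7)
  expect_identical(c1$spikes, c2$spikes)
  # error shrinks as dt is halved (subthreshold checkpoint at 120 ms)
  vat <- function(dt) {
    sim <- lc_simulate(p, duration_ms = 120, dt = dt, record_dt = 10,
                       noise = FALSE)
    sim$trace$v_s[sim$trace$time_ms == 120]
  }
  e1 <- abs(vat(0.04) - vat(0.02))
  e2 <- abs(vat(0.02) - vat(0.01))
  e3 <- abs(vat(0.01) - vat(0.005))
  expect_lt(e3, e2)
  expect_lt(e2, e1)
  expect_lt(e3, 0.01)
})

test_that("stimulus protocols are validated", {
  expect_error(stimulus_protocol(0, -5, 1), "durations")
  expect_error(stimulus_protocol(c(0, 50), c(100, 100), c(1, 1)),
               "overlap")
  p <- stimulus_protocol(c(500, 0), c(100, 100), c(2, 1))
  expect_s3_class(p, "stimulus_protocol")
})

test_that("unknown neuron parameters are rejected, conductances checked", {
  expect_error(lc_neuron_params(g_bogus = 1), "g_bogus")
  expect_error(lc_neuron_params(g_na = -1), "g_na")
  expect_error(lc_neuron_params(tau_ca = 0), "tau_ca")
})
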