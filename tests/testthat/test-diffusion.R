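test_that("point-source solution conserves mass without reuptake", {
  dp <- diffusion_params(k_up_ms = 0)
  mass <- function(t) {
    f <- function(r) 4 * pi * r^2 * ne_concentration(r, t, dp)
    integrate(f, 0, 400, rel.tol = 1e-9)$value
  }
  expect_equal(mass(50), dp$alpha, tolerance = 1e-4)
  expect_equal(mass(400), dp$alpha, tolerance = 1e-4)
})

test_that("total extracellular mass decays exactly as exp(-k t)", {
  dp <- diffusion_params()
  mass <- function(t) {
    f <- function(r) 4 * pi * r^2 * ne_concentration(r, t, dp)
    integrate(f, 0, 400, rel.tol = 1e-9)$value
  }
  expect_equal(mass(500) / mass(100), exp(-dp$k_up_ms * 400),
               tolerance = 1e-6)
})

test_that("concentration decreases monotonically with distance", {
  dp <- diffusion_params()
  for (t in c(10, 100, 800)) {
    cc <- ne_concentration(seq(1, 60, by = 1), t, dp)
    expect_true(all(diff(cc) < 0))
  }
  expect_error(ne_concentration(10, 0, dp), "t_ms")
  expect_error(ne_concentration(-1, 10, dp), "r_um")
})

test_that("attenuation profile is a normalised, monotone field", {
  dp <- diffusion_params()
  f <- attenuation_profile(c(5, 10, 20, 25), c(100, 500), dp)
  expect_s3_class(f, "concentration_field")
  expect_equal(f$c_over_c0, f$c_nM / 200)
  by_t <- split(f, f$t_ms)
  for (b in by_t) expect_true(all(diff(b$c_over_c0) < 0))
  expect_error(attenuation_profile(c(10, 5), 100, dp), "sorted")
})

test_that("closed-form solution agrees with a radial FD oracle", {
  dp <- diffusion_params()
  r_eval <- c(5, 10, 20, 35, 50)
  t_eval <- c(50, 200, 500, 1000)
  fd <- fd_concentration(dp, r_eval, t_eval)
  cf <- outer(r_eval, t_eval, ne_concentration, params = dp)
  rel <- abs(fd - cf) / cf
  expect_lt(max(rel), 0.02)
})

test_that("receptor binding relaxes to the closed-form equilibria", {
  dp <- diffusion_params()
  run_const <- function(c_nM) {
    tr <- receptor_binding(rep(c_nM, 8000), dp, dt_ms = 1)
    tail(tr$x_bound, 1)
  }
  expect_equal(run_const(1.25), 0.5, tolerance = 1e-3)
  expect_equal(run_const(200), 200 / 201.25, tolerance = 1e-6)
  expect_equal(run_const(0.2), 0.2 / 1.45, tolerance = 1e-3)
  expect_error(receptor_binding(c(1, -1), dp, dt_ms = 1), "negative|>= 0")
})

test_that("bound fraction is bounded and monotone under rising input", {
  dp <- diffusion_params()
  set.seed(1)
  cc <- cumsum(runif(500)) / 20 # non-decreasing concentration
  tr <- receptor_binding(cc, dp, dt_ms = 1)
  expect_true(all(tr$x_bound >= 0 & tr$x_bound <= 1))
  expect_true(all(diff(tr$x_bound) >= -1e-12))
})

test_that("alpha filter is causal, unit gain, with mode at tau", {
  imp <- c(1, numeric(1499))
  out <- alpha_filter(imp, tau_ms = 50, dt_ms = 1)
  expect_equal(which.max(out) - 1, 50)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  cst <- alpha_filter(rep(3, 1200), tau_ms = 50, dt_ms = 1)
  expect_equal(tail(cst, 1), 3, tolerance = 1e-9)
  # closed-form step response: 95% of final value by ~ 4.74 tau
  st <- alpha_filter(rep(1, 2000), tau_ms = 50, dt_ms = 1)
  expect_equal(which(st >= 0.95)[1], 237, tolerance = 6 / 237)
})

test_that("kernel fit recovers the synaptic kernel from its own curve", {
  gp <- girk_params()
  tt <- seq(1, 4000)
  fit <- fit_effective_kernel(
    tibble::tibble(t_ms = tt, drive = girk_open_prob(tt, 0, gp)))
  expect_equal(fit$tau_fast, 300, tolerance = 0.01)
  expect_equal(fit$tau_slow, 350, tolerance = 0.01)
  expect_equal(fit$attenuation, 1, tolerance = 0.01)
})

test_that("diffusion-driven kernel at 25 um is slow and attenuated", {
  dp <- diffusion_params()
  tr <- girk_drive_trajectory(25, dp, t_max_ms = 8000)
  expect_true(all(tr$x_bound >= 0 & tr$x_bound <= 1))
  fit <- fit_effective_kernel(tr)
  # weaker than the synaptic kernel by an order of magnitude
  expect_lt(fit$attenuation, 0.1)
  expect_gt(fit$attenuation, 0.02)
  # and slower than the 300/350 ms synaptic kernel
  expect_gt(fit$t_peak, girk_params()$t_peak)
  expect_error(fit_effective_kernel(tibble::tibble(t_ms = 1:10,
                                                   drive = numeric(10))),
               "peak")
})

test_that("volume kernel modes agree on the reference distance scale", {
  dp <- diffusion_params()
  shipped <- volume_kernel(25, dp, method = "shipped")
  expect_equal(shipped$tau_fast, dp$tau_fast_eff)
  expect_equal(shipped$attenuation, dp$attenuation)
  fitted <- volume_kernel(25, dp, method = "fitted")
  expect_gt(fitted$tau_slow, fitted$tau_fast)
  expect_equal(fitted$attenuation, 0.07, tolerance = 0.5)
})
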