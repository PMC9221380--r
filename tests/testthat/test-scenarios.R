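test_that("identical configuration and seed give identical results", {
  p <- lc_neuron_params()
  cfg <- scenario_dendro_somatic(p, step_amp = 10, seed = 4)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$trace$v_s, b$trace$v_s)
  expect_identical(a$meta$config_hash, b$meta$config_hash)
})

test_that("no postsynaptic conductance precedes the first release", {
  p <- lc_neuron_params()
  sim <- run_scenario(scenario_dendro_somatic(p, step_amp = 10, seed = 1))
  t_first <- min(sim$releases$t_ap_ms)
  tr2 <- sim$trace[sim$trace$neuron == 2, ]
  expect_true(all(tr2$g_girk[tr2$time_ms < t_first] == 0))
  expect_gt(max(tr2$g_girk[tr2$time_ms > t_first + 100]), 0)
})

test_that("unconnected neurons both pace near the spontaneous rate", {
  p <- lc_neuron_params()
  cfg <- network_config(list(p, p), duration_ms = 10000, seed = 2)
  sim <- run_scenario(cfg)
  for (i in 1:2)
    expect_equal(spike_rate(sim, i, 1000, 10000), 4.3, tolerance = 0.1)
})

test_that("step calibration reaches the requested rate", {
  p <- lc_neuron_params()
  amp <- calibrate_step_current(p, 20, 1000)
  expect_lt(abs(attr(amp, "rate_hz") - 20), 1)
  amp10 <- calibrate_step_current(p, 10, 1000, tol_hz = 1)
  expect_lt(abs(attr(amp10, "rate_hz") - 10), 1.5)
  expect_lt(amp10, amp)
})

test_that("FI curve rises monotonically with early-spike facilitation", {
  p <- lc_neuron_params()
  fi <- fi_protocol(p, c(0, 3, 6, 9, 12))
  expect_true(all(diff(fi$rate_hz) >= 0))
  # spontaneous rate at zero amplitude (short-window quantisation)
  expect_equal(fi$rate_hz[1], 4.3, tolerance = 0.35)
  top <- fi[fi$amplitude >= 9, ]
  expect_true(all(top$early_rate_hz >= top$rate_hz))
  gap <- fi$early_rate_hz - fi$rate_hz
  expect_gt(gap[fi$amplitude == 12], gap[fi$amplitude == 6])
  expect_error(fi_protocol(p, c(5, 0)), "sorted")
})

test_that("volume conductance accumulates across repeated steps", {
  p <- lc_neuron_params()
  vs <- run_volume_scenario(p, step_amp = 10, seed = 1, kernel = "shipped")
  tr2 <- vs$trace[vs$trace$neuron == 2, ]
  onsets <- vs$config$protocols[[1]]$onset_ms
  split_t <- onsets[2]
  g1 <- max(tr2$g_girk[tr2$time_ms < split_t])
  g2 <- max(tr2$g_girk[tr2$time_ms >= split_t])
  expect_gt(g2, g1)
  # a shorter inter-step interval facilitates the build-up further
  vs_short <- run_volume_scenario(p, step_amp = 10, gap_ms = 500,
                                  seed = 1, kernel = "shipped")
  tr2s <- vs_short$trace[vs_short$trace$neuron == 2, ]
  split_s <- vs_short$config$protocols[[1]]$onset_ms[2]
  g2s <- max(tr2s$g_girk[tr2s$time_ms >= split_s])
  expect_gt(g2s / g1, g2 / g1)
})

test_that("volume interaction spares the source and slows the neighbour", {
  p <- lc_neuron_params()
  on <- run_volume_scenario(p, step_amp = 10, seed = 2)
  off <- run_volume_scenario(p, step_amp = 10, seed = 2, girk_on = FALSE)
  onsets <- on$config$protocols[[1]]$onset_ms
  # driven neuron's step rate is unchanged (< 10%)
  r_on <- spike_rate(on, 1, onsets[1], onsets[1] + 1000)
  r_off <- spike_rate(off, 1, onsets[1], onsets[1] + 1000)
  expect_lt(abs(r_on - r_off) / r_off, 0.10)
  # neighbour can only lose spikes, and its ISI does not shorten
  expect_lte(length(on$spikes[[2]]), length(off$spikes[[2]]))
  end2 <- onsets[2] + 1000
  il_on <- isi_lengthening(on, 2, end2, 4000)
  il_off <- isi_lengthening(off, 2, end2, 4000)
  expect_gte(il_on$isi_post_ms, il_off$isi_post_ms - 1)
  # a far neighbour at 100 um is essentially untouched
  far <- run_volume_scenario(p, step_amp = 10, distance_um = 100, seed = 2)
  il_far <- isi_lengthening(far, 2, end2, 4000)
  expect_lt(abs(il_far$ratio - 1), 0.05)
})

test_that("GIRK decay after the dendro-somatic step fits tau_slow", {
  p <- lc_neuron_params()
  sim <- run_scenario(scenario_dendro_somatic(p, step_amp = 10,
                                              hold = TRUE,
                                              duration_ms = 9000,
                                              seed = 1))
  fit <- girk_decay_fit(sim, 2)
  expect_equal(fit$tau_ms, 350, tolerance = 20 / 350)
})

test_that("network configs validate wiring", {
  p <- lc_neuron_params()
  expect_error(network_config(list(p), edges = tibble::tibble(
    src = 1L, dst = 2L, mode = "dendro_somatic", weight = 1)),
    "src")
  expect_error(network_config(list(p, p), edges = tibble::tibble(
    src = 1L, dst = 2L, mode = "autoinhibition", weight = 1)),
    "autoinhibition")
  expect_error(network_config(list(p, p), edges = tibble::tibble(
    src = 1L, dst = 2L, mode = "volume", weight = 1)),
    "distance_um")
  expect_error(network_config(list(p, p), edges = tibble::tibble(
    src = 1L, dst = 2L, mode = "wireless", weight = 1)),
    "mode")
})

test_that("tidy and glance summarise simulations", {
  sim <- run_scenario(network_config(list(lc_neuron_params()),
                                     duration_ms = 2000, seed = 1))
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("neuron", "rate_hz", "n_spikes") %in% names(td)))
  gl <- glance(sim)
  expect_equal(gl$n_neurons, 1)
  expect_false(is.na(gl$config_hash))
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
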