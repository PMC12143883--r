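test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, session_length_s = 120, sweep_duration_s = 5)
  s1 <- generate_photometry_session(cfg, "day7_partner", "a1")
  s2 <- generate_photometry_session(cfg, "day7_partner", "a1")
  expect_identical(s1, s2)
  w1 <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c1")
  w2 <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c1")
  expect_identical(w1, w2)
  p1 <- generate_preference_trial(cfg, "Gi_CNO", "s1")
  p2 <- generate_preference_trial(cfg, "Gi_CNO", "s1")
  expect_identical(p1, p2)
})

test_that("per-session streams are independent of other sessions", {
  cfg <- sim_config(seed = 11, session_length_s = 120)
  a <- generate_photometry_session(cfg, "day7_partner", "a1")
  invisible(generate_photometry_session(cfg, "day7_stranger", "a2"))
  b <- generate_photometry_session(cfg, "day7_partner", "a1")
  expect_identical(a, b)
})

test_that("null signal produces a constant trace and zero dF/F downstream", {
  cfg <- sim_config(seed = 2, session_length_s = 120,
                    transient_amp = c(partner = 0, stranger = 0, object = 0),
                    transient_amp_sd = 0, animal_scale_sd = 0,
                    noise_sd_photometry = 0, drift_slope = 0)
  ses <- generate_photometry_session(cfg, "day7_partner", "a1")
  expect_true(all(ses$trace$samples == ses$trace$samples[1]))
  res <- analyze_photometry_session(ses)
  expect_true(all(res$dff$values == 0))
  expect_equal(res$summary$mean_dff, 0)
})

test_that("bout counts follow the configured Poisson rate", {
  # bouts are drawn on the epoch minus fixed margins; the Poisson-moments
  # oracle predicts mean = rate * window length
  cfg0 <- sim_config(seed = 1, session_length_s = 600, bout_rate_hz = 0.05)
  window_s <- 600 - cfg0$pre_stimulus_s - 2 - 12
  expected <- 0.05 * window_s
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, session_length_s = 600, bout_rate_hz = 0.05)
    nrow(generate_photometry_session(cfg, "day7_partner", "a1")$events)
  }, numeric(1))
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 4 * se)
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30))
})

test_that("ground-truth events always lie within their trace span", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s, session_length_s = 150, sweep_duration_s = 5)
    ses <- generate_photometry_session(cfg, "day3_stranger", "a1")
    expect_true(all(ses$events$start_s >= 0 &
                      ses$events$end_s <= cfg$session_length_s))
    ss <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c1")
    tt <- ss$ground_truth$true_psc_times_s[[1]]
    expect_true(all(tt >= 0 & tt <= cfg$sweep_duration_s))
  }
})

test_that("sessions too short for the baseline window are rejected", {
  cfg <- sim_config(seed = 1, session_length_s = 25)
  expect_error(generate_photometry_session(cfg, "day7_partner"),
               "too short")
})

test_that("zero-rate, zero-noise sweeps are flat with no ground truth", {
  cfg <- sim_config(seed = 3, psc_rate_hz = 0, noise_sd_ephys_pA = 0,
                    sweep_duration_s = 2)
  ss <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c1")
  expect_true(all(ss$sweeps[[1]]$samples == 0))
  expect_length(ss$ground_truth$true_psc_times_s[[1]], 0)
})

test_that("evoked protocol yields exactly 20 trials per holding potential", {
  cfg <- sim_config(seed = 4)
  ss <- generate_sweep_set(cfg, "evoked_vclamp", "cohabitation", "c1")
  hold <- vapply(ss$sweeps, `[[`, numeric(1), "holding_mV")
  expect_equal(sum(hold == -70), 20)
  expect_equal(sum(hold == 0), 20)
})

test_that("unknown protocol labels are rejected", {
  cfg <- sim_config(seed = 1)
  expect_error(generate_sweep_set(cfg, "banana"), "unknown protocol")
})

test_that("sweep polarity follows the holding potential", {
  cfg <- sim_config(seed = 5, sweep_duration_s = 10, noise_sd_ephys_pA = 0)
  inw <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c1",
                            holding_mV = -70)
  out <- generate_sweep_set(cfg, "spontaneous_vclamp", "control", "c2",
                            holding_mV = 0)
  expect_lte(min(inw$sweeps[[1]]$samples), -5)
  expect_lte(max(inw$sweeps[[1]]$samples), 1e-9)  # all deflections inward
  expect_gte(max(out$sweeps[[1]]$samples), 5)
})

test_that("LIF spike counts match the closed-form interspike prediction", {
  cfg <- sim_config(seed = 6, noise_sd_vm_mV = 0)
  ss <- generate_sweep_set(cfg, "current_steps", "control", "c1")
  for (i in seq_along(cfg$step_currents_pA)) {
    pred <- oracle_lif_count(cfg$step_currents_pA[i], cfg$lif_params,
                             cfg$step_duration_s)
    expect_lte(abs(ss$ground_truth$true_spike_counts[i] - pred), 1)
  }
})

test_that("preference trials are null when group effects are absent", {
  ratios <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, group_effects = list())
    preference_ratio(generate_preference_trial(cfg, "mCherry_saline",
                                               "s1"))$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 0.05)
})

test_that("a positive partner side-by-side effect shifts the ratio up", {
  eff <- list("Gi_CNO.sbs_partner_s" = 800)
  ratios <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, group_effects = eff)
    preference_ratio(generate_preference_trial(cfg, "Gi_CNO", "s1"))$ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.02)
  expect_gt(t.test(ratios)$statistic, 2)
})

test_that("trial times are non-negative and bounded by the trial span", {
  for (s in 1:20) {
    cfg <- sim_config(seed = s)
    tr <- generate_preference_trial(cfg, "Gq_CNO", "s1")
    expect_gte(tr$time_partner_side_s, 0)
    expect_gte(tr$time_stranger_side_s, 0)
    expect_lte(tr$time_partner_side_s + tr$time_stranger_side_s,
               tr$trial_span_s)
    expect_lte(tr$side_by_side_partner_s, tr$time_partner_side_s)
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(transient_tau_rise_s = 2, transient_tau_decay_s = 1),
               "decay")
  expect_error(sim_config(bout_duration_s = c(4, 1)), "min <= max")
  expect_error(sim_config(fs_photometry = -1), "positive")
})
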