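epoch <- function(onset, end) list(stimulus_onset_s = onset, epoch_end_s = end)

test_that("dF/F is zero on a constant trace and matches the ratio formula", {
  tr <- photometry_trace(rep(2, 600), fs = 10)
  d <- compute_dff(tr, epoch(15, 60))
  expect_true(all(d$values == 0))
  expect_equal(d$f0, 2)

  # F0 = 1, F = 1.5 at one sample -> dF/F = 0.5 there
  x <- rep(1, 400)
  x[300] <- 1.5
  d2 <- compute_dff(photometry_trace(x, fs = 10), epoch(15, 40))
  expect_equal(max(d2$values), 0.5)
})

test_that("dF/F is invariant to multiplicative gain", {
  set.seed(1)
  for (i in 1:10) {
    x <- 5 + abs(rnorm(500, 0, 0.5)) + 0.2 * sin(seq_len(500) / 30)
    tr1 <- photometry_trace(x, fs = 20)
    tr3 <- photometry_trace(3 * x, fs = 20)
    ep <- epoch(12, 25)
    expect_equal(compute_dff(tr1, ep)$values, compute_dff(tr3, ep)$values,
                 tolerance = 1e-12)
  }
})

test_that("invalid or truncated baselines are errors", {
  expect_error(compute_dff(photometry_trace(rep(-1, 300), fs = 10),
                           epoch(15, 30)), "F0 must be positive")
  expect_error(compute_dff(photometry_trace(rep(1, 100), fs = 10),
                           epoch(5, 10)), "truncated")
})

test_that("refractory exclusion applies the 4-s gap rule", {
  # gaps of 8 s offset-to-onset: all included
  b <- data.frame(start_s = c(0, 10, 20), end_s = c(2, 12, 22))
  expect_equal(apply_refractory_exclusion(b)$included, rep(TRUE, 3))

  # bout [0,2) then onset at 5: gap 3 s < 4 s, excluded
  b2 <- data.frame(start_s = c(0, 5), end_s = c(2, 7))
  r2 <- apply_refractory_exclusion(b2)
  expect_equal(r2$included, c(TRUE, FALSE))
  expect_match(r2$exclusion_reason[2], "within 4")

  # single bout always included
  b3 <- data.frame(start_s = 3, end_s = 4)
  expect_true(apply_refractory_exclusion(b3)$included)

  # excluded bouts do not reset the clock: the reference is the previous
  # *included* bout
  b4 <- data.frame(start_s = c(0, 5, 9), end_s = c(2, 8, 10))
  expect_equal(apply_refractory_exclusion(b4)$included, c(TRUE, FALSE, TRUE))

  # onset-to-onset alternative behind the flag
  b5 <- data.frame(start_s = c(0, 5), end_s = c(4.5, 7))
  expect_equal(apply_refractory_exclusion(b5, from = "onset")$included,
               c(TRUE, TRUE))
  expect_equal(apply_refractory_exclusion(b5, from = "offset")$included,
               c(TRUE, FALSE))
})

test_that("exclusion is monotone: appending a bout never rescues earlier ones", {
  set.seed(42)
  for (i in 1:25) {
    starts <- sort(runif(8, 0, 60))
    ends <- starts + runif(8, 0.5, 3)
    ends <- pmin(ends, c(starts[-1] - 0.01, Inf))
    b <- data.frame(start_s = starts, end_s = ends)
    full <- apply_refractory_exclusion(b)$included
    head_ <- apply_refractory_exclusion(b[1:7, ])$included
    expect_equal(full[1:7], head_)
  }
})

test_that("peri-event extraction builds the expected grid", {
  d <- structure(list(values = rep(0, 2000), fs = 20, t0_s = 0, f0 = 1,
                      stimulus_onset_s = 10), class = "dff_trace")
  b <- data.frame(start_s = c(20, 40, 60))
  p <- extract_peri_event(d, b, pre_s = 10, post_s = 10)
  expect_equal(ncol(p$values), 401)   # round((10+10)*20)+1
  expect_equal(nrow(p$values), 3)
  expect_true(all(p$values == 0))

  # empty bout list -> 0 rows, not an error
  p0 <- extract_peri_event(d, data.frame(start_s = numeric(0)), 10, 10)
  expect_equal(nrow(p0$values), 0)

  # bouts whose window leaves the trace are dropped with a message
  expect_message(
    p1 <- extract_peri_event(d, data.frame(start_s = c(5, 50)), 10, 10),
    "dropped")
  expect_equal(nrow(p1$values), 1)
})

test_that("bout responses average the 4-s window", {
  fs <- 20
  rel <- seq(-10 * fs, 10 * fs) / fs
  ramp <- ifelse(rel >= 0 & rel < 4, rel * 0.1, 0)
  p <- structure(list(values = rbind(rep(0.1, length(rel)), ramp),
                      rel_time_s = rel, fs = fs, bout_start_s = c(1, 2)),
                 class = "peri_event_matrix")
  r <- bout_response(p)   # default window (0, 4)
  expect_equal(r$mean_dff[1], 0.1)
  # mean of the sampled ramp over [0, 4): 0.1 * mean(0, 0.05, ..., 3.95)
  expect_equal(r$mean_dff[2], 0.1975, tolerance = 1e-12)
  expect_error(bout_response(p, window_s = c(0, 11)), "outside")
})

test_that("session summaries respect inclusion flags and flag missing stimuli", {
  ep <- data.frame(stimulus_label = c("partner", "stranger"))
  resp <- data.frame(
    bout = 1:4, start_s = 1:4,
    mean_dff = c(0.3, 0.1, 0.3, 9.9),
    included = c(TRUE, TRUE, TRUE, FALSE),
    exclusion_reason = c("", "", "", "close"),
    stimulus = c("partner", "stranger", "stranger", "stranger"))
  s <- summarize_session(resp, ep)
  expect_equal(s$mean_dff[s$stimulus == "partner"], 0.3)
  expect_equal(s$mean_dff[s$stimulus == "stranger"], 0.2)

  ep2 <- data.frame(stimulus_label = c("partner", "object"))
  s2 <- summarize_session(resp, ep2)
  expect_true(s2$missing[s2$stimulus == "object"])
  expect_true(is.na(s2$mean_dff[s2$stimulus == "object"]))
})

test_that("pipeline recovers generated bout amplitudes within noise", {
  cfg <- sim_config(seed = 21, session_length_s = 600)
  ses <- generate_photometry_session(cfg, "day7_partner", "a1")
  res <- analyze_photometry_session(ses)
  truth <- mean(ses$ground_truth$true_window_means[res$bouts$included])
  expect_equal(res$summary$mean_dff, truth, tolerance = 0.25)
})

test_that("configured partner > stranger ordering survives the pipeline", {
  ok <- vapply(1:10, function(rep) {
    cfg <- sim_config(seed = 300 + rep, session_length_s = 600)
    vals <- vapply(c("partner", "stranger"), function(st) {
      ses <- generate_photometry_session(cfg, paste0("day7_", st), "a1")
      analyze_photometry_session(ses)$summary$mean_dff
    }, numeric(1))
    vals["partner"] > vals["stranger"]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("negative transient amplitudes yield negative responses", {
  cfg <- sim_config(seed = 8, session_length_s = 600,
                    transient_amp = c(partner = -0.04, stranger = -0.02,
                                      object = 0))
  ses <- generate_photometry_session(cfg, "day7_partner", "a1")
  res <- analyze_photometry_session(ses)
  expect_lt(res$summary$mean_dff, 0)
})
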