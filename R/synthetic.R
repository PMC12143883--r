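#' Simulation configuration for synthetic pair-bonding experiments
#'
#' Builds the configuration object consumed by all generators. Defaults
#' describe a dopamine-sensor-like photometry preparation and medium spiny
#' neuron (MSN)-like voltage-clamp recordings: transients of a few percent
#' dF/F riding on a stable baseline, spontaneous postsynaptic currents (PSCs)
#' around 2 Hz and 20 pA, and a leaky-integrate-and-fire (LIF) cell whose
#' rheobase falls inside the 0-250 pA current-step protocol.
#'
#' @param seed Integer master seed. Every generated object draws from a
#'   private stream derived from `(seed, id)`, so adding sessions to an
#'   experiment never perturbs existing ones.
#' @param fs_photometry Photometry sampling rate (Hz).
#' @param fs_ephys Electrophysiology sampling rate (Hz); acquisition systems
#'   for whole-cell recordings typically digitize at 10 kHz.
#' @param session_length_s Photometry session length (seconds); a full
#'   stimulus-exposure session is 30 min.
#' @param pre_stimulus_s Recording time before stimulus introduction
#'   (seconds); must be at least 10 s to hold the dF/F baseline window.
#' @param transient_amp Named numeric map from behavior/stimulus label to
#'   peak transient amplitude in dF/F units (may be negative, as for neurons
#'   whose activity decreases during social contact).
#' @param transient_amp_sd Between-bout standard deviation of the peak
#'   amplitude (dF/F units).
#' @param animal_scale_sd Between-animal lognormal sd of a multiplicative
#'   gain applied to all of one animal's transient amplitudes.
#' @param transient_tau_rise_s,transient_tau_decay_s Double-exponential
#'   transient kinetics (seconds); decay must exceed rise.
#' @param baseline_f Baseline fluorescence level (arbitrary units).
#' @param noise_sd_photometry Gaussian noise sd on the fluorescence trace
#'   (same arbitrary units as `baseline_f`).
#' @param drift_slope Linear drift added to the trace (fluorescence units per
#'   second); emulates slow photobleaching, 0 by default.
#' @param bout_rate_hz Poisson rate of behavioral bout onsets (Hz).
#' @param bout_duration_s Length-2 numeric `(min, max)` of uniform bout
#'   durations (seconds).
#' @param psc_rate_hz Poisson rate of spontaneous PSCs (Hz).
#' @param psc_amp_mean_pA,psc_amp_sd_pA Normal peak-amplitude distribution of
#'   spontaneous PSCs (pA, magnitudes; sign comes from the holding potential).
#' @param psc_tau_rise_ms,psc_tau_decay_ms Biexponential PSC kinetics (ms).
#' @param cell_rate_sd,cell_amp_sd Between-cell lognormal sd of each cell's
#'   PSC rate and amplitude multipliers; real populations of neurons vary
#'   far more between cells than counting noise alone.
#' @param noise_sd_ephys_pA Gaussian current noise in voltage clamp (pA).
#' @param noise_sd_vm_mV Gaussian voltage noise in current clamp (mV).
#' @param sweep_duration_s Duration of one spontaneous voltage-clamp sweep
#'   (seconds).
#' @param evoked_amp_epsc_pA,evoked_amp_ipsc_pA Mean evoked PSC magnitudes at
#'   the two holding potentials (pA).
#' @param evoked_amp_cv Coefficient of variation of evoked amplitudes across
#'   trials.
#' @param evoked_n_trials Trials per holding potential in the evoked
#'   protocol; the study design records 20 events per potential.
#' @param lif_params Named numeric vector `(R_MOhm, tau_m_ms, V_rest_mV,
#'   V_thresh_mV, V_reset_mV)` of the LIF cell.
#' @param step_currents_pA Injected current steps (pA), 0-250 pA range.
#' @param step_duration_s Current-step duration (seconds; 1000 ms steps).
#' @param bath_total_s Total bath-application recording span (seconds);
#'   the drug protocol records 40 min per cell.
#' @param bath_window_s Length of the analyzed baseline and drug windows
#'   (seconds); the first and last 10 min of the recording.
#' @param da_freq_ratio,da_amp_ratio Multipliers applied to PSC rate and
#'   amplitude in the drug window when no group-specific effect is supplied.
#' @param trial_span_s Partner-preference trial span (seconds); 3 h.
#' @param side_time_mean_s,side_time_sd_s Normal draw (truncated at 0) of the
#'   time spent on each stimulus side (seconds).
#' @param sbs_partner_mean_s,sbs_stranger_mean_s,sbs_sd_s Side-by-side
#'   contact time draws (seconds).
#' @param group_effects Named list mapping `"<group-or-arm>.<measure>"` to an
#'   effect value. Recognized measures: `side_partner_s`, `side_stranger_s`,
#'   `sbs_partner_s`, `sbs_stranger_s` (additive seconds);
#'   `sepsc_freq_ratio`, `sepsc_amp_ratio`, `epsc_amp_ratio`,
#'   `ipsc_amp_ratio`, `da_freq_ratio`, `da_amp_ratio` (multipliers);
#'   `rheobase_shift_pa` (additive pA, implemented as a threshold shift);
#'   `amp_shift.<behavior>` (additive dF/F on a transient amplitude).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$transient_amp
sim_config <- function(seed = 1L,
                       fs_photometry = 20,
                       fs_ephys = 10000,
                       session_length_s = 1800,
                       pre_stimulus_s = 30,
                       transient_amp = c(partner = 0.04, stranger = 0.025,
                                         object = 0.005),
                       transient_amp_sd = 0.01,
                       animal_scale_sd = 0.2,
                       transient_tau_rise_s = 0.2,
                       transient_tau_decay_s = 1.5,
                       baseline_f = 100,
                       noise_sd_photometry = 1,
                       drift_slope = 0,
                       bout_rate_hz = 0.05,
                       bout_duration_s = c(1, 4),
                       psc_rate_hz = 2,
                       psc_amp_mean_pA = 20,
                       psc_amp_sd_pA = 6,
                       psc_tau_rise_ms = 0.5,
                       psc_tau_decay_ms = 5,
                       cell_rate_sd = 0.4,
                       cell_amp_sd = 0.15,
                       noise_sd_ephys_pA = 2,
                       noise_sd_vm_mV = 0.3,
                       sweep_duration_s = 60,
                       evoked_amp_epsc_pA = 100,
                       evoked_amp_ipsc_pA = 80,
                       evoked_amp_cv = 0.15,
                       evoked_n_trials = 20,
                       lif_params = c(R_MOhm = 200, tau_m_ms = 20,
                                      V_rest_mV = -80, V_thresh_mV = -45,
                                      V_reset_mV = -60),
                       step_currents_pA = seq(0, 250, by = 25),
                       step_duration_s = 1,
                       bath_total_s = 2400,
                       bath_window_s = 600,
                       da_freq_ratio = 0.5,
                       da_amp_ratio = 0.8,
                       trial_span_s = 3 * 3600,
                       side_time_mean_s = 3600,
                       side_time_sd_s = 600,
                       sbs_partner_mean_s = 1200,
                       sbs_stranger_mean_s = 800,
                       sbs_sd_s = 350,
                       group_effects = list()) {
  assert_scalar_pos(fs_photometry, "fs_photometry")
  assert_scalar_pos(fs_ephys, "fs_ephys")
  assert_scalar_pos(session_length_s, "session_length_s")
  if (transient_tau_decay_s <= transient_tau_rise_s) {
    stop("transient_tau_decay_s must exceed transient_tau_rise_s")
  }
  if (psc_tau_decay_ms <= psc_tau_rise_ms) {
    stop("psc_tau_decay_ms must exceed psc_tau_rise_ms")
  }
  if (length(bout_duration_s) != 2L || bout_duration_s[1] > bout_duration_s[2]) {
    stop("bout_duration_s must be (min, max) with min <= max")
  }
  if (is.null(names(transient_amp)) || any(!nzchar(names(transient_amp)))) {
    stop("transient_amp must be a named vector (behavior label -> dF/F)")
  }
  need <- c("R_MOhm", "tau_m_ms", "V_rest_mV", "V_thresh_mV", "V_reset_mV")
  if (!all(need %in% names(lif_params))) {
    stop("lif_params must name ", paste(need, collapse = ", "))
  }
  cfg <- mget(names(formals(sim_config)), envir = environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Canonical study-like group-effect map
#'
#' The package's reference parameterization of the between-group effects a
#' pair-bonding experiment exhibits, expressed in generator units: paired
#' (cohabitation) cells show more frequent and larger spontaneous EPSCs and
#' a shifted evoked excitation-inhibition balance; bath dopamine suppresses
#' spontaneous EPSCs in naive (control) cells but no longer in paired ones;
#' chemogenetic inhibition of the target projection (Gi + CNO) increases
#' partner-directed side-by-side contact while activation (Gq + CNO)
#' decreases it. Magnitudes are chosen so that group contrasts at the
#' study's sample sizes are detectable but not trivial; directions follow
#' the D2-type phenotype.
#'
#' @return Named list suitable for `sim_config(group_effects = ...)`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, group_effects = study_effects())
study_effects <- function() {
  list(
    "cohabitation.sepsc_freq_ratio" = 1.6,
    "cohabitation.sepsc_amp_ratio" = 1.25,
    "cohabitation.epsc_amp_ratio" = 1.9,
    "cohabitation.da_freq_ratio" = 1.0,
    "cohabitation.da_amp_ratio" = 1.0,
    "Gi_CNO.sbs_partner_s" = 600,
    "Gq_CNO.sbs_partner_s" = -500
  )
}

# Lookup of one group/arm-scoped effect with a fallback default.
ge_lookup <- function(config, scope, measure, default) {
  v <- config$group_effects[[paste0(scope, ".", measure)]]
  if (is.null(v)) default else v
}

# Unit-peak double-exponential kernel evaluated at times t >= 0.
biexp_kernel <- function(t, tau_rise, tau_decay) {
  raw <- exp(-t / tau_decay) - exp(-t / tau_rise)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  raw / peak
}

# Mean of the unit-peak kernel over [0, window_s): links a configured peak
# amplitude to the expected windowed dF/F response.
kernel_window_mean <- function(tau_rise, tau_decay, window_s) {
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  integ <- tau_decay * (1 - exp(-window_s / tau_decay)) -
    tau_rise * (1 - exp(-window_s / tau_rise))
  integ / (window_s * peak)
}

# Non-overlapping behavioral bouts with Poisson onsets on [from, to).
draw_bouts <- function(rate_hz, from, to, dur_range) {
  if (rate_hz <= 0 || to <= from) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  onsets <- numeric(0)
  t <- from + stats::rexp(1, rate_hz)
  while (t < to) {
    onsets <- c(onsets, t)
    t <- t + stats::rexp(1, rate_hz)
  }
  if (!length(onsets)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  dur <- stats::runif(length(onsets), dur_range[1], dur_range[2])
  # keep bouts of one behavior non-overlapping without disturbing onsets
  gap_to_next <- c(diff(onsets), Inf)
  dur <- pmin(dur, gap_to_next - 0.05, to - onsets)
  data.frame(start_s = onsets, end_s = onsets + pmax(dur, 0.05))
}

#' Generate one synthetic fiber-photometry session
#'
#' Simulates a single stimulus-exposure session: a pre-stimulus baseline
#' period, then Poisson-timed behavioral bouts, each locking a
#' double-exponential fluorescence transient onto a stable baseline. The
#' transient is multiplicative on the baseline so the downstream dF/F
#' recovers the configured amplitude regardless of optical gain. Negative
#' amplitudes (activity decreases) are supported; the fluorescence is floored
#' at 1% of baseline with a warning if a draw would push it below that.
#'
#' @param config A [sim_config()].
#' @param condition Session condition, `"<day>_<stimulus>"` with day in
#'   `day3`/`day7` and stimulus in the names of `config$transient_amp`
#'   (e.g. `"day7_partner"`).
#' @param animal_id Identifier used both for labeling and to derive the
#'   session's private random stream.
#' @return A list of class `photometry_session` with elements `trace`
#'   (a [photometry_trace()]), `events` (data.frame `behavior`, `start_s`,
#'   `end_s`), `epochs` (data.frame `stimulus_label`, `stimulus_onset_s`,
#'   `epoch_end_s`), `animal_id`, `condition`, and `ground_truth` with
#'   `true_bout_amplitudes` (peak dF/F per bout) and
#'   `true_window_means` (expected mean dF/F over the 4-s response window).
#' @export
generate_photometry_session <- function(config, condition,
                                        animal_id = "animal1") {
  stopifnot(inherits(config, "sim_config"))
  parts <- strsplit(condition, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("day3", "day7") ||
      !parts[2] %in% names(config$transient_amp)) {
    stop("condition must be '<day3|day7>_<",
         paste(names(config$transient_amp), collapse = "|"), ">'")
  }
  stimulus <- parts[2]
  if (config$session_length_s < config$pre_stimulus_s + 20 ||
      config$pre_stimulus_s < 10) {
    stop("session too short: need >= 10 s pre-stimulus baseline plus epoch")
  }

  with_stream(config$seed, paste("photometry", animal_id, condition), {
    fs <- config$fs_photometry
    n <- round(config$session_length_s * fs)
    tt <- (seq_len(n) - 1L) / fs
    onset <- config$pre_stimulus_s
    epoch_end <- config$session_length_s

    animal_scale <- exp(stats::rnorm(1, 0, config$animal_scale_sd))
    amp0 <- config$transient_amp[[stimulus]] +
      ge_lookup(config, parts[1], paste0("amp_shift.", stimulus), 0)

    bouts <- draw_bouts(config$bout_rate_hz, onset + 2,
                        epoch_end - 12, config$bout_duration_s)
    n_bouts <- nrow(bouts)
    amps <- if (n_bouts) {
      stats::rnorm(n_bouts, amp0 * animal_scale, config$transient_amp_sd)
    } else numeric(0)

    rel_gain <- numeric(n)
    for (i in seq_len(n_bouts)) {
      idx <- which(tt >= bouts$start_s[i])
      rel_gain[idx] <- rel_gain[idx] +
        amps[i] * biexp_kernel(tt[idx] - bouts$start_s[i],
                               config$transient_tau_rise_s,
                               config$transient_tau_decay_s)
    }
    f <- config$baseline_f * (1 + rel_gain) +
      config$drift_slope * tt +
      stats::rnorm(n, 0, config$noise_sd_photometry)
    floor_f <- 0.01 * config$baseline_f
    if (any(f < floor_f)) {
      warning("fluorescence floored at 1% of baseline for ",
              sum(f < floor_f), " samples")
      f[f < floor_f] <- floor_f
    }

    wm <- kernel_window_mean(config$transient_tau_rise_s,
                             config$transient_tau_decay_s, 4)
    structure(list(
      trace = photometry_trace(f, fs = fs, t0_s = 0),
      events = data.frame(behavior = rep(stimulus, n_bouts),
                          start_s = bouts$start_s, end_s = bouts$end_s),
      epochs = data.frame(stimulus_label = stimulus,
                          stimulus_onset_s = onset,
                          epoch_end_s = epoch_end),
      animal_id = animal_id,
      condition = condition,
      ground_truth = list(true_bout_amplitudes = amps,
                          true_window_means = amps * wm,
                          animal_scale = animal_scale)
    ), class = "photometry_session")
  })
}

# Insert unit-peak biexponential PSCs at `times_s` into a zero trace.
render_psc_train <- function(n, fs, times_s, amps, tau_rise_ms, tau_decay_ms) {
  out <- numeric(n)
  tau_r <- tau_rise_ms / 1000
  tau_d <- tau_decay_ms / 1000
  span <- ceiling(fs * (tau_d * 8 + tau_r))
  kern_t <- (0:span) / fs
  kern <- biexp_kernel(kern_t, tau_r, tau_d)
  for (i in seq_along(times_s)) {
    i0 <- floor(times_s[i] * fs) + 1L
    idx <- i0:min(i0 + span, n)
    out[idx] <- out[idx] + amps[i] * kern[seq_along(idx)]
  }
  out
}

# Leaky-integrate-and-fire response to a constant current step. Spikes are
# painted as brief +30 mV excursions so a threshold-crossing counter sees
# exactly the integrator's spikes.
simulate_lif <- function(I_pA, lif, fs, duration_s, noise_sd_mV = 0,
                         thresh_shift_mV = 0) {
  dt <- 1 / fs
  n <- round(duration_s * fs)
  R <- lif[["R_MOhm"]] / 1000   # mV per pA
  tau <- lif[["tau_m_ms"]] / 1000
  v_rest <- lif[["V_rest_mV"]]
  v_th <- lif[["V_thresh_mV"]] + thresh_shift_mV
  v_reset <- lif[["V_reset_mV"]]
  spike_w <- max(1L, round(0.0005 * fs))  # 0.5 ms painted spike

  v <- numeric(n)
  vcur <- v_rest
  spikes <- 0L
  spike_times <- numeric(0)
  i <- 1L
  while (i <= n) {
    vcur <- vcur + dt * (-(vcur - v_rest) + R * I_pA) / tau
    if (vcur >= v_th) {
      spikes <- spikes + 1L
      spike_times <- c(spike_times, (i - 1L) / fs)
      j <- i:min(i + spike_w - 1L, n)
      v[j] <- 30
      i <- max(j) + 1L
      vcur <- v_reset
    } else {
      v[i] <- vcur
      i <- i + 1L
    }
  }
  if (noise_sd_mV > 0) {
    v <- v + stats::rnorm(n, 0, noise_sd_mV)
  }
  list(v = v, n_spikes = spikes, spike_times = spike_times)
}

#' Generate a synthetic patch-clamp sweep set
#'
#' Produces the voltage- or current-clamp sweeps of one simulated cell under
#' one of four protocols:
#' \describe{
#'   \item{`spontaneous_vclamp`}{One long sweep of Poisson-timed
#'     biexponential spontaneous PSCs plus Gaussian current noise. Polarity
#'     follows the holding potential: inward (negative) at -70 mV, outward
#'     (positive) at 0 mV.}
#'   \item{`evoked_vclamp`}{Exactly `evoked_n_trials` (20 by design) short
#'     trials at each of -70 mV (EPSC) and 0 mV (IPSC), each with one evoked
#'     PSC of configurable mean amplitude at a fixed latency.}
#'   \item{`current_steps`}{One 1000-ms leaky-integrate-and-fire voltage
#'     response per injected step current (0-250 pA); the integrator's spike
#'     count per step is recorded as ground truth.}
#'   \item{`bath_da`}{Two spontaneous sweeps representing the analyzed
#'     windows of a 40-min bath-application recording: the pre-drug baseline
#'     (start of recording) and the drug window (end of recording), with the
#'     PSC rate and amplitude scaled by the drug-effect ratios.}
#' }
#'
#' @param config A [sim_config()].
#' @param protocol One of `"spontaneous_vclamp"`, `"evoked_vclamp"`,
#'   `"current_steps"`, `"bath_da"`.
#' @param group Group label (e.g. `"control"`, `"cohabitation"`); scoped
#'   entries of `config$group_effects` are applied to rates and amplitudes.
#' @param cell_id Identifier; also seeds the cell's private random stream.
#' @param holding_mV Holding potential for `spontaneous_vclamp`/`bath_da`
#'   (-70 for excitatory, 0 for inhibitory currents).
#' @return A list of class `sweep_set`: `cell_id`, `group`, `protocol`,
#'   `fs`, `units`, `sweeps` (each with `samples`, `duration_s`, plus
#'   `holding_mV` or `step_pA`, `label`, `window_start_s`),
#'   `meta` (e.g. `total_recording_s`, `access_resistance_ok`), and
#'   `ground_truth` (`true_psc_times_s` per sweep, `true_spike_counts`).
#' @export
generate_sweep_set <- function(config, protocol, group = "control",
                               cell_id = "cell1", holding_mV = -70) {
  stopifnot(inherits(config, "sim_config"))
  protocols <- c("spontaneous_vclamp", "evoked_vclamp", "current_steps",
                 "bath_da")
  if (!protocol %in% protocols) {
    stop("unknown protocol '", protocol, "'; expected one of ",
         paste(protocols, collapse = ", "))
  }

  with_stream(config$seed, paste("sweeps", cell_id, protocol, group), {
    fs <- config$fs_ephys
    out <- list(cell_id = cell_id, group = group, protocol = protocol,
                fs = fs, sweeps = list(),
                meta = list(access_resistance_ok = TRUE),
                ground_truth = list())
    sign_for <- function(hold) if (hold < -35) -1 else 1
    # every cell carries its own multiplicative rate/amplitude factors
    cell_rate <- exp(stats::rnorm(1, 0, config$cell_rate_sd))
    cell_amp <- exp(stats::rnorm(1, 0, config$cell_amp_sd))

    spont_sweep <- function(duration_s, hold, rate, amp_scale) {
      n <- round(duration_s * fs)
      n_ev <- stats::rpois(1, rate * duration_s)
      times <- sort(stats::runif(n_ev, 0, duration_s - 0.05))
      amps <- pmax(stats::rnorm(n_ev, config$psc_amp_mean_pA * amp_scale,
                                config$psc_amp_sd_pA), 1)
      x <- render_psc_train(n, fs, times, sign_for(hold) * amps,
                            config$psc_tau_rise_ms, config$psc_tau_decay_ms)
      x <- x + stats::rnorm(n, 0, config$noise_sd_ephys_pA)
      list(samples = x, times = times)
    }

    if (protocol == "spontaneous_vclamp") {
      rate <- config$psc_rate_hz * cell_rate *
        ge_lookup(config, group, "sepsc_freq_ratio", 1)
      ampr <- cell_amp * ge_lookup(config, group, "sepsc_amp_ratio", 1)
      sw <- spont_sweep(config$sweep_duration_s, holding_mV, rate, ampr)
      out$units <- "pA"
      out$sweeps <- list(list(samples = sw$samples, holding_mV = holding_mV,
                              duration_s = config$sweep_duration_s,
                              label = "spontaneous", window_start_s = 0))
      out$ground_truth$true_psc_times_s <- list(sw$times)
    } else if (protocol == "evoked_vclamp") {
      trial_s <- 0.5
      stim_at <- 0.1
      n <- round(trial_s * fs)
      mk_trial <- function(hold, mean_amp) {
        amp <- max(stats::rnorm(1, mean_amp,
                                config$evoked_amp_cv * mean_amp), 1)
        x <- render_psc_train(n, fs, stim_at, sign_for(hold) * amp,
                              config$psc_tau_rise_ms, config$psc_tau_decay_ms)
        x <- x + stats::rnorm(n, 0, config$noise_sd_ephys_pA)
        list(samples = x, holding_mV = hold, duration_s = trial_s,
             label = if (hold < -35) "evoked_epsc" else "evoked_ipsc",
             stim_at_s = stim_at, window_start_s = 0)
      }
      # excitatory and inhibitory inputs vary independently across cells,
      # so the E/I ratio itself is variable between cells
      cell_amp_i <- exp(stats::rnorm(1, 0, config$cell_amp_sd))
      e_amp <- config$evoked_amp_epsc_pA * cell_amp *
        ge_lookup(config, group, "epsc_amp_ratio", 1)
      i_amp <- config$evoked_amp_ipsc_pA * cell_amp_i *
        ge_lookup(config, group, "ipsc_amp_ratio", 1)
      out$units <- "pA"
      out$sweeps <- c(
        lapply(seq_len(config$evoked_n_trials), function(k) mk_trial(-70, e_amp)),
        lapply(seq_len(config$evoked_n_trials), function(k) mk_trial(0, i_amp))
      )
    } else if (protocol == "current_steps") {
      shift <- ge_lookup(config, group, "rheobase_shift_pa", 0) *
        config$lif_params[["R_MOhm"]] / 1000
      out$units <- "mV"
      counts <- integer(length(config$step_currents_pA))
      times <- vector("list", length(config$step_currents_pA))
      out$sweeps <- lapply(seq_along(config$step_currents_pA), function(i) {
        sim <- simulate_lif(config$step_currents_pA[i], config$lif_params,
                            fs, config$step_duration_s,
                            config$noise_sd_vm_mV, shift)
        counts[i] <<- sim$n_spikes
        times[[i]] <<- sim$spike_times
        list(samples = sim$v, step_pA = config$step_currents_pA[i],
             duration_s = config$step_duration_s, label = "step",
             window_start_s = 0)
      })
      out$ground_truth$true_spike_counts <- counts
      out$ground_truth$true_spike_times_s <- times
    } else { # bath_da
      if (config$bath_total_s < 2 * config$bath_window_s) {
        stop("bath_total_s must hold two non-overlapping analysis windows")
      }
      base_rate <- config$psc_rate_hz * cell_rate *
        ge_lookup(config, group, "sepsc_freq_ratio", 1)
      base_amp <- cell_amp * ge_lookup(config, group, "sepsc_amp_ratio", 1)
      fr <- ge_lookup(config, group, "da_freq_ratio", config$da_freq_ratio)
      ar <- ge_lookup(config, group, "da_amp_ratio", config$da_amp_ratio)
      b <- spont_sweep(config$bath_window_s, holding_mV, base_rate, base_amp)
      d <- spont_sweep(config$bath_window_s, holding_mV, base_rate * fr,
                       base_amp * ar)
      out$units <- "pA"
      out$meta$total_recording_s <- config$bath_total_s
      out$meta$drug <- "DA 5 uM"
      out$sweeps <- list(
        list(samples = b$samples, holding_mV = holding_mV,
             duration_s = config$bath_window_s, label = "baseline",
             window_start_s = 0),
        list(samples = d$samples, holding_mV = holding_mV,
             duration_s = config$bath_window_s, label = "da",
             window_start_s = config$bath_total_s - config$bath_window_s)
      )
      out$ground_truth$true_psc_times_s <- list(b$times, d$times)
    }
    class(out) <- "sweep_set"
    out
  })
}

#' Generate one synthetic partner-preference trial
#'
#' Draws per-subject chamber-side occupancy and side-by-side contact times
#' for a 3-h three-chamber partner-preference test. Baseline draws are
#' symmetric between partner and stranger sides (so the expected preference
#' ratio is zero); entries of `config$group_effects` scoped to `arm` shift
#' the means additively (in seconds), which is how chemogenetic group
#' effects are injected.
#'
#' @param config A [sim_config()].
#' @param arm Trial arm, `"<virus>_<drug>"` with virus in `Gq`/`Gi`/`mCherry`
#'   and drug in `CNO`/`saline`.
#' @param subject_id Identifier; seeds the subject's private random stream.
#' @return A list of class `preference_trial` with `subject_id`, `arm`,
#'   `time_partner_side_s`, `time_stranger_side_s`, `side_by_side_partner_s`,
#'   `side_by_side_stranger_s`, `trial_span_s`.
#' @export
generate_preference_trial <- function(config, arm, subject_id = "subj1") {
  stopifnot(inherits(config, "sim_config"))
  parts <- strsplit(arm, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("Gq", "Gi", "mCherry") ||
      !parts[2] %in% c("CNO", "saline")) {
    stop("arm must be '<Gq|Gi|mCherry>_<CNO|saline>'")
  }
  with_stream(config$seed, paste("preference", subject_id, arm), {
    span <- config$trial_span_s
    # side-by-side huddling happens while on that side, so a side-by-side
    # effect also extends the corresponding side-occupancy mean
    p_shift <- ge_lookup(config, arm, "side_partner_s", 0) +
      ge_lookup(config, arm, "sbs_partner_s", 0)
    s_shift <- ge_lookup(config, arm, "side_stranger_s", 0) +
      ge_lookup(config, arm, "sbs_stranger_s", 0)
    p_side <- max(stats::rnorm(1, config$side_time_mean_s + p_shift,
                               config$side_time_sd_s), 0)
    s_side <- max(stats::rnorm(1, config$side_time_mean_s + s_shift,
                               config$side_time_sd_s), 0)
    if (p_side + s_side > 0.95 * span) {
      sc <- 0.95 * span / (p_side + s_side)
      p_side <- p_side * sc
      s_side <- s_side * sc
    }
    sbs_p <- max(stats::rnorm(1, config$sbs_partner_mean_s +
                                ge_lookup(config, arm, "sbs_partner_s", 0),
                              config$sbs_sd_s), 0)
    sbs_s <- max(stats::rnorm(1, config$sbs_stranger_mean_s +
                                ge_lookup(config, arm, "sbs_stranger_s", 0),
                              config$sbs_sd_s), 0)
    structure(list(subject_id = subject_id, arm = arm,
                   time_partner_side_s = p_side,
                   time_stranger_side_s = s_side,
                   side_by_side_partner_s = min(sbs_p, p_side),
                   side_by_side_stranger_s = min(sbs_s, s_side),
                   trial_span_s = span),
              class = "preference_trial")
  })
}
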