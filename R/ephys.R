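#' Spontaneous PSC detection by sliding template fit
#'
#' Slides a biexponential PSC template along a voltage-clamp sweep, fitting
#' scale and offset by least squares at every position (the classic
#' template-matching detector for spontaneous synaptic events). A detection
#' requires both the detection criterion (fitted scale divided by the
#' residual standard deviation) and the fitted peak amplitude to clear their
#' thresholds; nearby detections are merged keeping the larger peak.
#'
#' @param sweep One sweep: a list with `samples` (pA), or a numeric vector.
#' @param fs Sampling rate (Hz); taken from `sweep$fs` if present.
#' @param polarity `"inward"` (negative events, holding -70 mV) or
#'   `"outward"` (positive events, holding 0 mV).
#' @param amp_threshold_pA Minimum fitted peak amplitude (pA).
#' @param crit_threshold Minimum detection criterion (scale / residual SD).
#' @param tau_rise_ms,tau_decay_ms Template kinetics (ms).
#' @param min_interval_ms Minimum separation between event onsets (ms).
#' @return data.frame with `onset_s`, `peak_amplitude_pA` (signed),
#'   `rise_10_90_ms`, `decay_tau_ms`, `polarity`, sorted by onset.
#' @export
detect_events <- function(sweep, fs = NULL,
                          polarity = c("inward", "outward"),
                          amp_threshold_pA = 5,
                          crit_threshold = 3.5,
                          tau_rise_ms = 0.5, tau_decay_ms = 5,
                          min_interval_ms = 2) {
  polarity <- match.arg(polarity)
  if (is.list(sweep)) {
    if (!is.null(sweep$holding_mV)) {
      want <- if (sweep$holding_mV < -35) "inward" else "outward"
      if (want != polarity) {
        stop("polarity '", polarity, "' inconsistent with holding potential ",
             sweep$holding_mV, " mV")
      }
    }
    fs <- fs %||% sweep$fs
    sweep <- sweep$samples
  }
  if (is.null(fs)) stop("sampling rate fs required")
  sgn <- if (polarity == "inward") -1 else 1
  y <- sgn * as.numeric(sweep)   # events now positive
  n <- length(y)

  # window spans the rise and ~3 decay constants: long enough to pin the
  # template, short enough that closely spaced events keep separate fits
  N <- max(8L, round((tau_rise_ms + 3 * tau_decay_ms) / 1000 * fs))
  e <- biexp_kernel((0:(N - 1)) / fs, tau_rise_ms / 1000, tau_decay_ms / 1000)
  empty <- data.frame(onset_s = numeric(0), peak_amplitude_pA = numeric(0),
                      rise_10_90_ms = numeric(0), decay_tau_ms = numeric(0),
                      polarity = character(0))
  if (n < N) return(empty)

  Se <- sum(e)
  See <- sum(e^2)
  # sliding sums over windows starting at i = 1 .. n-N+1
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  i_end <- N:n
  Sy <- cs[i_end + 1L] - cs[i_end + 1L - N]
  Syy <- cs2[i_end + 1L] - cs2[i_end + 1L - N]
  Ey <- xcorr_template(y, e)

  scale <- (Ey - Se * Sy / N) / (See - Se^2 / N)
  offset <- (Sy - scale * Se) / N
  sse <- Syy + scale^2 * See + N * offset^2 -
    2 * (scale * Ey + offset * Sy - scale * offset * Se)
  sse[sse < 0] <- 0
  crit <- scale / sqrt(sse / (N - 1) + 1e-12)

  hits <- crit >= crit_threshold & scale >= amp_threshold_pA
  if (!any(hits)) return(empty)
  # candidate onsets = local maxima of the criterion inside the
  # supra-threshold region, so overlapping events in one run each keep
  # their own peak
  m <- length(crit)
  is_peak <- hits &
    crit >= c(-Inf, crit[-m]) &
    crit > c(crit[-1], -Inf)
  onsets <- which(is_peak)
  amps <- scale[onsets]
  # reject re-detections on the decay shoulder of a prior event: the peak
  # must rise by at least the amplitude threshold above the local pre-onset
  # baseline (median of the 2 ms before onset)
  pre <- max(1L, round(0.002 * fs))
  local_amp <- vapply(onsets, function(o) {
    pk <- max(y[o:min(o + N, n)])
    pk - stats::median(y[max(1L, o - pre):o])
  }, numeric(1))
  keep0 <- local_amp >= amp_threshold_pA
  onsets <- onsets[keep0]
  amps <- amps[keep0]
  if (!length(onsets)) return(empty)
  # enforce minimum inter-event interval, keeping the larger peak
  min_gap <- round(min_interval_ms / 1000 * fs)
  o <- sort(onsets)
  a <- amps[order(onsets)]
  keep <- rep(TRUE, length(o))
  last <- 1L
  for (i in seq_along(o)[-1]) {
    if (o[i] - o[last] < min_gap) {
      if (a[i] > a[last]) keep[last] <- FALSE else keep[i] <- FALSE
      if (keep[i]) last <- i
    } else last <- i
  }
  o <- o[keep]
  a <- a[keep]

  kin <- t(vapply(seq_along(o), function(i) {
    event_kinetics(y, o[i], min(o[i] + N - 1L, n), fs)
  }, numeric(2)))
  data.frame(onset_s = (o - 1L) / fs,
             peak_amplitude_pA = sgn * a,
             rise_10_90_ms = kin[, 1],
             decay_tau_ms = kin[, 2],
             polarity = polarity)
}

# FFT cross-correlation: r_i = sum_j e_j * y[i + j - 1], i = 1 .. n-N+1.
# Padded to a power of two so the transform length is always FFT-friendly.
xcorr_template <- function(y, e) {
  n <- length(y)
  N <- length(e)
  L <- stats::nextn(n + N - 1L, 2)
  fy <- stats::fft(c(y, numeric(L - n)))
  fe <- stats::fft(c(e, numeric(L - N)))
  r <- Re(stats::fft(fy * Conj(fe), inverse = TRUE)) / L
  r[seq_len(n - N + 1L)]
}

# 10-90% rise time and log-linear decay tau of one positive-going event.
event_kinetics <- function(y, i0, i1, fs) {
  seg <- y[i0:i1]
  base <- seg[1]
  pk <- which.max(seg)
  amp <- seg[pk] - base
  if (amp <= 0 || pk < 2L) return(c(NA_real_, NA_real_))
  up <- seg[1:pk] - base
  t10 <- which(up >= 0.1 * amp)[1]
  t90 <- which(up >= 0.9 * amp)[1]
  rise <- if (!is.na(t10) && !is.na(t90)) (t90 - t10) / fs * 1000 else NA_real_
  dec <- seg[pk:length(seg)] - base
  j <- which(dec <= 0.1 * amp)[1]
  if (is.na(j)) j <- length(dec)
  tau <- NA_real_
  if (j >= 3) {
    v <- dec[1:j]
    ok <- v > 0
    if (sum(ok) >= 3) {
      tt <- (which(ok) - 1L) / fs
      fit <- stats::lm.fit(cbind(1, tt), log(v[ok]))
      sl <- fit$coefficients[2]
      if (is.finite(sl) && sl < 0) tau <- -1000 / sl  # ms
    }
  }
  c(rise, tau)
}

#' Frequency and amplitude summary of detected events
#'
#' @param events data.frame from [detect_events()].
#' @param duration_s Recorded duration the events came from (seconds).
#' @return data.frame with `n_events`, `frequency_hz` (count / duration),
#'   `mean_amplitude_pA` (mean absolute peak; NA-flagged when no events).
#' @export
#' @examples
#' ev <- data.frame(peak_amplitude_pA = c(-20, -30))
#' event_stats(ev, 60)$frequency_hz  # 2/60
event_stats <- function(events, duration_s) {
  assert_scalar_pos(duration_s, "duration_s")
  n <- nrow(events)
  data.frame(n_events = n,
             frequency_hz = n / duration_s,
             mean_amplitude_pA = if (n) mean(abs(events$peak_amplitude_pA))
                                 else NA_real_)
}

# Baseline-subtracted peak magnitude of one evoked trial.
evoked_peak <- function(trial, fs, stim_at_s = NULL) {
  stim <- stim_at_s %||% trial$stim_at_s %||% 0.1
  x <- trial$samples
  i_stim <- round(stim * fs) + 1L
  base <- mean(x[seq_len(max(i_stim - 1L, 1L))])
  resp <- x[i_stim:length(x)] - base
  max(abs(resp))
}

#' Evoked excitation-inhibition ratio for one cell
#'
#' Per-trial peak amplitudes are measured on baseline-subtracted traces
#' (pre-stimulus mean removed per trial), averaged within each holding
#' potential, and the ratio formed as mean EPSC amplitude divided by mean
#' IPSC amplitude. The design requires exactly `n_required` (20) trials per
#' potential; a shortfall is an error naming it.
#'
#' @param epsc_trials,ipsc_trials Lists of trial sweeps (each with
#'   `samples`, and optionally `stim_at_s`).
#' @param fs Sampling rate (Hz).
#' @param n_required Required trials per holding potential.
#' @return data.frame with `mean_epsc_pA`, `mean_ipsc_pA`, `raw_ratio`.
#' @export
evoked_ei_ratio <- function(epsc_trials, ipsc_trials, fs, n_required = 20) {
  if (length(epsc_trials) != n_required || length(ipsc_trials) != n_required) {
    stop(sprintf(
      "need exactly %d trials per holding potential; got %d EPSC, %d IPSC",
      n_required, length(epsc_trials), length(ipsc_trials)))
  }
  me <- mean(vapply(epsc_trials, evoked_peak, numeric(1), fs = fs))
  mi <- mean(vapply(ipsc_trials, evoked_peak, numeric(1), fs = fs))
  if (mi <= 0) stop("mean IPSC amplitude must be positive")
  data.frame(mean_epsc_pA = me, mean_ipsc_pA = mi, raw_ratio = me / mi)
}

#' E/I ratio of one sweep set from the evoked protocol
#'
#' @param sweep_set A `sweep_set` with protocol `evoked_vclamp`.
#' @param n_required Required trials per holding potential.
#' @return As [evoked_ei_ratio()], with `cell_id` and `group` columns.
#' @export
ei_ratio_from_sweep_set <- function(sweep_set, n_required = 20) {
  stopifnot(inherits(sweep_set, "sweep_set"))
  if (sweep_set$protocol != "evoked_vclamp") {
    stop("sweep set is not from the evoked protocol")
  }
  hold <- vapply(sweep_set$sweeps, `[[`, numeric(1), "holding_mV")
  r <- evoked_ei_ratio(sweep_set$sweeps[hold < -35],
                       sweep_set$sweeps[hold >= -35],
                       fs = sweep_set$fs, n_required = n_required)
  cbind(data.frame(cell_id = sweep_set$cell_id, group = sweep_set$group), r)
}

#' Normalize E/I ratios to the control-group mean
#'
#' Divides every cell's raw ratio by the mean raw ratio of the control
#' group, so the control group's normalized mean is 1 by construction.
#'
#' @param results data.frame with columns `raw_ratio` and `group`.
#' @param control_group Label of the control group.
#' @return `results` with a `normalized_ratio` column added.
#' @export
normalize_ei <- function(results, control_group = "control") {
  ctrl <- results$raw_ratio[results$group == control_group]
  if (!length(ctrl)) stop("no cells in control group '", control_group, "'")
  results$normalized_ratio <- results$raw_ratio / mean(ctrl)
  results
}

#' Count action potentials in a current-clamp sweep
#'
#' Spikes are upward crossings of a fixed voltage threshold (0 mV by
#' default) with a refractory gap so one spike is never counted twice.
#'
#' @param v Numeric membrane-potential samples (mV), or a sweep list.
#' @param fs Sampling rate (Hz).
#' @param threshold_mV Crossing threshold (mV).
#' @param refractory_ms Minimum spacing between counted crossings (ms).
#' @return Integer spike count.
#' @export
count_spikes <- function(v, fs, threshold_mV = 0, refractory_ms = 2) {
  if (is.list(v)) {
    fs <- fs %||% v$fs
    v <- v$samples
  }
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV)
  if (!length(up)) return(0L)
  gap <- round(refractory_ms / 1000 * fs)
  kept <- up[1]
  for (i in up[-1]) if (i - kept[length(kept)] >= gap) kept <- c(kept, i)
  length(kept)
}

#' F-I curve and rheobase from a current-step sweep set
#'
#' @param sweep_set A `sweep_set` with protocol `current_steps` (1000-ms
#'   steps over 0-250 pA).
#' @param threshold_mV Spike-detection threshold (mV).
#' @return List of class `fi_curve`: `step_currents_pA`, `spike_counts`,
#'   `rheobase_pA` (smallest step with >= 1 spike; NA with
#'   `rheobase_defined = FALSE` if no step spikes).
#' @export
fi_curve <- function(sweep_set, threshold_mV = 0) {
  stopifnot(inherits(sweep_set, "sweep_set"))
  if (sweep_set$protocol != "current_steps") {
    stop("sweep set is not from the current-step protocol")
  }
  steps <- vapply(sweep_set$sweeps, `[[`, numeric(1), "step_pA")
  if (anyDuplicated(steps) || is.unsorted(steps)) {
    stop("step currents must be strictly increasing without duplicates")
  }
  counts <- vapply(sweep_set$sweeps, function(sw) {
    count_spikes(sw$samples, sweep_set$fs, threshold_mV)
  }, integer(1))
  spk <- which(counts >= 1L)
  structure(list(step_currents_pA = steps,
                 spike_counts = counts,
                 rheobase_pA = if (length(spk)) steps[spk[1]] else NA_real_,
                 rheobase_defined = length(spk) > 0),
            class = "fi_curve")
}

#' Paired baseline vs bath-drug comparison for one cell
#'
#' Detects spontaneous events separately in the pre-drug baseline window
#' (start of the recording) and the drug-assessment window (the last part of
#' the recording) and emits a paired per-cell record for the stats module.
#' The windows must be non-overlapping and lie within the recording span.
#'
#' @param sweep_set A `sweep_set` with protocol `bath_da` (sweeps labeled
#'   `baseline` and `da`, each carrying `window_start_s`).
#' @param ... Detector parameters passed to [detect_events()].
#' @return data.frame with `cell_id`, `group`, `baseline_frequency_hz`,
#'   `baseline_amplitude_pA`, `da_frequency_hz`, `da_amplitude_pA`.
#' @export
bath_da_compare <- function(sweep_set, ...) {
  stopifnot(inherits(sweep_set, "sweep_set"))
  if (sweep_set$protocol != "bath_da") {
    stop("sweep set is not from the bath-application protocol")
  }
  labs <- vapply(sweep_set$sweeps, `[[`, character(1), "label")
  total <- sweep_set$meta$total_recording_s
  get_window <- function(lab) {
    sw <- sweep_set$sweeps[[match(lab, labs)]]
    if (is.null(sw)) stop("missing '", lab, "' window sweep")
    if (sw$window_start_s + sw$duration_s > total + 1e-9) {
      stop("window '", lab, "' extends past the recording span")
    }
    sw
  }
  b <- get_window("baseline")
  d <- get_window("da")
  if (b$window_start_s + b$duration_s > d$window_start_s) {
    stop("baseline and drug windows overlap")
  }
  pol <- if (b$holding_mV < -35) "inward" else "outward"
  bs <- event_stats(detect_events(b$samples, fs = sweep_set$fs,
                                  polarity = pol, ...), b$duration_s)
  ds <- event_stats(detect_events(d$samples, fs = sweep_set$fs,
                                  polarity = pol, ...), d$duration_s)
  data.frame(cell_id = sweep_set$cell_id, group = sweep_set$group,
             baseline_frequency_hz = bs$frequency_hz,
             baseline_amplitude_pA = bs$mean_amplitude_pA,
             da_frequency_hz = ds$frequency_hz,
             da_amplitude_pA = ds$mean_amplitude_pA)
}
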