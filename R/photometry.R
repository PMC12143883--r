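#' Photometry trace container
#'
#' @param samples Numeric fluorescence samples (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param t0_s Time of the first sample (seconds). Sample `i` covers time
#'   `t0_s + (i - 1) / fs`; all intervals are half-open `[start, end)`.
#' @return Object of class `photometry_trace`.
#' @export
photometry_trace <- function(samples, fs, t0_s = 0) {
  assert_scalar_pos(fs, "fs")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, t0_s = t0_s),
            class = "photometry_trace")
}

trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1L) / trace$fs
}

#' Fractional fluorescence change (dF/F) for one exposure epoch
#'
#' Computes `(F - F0) / F0`, where the baseline `F0` is the mean fluorescence
#' over the 10 s immediately preceding the stimulus introduction
#' (`[onset - 10, onset)`). `F0` is computed once per exposure epoch and
#' reused for every bout within it; if an animal receives two stimuli in
#' separate exposures, each epoch gets its own baseline.
#'
#' @param trace A [photometry_trace()].
#' @param epoch A one-row data.frame (or list) with `stimulus_onset_s` and
#'   `epoch_end_s`.
#' @param baseline_s Length of the pre-stimulus baseline window (seconds).
#' @return Object of class `dff_trace`: `values` (dimensionless dF/F over
#'   the epoch, from `onset - baseline_s` to `epoch_end_s`), `fs`, `t0_s`,
#'   `f0`, `stimulus_onset_s`.
#' @export
#' @examples
#' tr <- photometry_trace(rep(2, 400), fs = 10)
#' d <- compute_dff(tr, list(stimulus_onset_s = 15, epoch_end_s = 40))
#' all(d$values == 0)
compute_dff <- function(trace, epoch, baseline_s = 10) {
  stopifnot(inherits(trace, "photometry_trace"))
  onset <- epoch$stimulus_onset_s
  end_s <- epoch$epoch_end_s
  tt <- trace_times(trace)
  if (onset - baseline_s < trace$t0_s - 1e-9) {
    stop("baseline window truncated: need ", baseline_s,
         " s of trace before stimulus onset")
  }
  base_idx <- in_interval(tt, onset - baseline_s, onset)
  if (!any(base_idx)) stop("baseline window contains no samples")
  f0 <- mean(trace$samples[base_idx])
  if (!is.finite(f0) || f0 <= 0) {
    stop("invalid baseline: F0 must be positive (got ", format(f0), ")")
  }
  keep <- tt >= onset - baseline_s & tt < end_s
  structure(list(values = (trace$samples[keep] - f0) / f0,
                 fs = trace$fs,
                 t0_s = tt[which(keep)[1]],
                 f0 = f0,
                 stimulus_onset_s = onset),
            class = "dff_trace")
}

#' Refractory exclusion of closely spaced bouts
#'
#' A bout is excluded when its onset follows the offset of the previous
#' *included* bout of the same behavior family by less than `refractory_s`
#' (4 s by default), so responses contaminated by an immediately preceding
#' bout are dropped. The first bout is always included. Set
#' `from = "onset"` for the alternative onset-to-onset reading of "within
#' 4 s of a prior bout".
#'
#' @param bouts data.frame with `start_s`, `end_s` (and optionally
#'   `behavior`), sorted by `start_s`.
#' @param refractory_s Minimum gap (seconds).
#' @param from Reference point on the prior included bout: its `"offset"`
#'   (default) or `"onset"`.
#' @return The input with logical `included` and character
#'   `exclusion_reason` columns added.
#' @export
#' @examples
#' b <- data.frame(start_s = c(0, 5, 20), end_s = c(2, 7, 22))
#' apply_refractory_exclusion(b)$included  # TRUE FALSE TRUE
apply_refractory_exclusion <- function(bouts, refractory_s = 4,
                                       from = c("offset", "onset")) {
  from <- match.arg(from)
  if (nrow(bouts) == 0) {
    bouts$included <- logical(0)
    bouts$exclusion_reason <- character(0)
    return(bouts)
  }
  if (is.unsorted(bouts$start_s)) stop("bouts must be sorted by start_s")
  if (any(bouts$end_s <= bouts$start_s)) stop("bouts must have start < end")
  inc <- logical(nrow(bouts))
  reason <- character(nrow(bouts))
  last_ref <- -Inf
  for (i in seq_len(nrow(bouts))) {
    gap <- bouts$start_s[i] - last_ref
    if (gap >= refractory_s) {
      inc[i] <- TRUE
      last_ref <- if (from == "offset") bouts$end_s[i] else bouts$start_s[i]
    } else {
      reason[i] <- sprintf("within %g s of prior included bout (gap %.3g s)",
                           refractory_s, gap)
    }
  }
  bouts$included <- inc
  bouts$exclusion_reason <- reason
  bouts
}

#' Peri-event matrix of dF/F around bout onsets
#'
#' Samples the epoch's dF/F trace on a common relative-time grid
#' `[-pre_s, +post_s]` around each included bout onset (one row per bout).
#' Bouts whose window would run off either end of the trace are dropped
#' with a message. An empty bout list yields a 0-row matrix.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param bouts data.frame with `start_s` (only rows with
#'   `included == TRUE` are used if that column is present).
#' @param pre_s,post_s Window extent before/after bout onset (seconds).
#' @return Object of class `peri_event_matrix`: `values` (bouts x time),
#'   `rel_time_s` (length `round((pre_s + post_s) * fs) + 1`), `fs`,
#'   `bout_start_s`.
#' @export
extract_peri_event <- function(dff, bouts, pre_s = 10, post_s = 10) {
  stopifnot(inherits(dff, "dff_trace"))
  if (!is.null(bouts$included)) bouts <- bouts[bouts$included, , drop = FALSE]
  fs <- dff$fs
  rel <- seq(-round(pre_s * fs), round(post_s * fs)) / fs
  t_end <- dff$t0_s + (length(dff$values) - 1L) / fs
  keep <- bouts$start_s - pre_s >= dff$t0_s - 1e-9 &
    bouts$start_s + post_s <= t_end + 1e-9
  if (any(!keep)) {
    message(sum(!keep), " bout(s) dropped: peri-event window outside trace")
  }
  starts <- bouts$start_s[keep]
  mat <- matrix(numeric(0), nrow = 0, ncol = length(rel))
  if (length(starts)) {
    idx <- outer(starts, rel, function(s, r) round((s + r - dff$t0_s) * fs)) + 1L
    idx[idx < 1L] <- 1L
    idx[idx > length(dff$values)] <- length(dff$values)
    mat <- matrix(dff$values[idx], nrow = length(starts))
  }
  structure(list(values = mat, rel_time_s = rel, fs = fs,
                 bout_start_s = starts),
            class = "peri_event_matrix")
}

#' Windowed bout responses
#'
#' The response to each bout is the arithmetic mean dF/F over a fixed time
#' window following bout onset — 4 s by default, applied regardless of the
#' bout's own duration.
#'
#' @param peri A `peri_event_matrix` from [extract_peri_event()].
#' @param window_s Length-2 numeric, response window `[from, to)` in seconds
#'   relative to bout onset.
#' @return data.frame with `bout`, `start_s`, `mean_dff`, `included`,
#'   `exclusion_reason`.
#' @export
bout_response <- function(peri, window_s = c(0, 4)) {
  stopifnot(inherits(peri, "peri_event_matrix"))
  if (window_s[1] < min(peri$rel_time_s) - 1e-9 ||
      window_s[2] > max(peri$rel_time_s) + 1/peri$fs + 1e-9) {
    stop("response window outside the peri-event matrix span")
  }
  cols <- in_interval(peri$rel_time_s, window_s[1], window_s[2])
  n <- nrow(peri$values)
  data.frame(
    bout = seq_len(n),
    start_s = peri$bout_start_s,
    mean_dff = if (n) rowMeans(peri$values[, cols, drop = FALSE]) else numeric(0),
    included = rep(TRUE, n),
    exclusion_reason = rep("", n)
  )
}

#' Per-session summary of bout responses
#'
#' Aggregates included bout responses per stimulus: mean windowed dF/F and
#' the number of contributing bouts. A stimulus with no included bout is
#' flagged missing (NA mean) rather than silently zero.
#'
#' @param responses data.frame as from [bout_response()], with a `stimulus`
#'   column (recycled from the session if absent).
#' @param epochs data.frame of exposure epochs (`stimulus_label`, ...).
#' @param animal_id,condition Carried through for reporting.
#' @return data.frame with `animal_id`, `condition`, `stimulus`,
#'   `mean_dff`, `n_bouts_included`, `missing`.
#' @export
summarize_session <- function(responses, epochs, animal_id = NA,
                              condition = NA) {
  stims <- unique(epochs$stimulus_label)
  if (is.null(responses$stimulus)) {
    if (length(stims) != 1L) {
      stop("responses lack a stimulus column and epochs are not unique")
    }
    responses$stimulus <- if (nrow(responses)) stims else character(0)
  }
  out <- lapply(stims, function(s) {
    r <- responses[responses$stimulus == s & responses$included, , drop = FALSE]
    data.frame(animal_id = animal_id, condition = condition, stimulus = s,
               mean_dff = if (nrow(r)) mean(r$mean_dff) else NA_real_,
               n_bouts_included = nrow(r),
               missing = nrow(r) == 0)
  })
  do.call(rbind, out)
}

#' Run the full photometry pipeline on one session
#'
#' dF/F against the pre-stimulus baseline, refractory exclusion of closely
#' spaced bouts, peri-event extraction, windowed bout responses, and the
#' per-session summary.
#'
#' @param session A `photometry_session` (e.g. from
#'   [generate_photometry_session()]).
#' @param refractory_s Refractory gap for bout exclusion (seconds).
#' @param window_s Response window relative to bout onset (seconds).
#' @param pre_s,post_s Peri-event extent (seconds).
#' @return List with `dff`, `bouts` (with inclusion flags), `peri`,
#'   `responses`, `summary`.
#' @export
analyze_photometry_session <- function(session, refractory_s = 4,
                                       window_s = c(0, 4),
                                       pre_s = 10, post_s = 10) {
  stopifnot(inherits(session, "photometry_session"))
  epoch <- session$epochs[1, ]
  dff <- compute_dff(session$trace, epoch)
  bouts <- apply_refractory_exclusion(session$events, refractory_s)
  peri <- extract_peri_event(dff, bouts, pre_s, post_s)
  resp <- bout_response(peri, window_s)
  resp$stimulus <- rep(epoch$stimulus_label, nrow(resp))
  summ <- summarize_session(resp, session$epochs,
                            animal_id = session$animal_id,
                            condition = session$condition)
  list(dff = dff, bouts = bouts, peri = peri, responses = resp,
       summary = summ)
}
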