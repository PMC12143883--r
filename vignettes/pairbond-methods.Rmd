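---
title: "Models and methods behind the pairbond pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pairbond pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairbond)
```

`pairbond` re-implements, as reusable and tested code, the quantitative
analysis chain of a pair-bonding experiment in socially monogamous rodents:
fiber-photometry recordings of accumbal dopamine and D1/D2 medium spiny
neuron (MSN) activity during social interaction, whole-cell patch-clamp
characterization of MSN synaptic transmission and excitability, a
three-chamber partner-preference assay, and the statistics used to compare
groups. Because raw recordings from such studies are rarely deposited, the
package ships a synthetic-data generator with configurable ground truth, so
every stage can be validated end to end.

## Photometry: dF/F and bout-aligned responses

The fractional fluorescence change is the classic ratio

$$\Delta F/F = \frac{F - F_0}{F_0},$$

with the baseline $F_0$ taken as the mean fluorescence over the 10 s
immediately preceding the introduction of a stimulus animal. $F_0$ is
computed **once per exposure epoch** and reused for every behavioral bout in
that epoch; when an animal experiences several exposures, each gets its own
baseline. There is no detrending or photobleaching correction beyond $F_0$:
the quantification assumes a stable baseline, and the generator's
`drift_slope` parameter exists precisely to probe sensitivity to that
assumption. This is a known limitation for long sessions with substantial
bleaching.

The response to a behavioral bout is the arithmetic mean of dF/F over a
fixed 4-s window starting at bout onset, irrespective of how long the bout
lasted (short bouts still use the full window). Bouts beginning within 4 s
of the end of the previous **included** bout are excluded, so a response
cannot be contaminated by the tail of the preceding transient. Two readings
of "within 4 s of a prior bout" are defensible; the package defaults to
offset-of-previous-included-bout → onset-of-current, and exposes the
onset-to-onset alternative via `apply_refractory_exclusion(from =
"onset")`. Excluded bouts do not reset the refractory clock: "prior" means
the nearest retained bout.

Time is continuous in seconds; all intervals are half-open `[start, end)`;
sample `i` of a trace covers `t0 + (i - 1) / fs`.

## The synthetic photometry model

A session is
$$F(t) = B\,\Bigl(1 + \sum_i a_i\,k(t - t_i)\Bigr) + \beta t + \varepsilon(t),$$
where $B$ is the baseline level, $k$ a unit-peak double-exponential kernel
(rise 0.2 s, decay 1.5 s — the order of magnitude of fluorescent dopamine
sensor and calcium indicator kinetics), $a_i$ the per-bout peak amplitude,
$\beta$ an optional linear drift, and $\varepsilon$ Gaussian noise.
Transients are **multiplicative on the baseline**, so the dF/F estimate
recovers $a_i$ independent of optical gain — the natural companion of the
ratio definition above. Negative amplitudes model populations whose
activity decreases during social contact (the D2-type phenotype); the
generator floors fluorescence at 1% of baseline with a warning rather than
emitting negative photon counts.

Default conditions mirror the study design: 30-min sessions at 20 Hz with
at least 10 s of pre-stimulus recording (30 s by default), bout onsets as a
0.05-Hz Poisson process with 1–4-s durations, peak amplitudes of 4%, 2.5%
and 0.5% dF/F for partner, stranger and object with 1% between-bout sd, a
20% between-animal lognormal gain, and noise of 1% of baseline per sample.
The ground truth stores both the drawn peak amplitudes and the expected
4-s-window means (peak times the kernel's window mean), which is what the
pipeline actually estimates.

Each generated object draws from a private random stream derived by hashing
`(seed, object id)`, so adding sessions, cells, or subjects to an
experiment never perturbs the data of existing ones.

## Patch-clamp models

**Spontaneous PSCs** are Poisson trains of biexponential currents (rise
0.5 ms, decay 5 ms, ~20 ± 6 pA) on Gaussian current noise (2 pA), inward at
a holding potential of −70 mV and outward at 0 mV. Cells carry lognormal
rate and amplitude factors (sd 0.4 and 0.15) because real neurons differ
between cells far more than counting noise alone; group effects
(`study_effects()`) multiply rates/amplitudes on top.

**Detection** uses a sliding least-squares template fit (the classic
template-matching detector): at every position a biexponential template is
fitted with free scale and offset, and the detection criterion is the
fitted scale divided by the residual standard deviation. A detection
requires criterion ≥ 3.5 and fitted amplitude ≥ 5 pA; candidate onsets are
local maxima of the criterion, so events overlapping within one template
window are still resolved. A candidate is rejected if its peak does not
rise by at least the amplitude threshold above the local 2-ms pre-onset
baseline — this removes re-detections on the decay shoulder of a large
event. The template window spans the rise plus three decay constants: long
enough to pin the template, short enough that closely spaced events keep
separate fits. These defaults were set by a synthetic receiver-operating
sweep at 10:1 amplitude-to-noise, where the detector achieves ≥95%
precision and recall; the residual misses are genuinely overlapping events
a single-template detector cannot split.

**Evoked E/I ratios** follow the standard design: exactly 20 trials per
holding potential (−70 mV for EPSCs, 0 mV for IPSCs), per-trial baseline
(pre-stimulus mean) subtraction, peak amplitudes averaged within potential,
ratio = mean EPSC / mean IPSC, then every cell normalized by the
control-group mean so the control average is 1 by construction. Peak
amplitude (not charge) is used. A shortfall in trials is an error, not a
silent average.

**Excitability** uses a leaky integrate-and-fire (LIF) neuron
(R = 200 MΩ, τ = 20 ms, rest −80 mV, threshold −45 mV, reset −60 mV) driven
by 1000-ms current steps from 0 to 250 pA. LIF is the simplest model with a
monotone F–I curve and a well-defined closed-form interspike interval — it
is a test oracle, not a claim about MSN biophysics. Spike counting uses
upward crossings of 0 mV with a 2-ms refractory; a dV/dt criterion was
considered and rejected as unnecessary for simulated and typical MSN
spikes. Rheobase is the smallest step evoking ≥1 spike and is flagged
undefined (not zero) for silent cells.

**Bath drug comparisons** mirror the 40-min protocol: the first 10 min are
the pre-drug baseline, the drug (dopamine, 5 µM, recorded as metadata) is
washed in, and the last 10 min are assessed; minutes in between are
deliberately unused, exactly as in the protocol. Event statistics are
computed per window and emitted as a paired record. By default the drug
halves the PSC rate in naive cells (ratio 0.5) and leaves paired cells
unchanged — the direction of the study's phenotype.

Access-resistance screening (<30 MΩ) is metadata-level: a boolean per cell
honored by the pipeline, not recomputed from raw sweeps.

## Behavior

The partner-preference trial spans 3 h in a three-chamber arena. The module
consumes annotated occupancy and side-by-side bouts (it does not score
video) and computes

$$\text{preference ratio} = \frac{P - S}{P + S}$$

on side-occupancy times, bounded in $[-1, 1]$, flagged undefined when both
times are zero, antisymmetric under partner/stranger exchange and invariant
to rescaling both times. Both the ratio and the raw side-by-side durations
are emitted, since studies report both; "preference formed" is always a
statistical statement (partner vs stranger contrast), never a hard-coded
threshold. The generator draws symmetric side times (null ratio) unless an
arm-scoped effect shifts them; a side-by-side effect also extends the
corresponding side time, since huddling happens while on that side.

## Statistics

The stats module reproduces SPSS-style conventions because reported degrees
of freedom in this literature are only reproducible under them:

- **t tests**: two-tailed; unpaired uses pooled variance with
  df = n₁ + n₂ − 2 (reported dfs in the source studies rule out Welch).
  Zero-variance, zero-difference data give t = 0, p = 1.
- **Repeated-measures ANOVA**: classical within-subject F; the
  Greenhouse–Geisser epsilon is computed from the (pooled, in mixed
  designs) covariance of level scores and applied to both dfs **always**,
  even when ε = 1 — hence reports like "F (2.000, 12.00)". ε is capped into
  [1/(k−1), 1], and ε = 1 exactly when k = 2.
- **Mixed (split-plot) ANOVA**: between effect tested against
  subjects-within-groups; within and interaction against the within-cell
  error; unbalanced group sizes use the Type III (unweighted marginal
  means) convention for the within main effect.
- **Two-way between ANOVA**: Type III sums of squares with sum-to-zero
  contrasts (via `car::Anova`); empty cells are an error.
- **Post-hoc**: Šidák, $p_{adj} = 1 - (1-p)^m$. For Kruskal–Wallis the
  follow-up is Dunn's z on mean ranks with tie correction and Šidák
  adjustment — the original analyses do not name their nonparametric
  post-hoc, so this was chosen for consistency with the parametric one and
  is configurable.
- **Assumption checks**: one-sample Kolmogorov–Smirnov against a normal
  with the sample's own moments, and the Brown–Forsythe (median-centered)
  Levene test.

All implementations are validated against brute-force sums-of-squares
oracles (to 1e-10 on small designs) and against the independent
multivariate-model route in `car`.

### Calibration

Type-I error is checked by simulation at 2000 null replicates per test.
The GG-corrected tests are calibrated under a *non-spherical* null (shared
subject factor plus heterogeneous level variances) — the regime the
correction exists for. Under an exactly spherical null, always-on GG is
mildly conservative (rejection ≈ 0.035 at n = 8, k = 3) because the
estimated ε is biased below 1; this is a property of the convention, not a
bug. Kruskal–Wallis is calibrated at 15 per group, where the χ² reference
for H is accurate; at very small n the rank statistic is discrete and
conservative.

## Problem sizes used in the test suite

Validation simulations run at the study's design sizes where those matter
(n = 7 animals per photometry experiment, 11 cells per group for
spontaneous currents, 20 evoked trials per potential, 5–7 cells per group
for E/I) and at reduced durations where only event counts matter: 10-s
detector sweeps, 60-s bath windows in place of the full 10-min windows,
shorter spontaneous sweeps. Rates, noise levels, amplitudes, and effect
sizes are never scaled. Replicate counts follow the validation design: 2000
null replicates per calibration, 100 replicate experiments for parameter
recovery, 50 sweeps for detector precision/recall.

## What the generator does and does not emulate

It emulates: event-locked transient structure with configurable group
differences, Poisson behavioral and synaptic event timing, biexponential
kinetics, between-animal and between-cell heterogeneity, drift, and
polarity conventions. It does **not** emulate: motion artifacts or
hemodynamic contamination (no isosbestic channel exists in the model),
bleaching nonlinearity, series-resistance errors, electrode drift,
correlated (non-Poisson) event trains, or chemogenetic receptor kinetics.
Passing the synthetic validation therefore demonstrates that the analysis
chain is correct and well-calibrated on data obeying its stated
assumptions — not that those assumptions hold for any particular recording.

## Known limitations

- No reference-channel motion correction; sessions with artifacts must be
  cleaned upstream.
- The template detector underestimates frequency when events overlap
  heavily (rate × decay ≫ 0.1); its miss rate is quantified in the test
  suite at the default regime.
- The paper-style convention of reporting cell-level excitability curves
  with a two-way RM ANOVA over current steps treats step current as a
  within-cell factor with GG correction; published dfs in this literature
  sometimes instead reflect cells × steps treated as independent, which no
  proper mixed model reproduces.
- Preference ratios at n = 8 subjects per arm are intrinsically noisy
  (se ≈ 0.04 under the default generator); group contrasts on side-by-side
  seconds are better powered.
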