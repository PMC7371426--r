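---
title: "Quantifying persistent firing and eyeblink-conditioning behavior: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying persistent firing and eyeblink-conditioning behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(persistfire)
```

## The measurement problem

Under cholinergic stimulation (carbachol in the bath), cortical pyramidal
neurons can keep firing action potentials after a depolarizing stimulus has
ended — *persistent firing*. Experiments of this kind record 20 s episodic
current-clamp sweeps: the cell is held a fixed number of mV below its own
spontaneous firing threshold, a stimulus is delivered (a 2 s current step of
100/150/200 pA, or a 20 Hz train of 2 ms, 2 nA pulses lasting 2 s or
250 ms), and the post-stimulus voltage is examined. Each protocol is evoked
three times per cell. The companion behavioral assay is trace eyeblink
conditioning: a 250 ms tone (CS) and a 100 ms periorbital shock (US)
separated by a 500 ms stimulus-free trace interval, 30 pairings per session,
five sessions, with eyelid EMG as the response channel.

This package implements the full quantification chain for both assays, plus
a synthetic-cohort generator whose ground truth makes every stage testable.

## Persistent-firing metrics

**Incidence and probability.** A sweep is an incidence of persistent firing
iff at least one AP falls in the window `(offset, offset + 10 s]` — strictly
after the end of the current injection, inclusive at 10 s (the source rule
says "within 10 s after"; we read the boundary inclusively and the offset
itself exclusively, so stimulus-locked spikes never count). A cell's
probability is the proportion of its recorded sweeps (1–3) with incidence;
a group's probability is the mean of per-cell proportions, reported as a
percentage with SEM and 25/50/75 percentiles.

**Binned rate and zero-fill.** Firing rate is counted in half-open 1 s bins
`[offset + k, offset + k + 1)`. Empty bins are 0, and *all* bins of a
non-firing sweep of a partially firing cell are 0; cells at 0% probability
are excluded from rate analyses entirely (flagged, with a named error if a
caller tries anyway). With the catalog's stimulus onsets a 20 s sweep leaves
17.75 s (2 s stimuli) or 18 s (250 ms trains) of post-offset window; the
final partial bin carries value count/width so per-sweep means are
time-weighted. The per-cell mean rate is the mean over sweeps of the
per-sweep whole-window mean; the peak rate is the maximum of the
sweep-averaged bin curve.

**Onset latency** is the first post-offset spike time minus the offset,
averaged over firing sweeps only — zero-filling a latency is meaningless,
so non-firing sweeps simply contribute nothing (a documented choice; the
source text is silent).

**Exponential rise fit.** The group rate curve (mean over non-excluded
cells of their sweep-averaged curves) rises toward an asymptote and is fit
over the 0–9 s bins with

\[ Y(t) = Y_{max}\,(1 - e^{-t/\tau}) \]

against bin centers `t = k + 0.5`. Fitting uses bounded
Levenberg/port nonlinear least squares, initialized at the maximal observed
bin and `tau = 2 s`, with up to five jittered restarts and a coarse
grid-search fallback that returns `converged = FALSE` rather than throwing.
A constant curve is representable (`Ymax -> c`, `tau ->` its lower bound
0.05 s) and is flagged by the near-degenerate `tau`. The fitted curve is
nondecreasing for any positive parameters, which the tests assert.

*Caveat that matters in practice:* when onset latencies are long relative
to the fit window, the measured group curve is the latency-distribution
convolution of the underlying exponential, and a direct two-parameter fit
is biased toward larger `tau`/`Ymax`. Parameter-recovery claims in the test
suite therefore use small-latency cohorts; fits to realistic cohorts are
descriptive summaries of the measured curve, exactly as they are for real
recordings.

## Spike detection

The detector registers an AP where dV/dt (central differences on the raw
trace, optional boxcar) crosses 20 V/s upward and the voltage peaks at
least 20 mV above the crossing within 5 ms. Spike time is the peak (this
convention feeds bin assignment and latency consistently); threshold is the
voltage at the crossing; amplitude is peak − threshold; half-width is
measured at threshold + amplitude/2 with linear interpolation between
samples; dV/dt max is the steepest slope between crossing and peak. Spikes
whose peaks fall inside the stimulus window are tagged `evoked` and never
count toward persistence. Sampling below 2 kHz raises a named error — the
upstroke cannot be resolved. The dV/dt-crossing threshold convention is a
package decision (the source does not state its detector numerically) and
the 20 V/s default is configurable.

## Subthreshold metrics

**Postburst AHP.** After a 15-pulse, 50 Hz, 2 nA burst delivered at an
absolute holding of −69 mV, the medium AHP is the negative-going peak of
the membrane potential within 0.5 s of the burst offset minus holding, and
the slow AHP is the value exactly 1 s after the offset minus holding; both
are negative for hyperpolarizations, measured independently (no ordering is
assumed). The per-cell value averages the five sweeps — following the
stated sweep-averaging procedure we average the *traces* first and measure
once, which is also what suppresses noise in the pointwise sAHP read.

**Smoothing choice.** A 5 ms boxcar is applied before locating the
trough/peak. With 0.2 mV recording noise, the raw pointwise minimum over a
0.5 s window is biased low by roughly 3.5 noise SDs (~0.7 mV), an order of
magnitude larger than the group-mean SE the recovery tests check; the
boxcar removes that bias while distorting the broad (tens of ms) AHP trough
negligibly. Passing `smooth_ms = 0` restores the raw-extremum rule.

**ADP / plateau potential.** Under a 10-mV-below-threshold holding the same
250 ms train evokes a subthreshold afterdepolarization followed by a decaying
plateau. Peak amplitude is the post-offset maximum within 2 s minus holding
(holding estimated from the 100 ms pre-stimulus baseline when not given);
the area under the curve is the trapezoidal integral of voltage − holding
from the offset to a configurable window end (default: sweep end), in
mV·ms, allowed to be negative where the trace dips below holding. Detected
post-offset spikes raise a contamination error since the protocol precludes
firing. The published AUC magnitudes imply an integration convention that
cannot be reconstructed from the text alone, which is why the window is an
explicit argument rather than a constant.

**Relationships and paired designs.** `adp_firing_relationships()` reports
Pearson correlations of ADP peak with mean rate and onset latency, and a
threshold scan for the ADP amplitude best separating firing from non-firing
cells (the ~4 mV boundary phenomenon). `paired_condition_compare()` handles
pre/post condition designs (e.g. a calcium-channel blocker) with the
signed-rank statistic `W` (sum of signed ranks), exact by enumeration for
n ≤ 14 (valid under midrank ties), exact via the signed-rank distribution
for tie-free n ≤ 20, and normally approximated beyond.

## Behavior scoring

Baseline statistics come from the raw rectified EMG in the 250 ms before CS
onset. The trial is a conditioned response iff the 10 ms-boxcar-smoothed
EMG exceeds `baseline mean + 4 SD` anywhere in the 200 ms immediately
preceding US onset. Reading "occurring 200 ms before US onset" as a
*window* confines scoring to late, adaptive responses and excludes
startle/alpha deflections to the CS; this matches the source tables'
"% Late CRs" labels. The rule is scale-free (multiplying a trial by any
positive constant cannot change the outcome), US-alone trials are never
scored, session %CR divides by scoreable trials only, and the 60%
final-session criterion is inclusive ("reached") when splitting aged
animals into unimpaired/impaired. Baseline length, window length, SD
multiple and smoothing are all arguments.

## The synthetic world

The generator emits cohorts whose statistical structure matches what the
analyses assume, together with a truth table the analyses never read.

- **Spike law:** per sweep, with probability `p_fire`, an inhomogeneous
  Poisson process with rate `Ymax (1 − e^{−(t − t0)/τ})` from
  `t0 = offset + latency draw` (Gaussian, truncated at 0), thinned to a
  4 ms refractory period. Sweeps are independent Bernoulli draws — the
  source gives no within-cell sweep correlation, so none is modeled.
- **AP template:** a raised-cosine upstroke (0.7 ms) and downstroke
  (3.3 ms) of 82 mV, giving amplitude ~82 mV, half-width ~2 ms and dV/dt
  max ~184 V/s — inside the reported ranges for these neurons — with closed
  forms the detector tests check analytically.
- **Subthreshold envelopes:** the ADP rises instantaneously to the drawn
  peak at stimulus offset and decays exponentially (`pp_decay_tau`, default
  8 s); the AHP trace reaches its drawn mAHP minimum at +80 ms and relaxes
  so its value at exactly +1 s equals the drawn sAHP. No conductances are
  simulated — the source provides no biophysical model, and the analyses
  only see voltage.
- **Noise:** Gaussian, default 0.2 mV on voltage; EMG baseline is rectified
  white noise with CR bursts as half-sine envelopes (50 ms wide, amplitude
  in baseline-SD units, default 6) placed inside the scoring window, alpha
  deflections outside it, and UR bursts after the US.
- **Defaults:** 10 kHz sampling (the source does not state its rate; the
  native format carries it explicitly), 20 s sweeps, 3 sweeps per
  persistence protocol, 5 for the AHP burst. `default_group_specs()` encodes
  a six-group world at the magnitudes the study reports (ceiling incidence
  and fast rise for conditioned young; reduced incidence, slower rise,
  longer latency, larger AHP, smaller ADP with aging and impairment).

What a green test does and does not establish: the generator produces
stylized waveforms on known envelopes, so passing tests verify the
*measurement chain* (detection, windows, binning rules, averaging,
statistics) — not robustness to real-recording pathologies such as
electrode drift, seal degradation, spikelet/burst morphology, or movement
artifacts in EMG. Trial exclusion for unstable baselines is deliberately
not applied (common practice, but unstated in the source).

## Statistics

Probability-of-firing comparisons default to nonparametric tests
(Mann-Whitney, Kruskal-Wallis + Dunn), everything else to parametric
(t, ANOVA + Tukey/Sidak), matching the stated analysis policy; both routes
are explicit arguments. The Mann-Whitney p is exact by full enumeration of
group assignments when `min(n) ≤ 8` (and feasible), otherwise a
tie-corrected normal approximation with continuity correction. The
split-plot repeated-measures ANOVA uses the classical weighted
decomposition (one balanced within factor, optional between factor) and
reports Greenhouse-Geisser corrected p-values with ε estimated from the
pooled within-group covariance; under true sphericity the GG-corrected test
is conservative (ε̂ < 1 by sampling bias), so the null-calibration tests
target the uncorrected F reference, which is exact there. Percentiles use
the type-7 linear-interpolation convention. Two-sided tests throughout;
0.05 is reported, never used to gate computation.

## Numerical and design decisions, collected

- Units: seconds (0-based per sweep), mV, pA (2 nA pulses stored as
  2000 pA). One consistent system; the source mixes ms/s and pA/nA.
- Bin edges half-open `[k, k+1)`, anchored at stimulus offset; incidence
  window `(offset, offset + 10]`.
- QC inclusion: RMP in closed `[-80, -50]` mV, input resistance strictly
  > 25 MΩ, AP height ≥ 70 mV above holding — the stated wording read
  literally at the boundaries.
- Fit bounds `Ymax ∈ (0, 10·max]`, `τ ∈ [0.05, 50] s`; solver tolerance
  1e-6 on noiseless curves.
- Native format: one JSON per cell/animal plus one CSV per sweep/trial,
  series written at 9 significant digits — diffable, deterministic
  (identical seeds give byte-identical directories), and human-inspectable.
- ABF adapter: read-only, ABF v1 episodic only, named errors for ABF2 and
  gap-free layouts; the pipeline never requires ABF input.
- Scaled-down test execution: heavy cohort tests run at 2 kHz (the
  detector's documented minimum) and the RM-ANOVA/rank-test null
  calibrations use sample sizes where the asymptotic references hold;
  both choices are about CPU budget, not about the stated world.

## Known limitations

- No biophysical (conductance) model; the ADP/plateau is an envelope, so
  interactions between firing and the plateau are not emulated.
- The exponential-rise fit is a two-parameter description of a curve that
  real latency distributions convolve; fits to long-latency groups describe
  the measured curve, not the generative τ.
- Only one within-subject factor in the repeated-measures ANOVA; no
  mixed-effects machinery.
- The source-data spreadsheets of the original study are not bundled, so
  the package reproduces printed group values only through its synthetic
  world, not from the archived recordings.
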