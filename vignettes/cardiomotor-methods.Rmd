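---
title: "Cardiac-phase-resolved motor excitability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-phase-resolved motor excitability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `cardiomotor`, the
parameters that matter, the numerical conventions, and the reasoning
behind the design choices that were genuinely open. It states no
empirical result that the test suite does not itself compute.

## The problem

Cardiac activity modulates cortical processing. To ask whether motor
excitability depends on the phase of the cardiac cycle, one needs to
(i) assign every stimulation or movement event to a cardiac phase from
the concurrent ECG, (ii) quantify the evoked responses — motor-evoked
potentials (MEPs) in the EMG, TMS-evoked potentials (TEPs) and
heartbeat-evoked potentials (HEPs) in the EEG, event-related
desynchronization (ERD) of sensorimotor rhythms — under heavy TMS
artifacts, and (iii) test phase contrasts with statistics that respect
the multiple-comparison structure of channels x time (x frequency)
grids. `cardiomotor` implements this pipeline and a synthetic-session
generator with known injected effects so that every stage has a testable
ground truth.

## Cardiac phase windows

Systole is operationalized as the interval from the R-peak to the end of
the T-wave; diastole as the window of the *same length* ending at the
next R-peak. Equal lengths equate the prior probability of a uniformly
timed event falling in either phase, which the test suite checks
directly (binomial test on 10,000 uniform events). Beats where twice the
systole length exceeds the RR interval would have overlapping windows
and are flagged unusable; events outside both windows are classified
"neither" and retained with their distance-from-R metadata, because the
distance models and the binned excitability profile use all events, while
phase contrasts use only classified ones.

The T-wave end is found per beat by trapezoid-area maximization: with
the T-peak at `(x_m, y_m)` and a reference sample `x_r` placed beyond
the search window, the T-end is the sample `x_i` in `(x_m, x_r)`
maximizing `A(i) = 0.5 (y_m − y_i)(2 x_r − x_i − x_m)`. Constants not
fixed by the method's definition are exposed as arguments and default
to: T-peak search window 80–450 ms post-R (clipped 50 ms short of the
next R), reference offset 120 ms beyond the search bound, minimum
T-peak prominence 50 µV (below it the beat is unusable), ties resolved
to the earliest sample. R-peaks come from a derivative-plus-integration
detector (5–30 Hz band-pass, squared derivative, 150 ms moving window,
250 ms refractory period, automatic polarity) refined to the raw-signal
extremum; a quality check rejects traces without clear QRS complexes.
Before any of this, a −2 to 10 ms window around each stimulation is
removed from the ECG and filled by cubic spline interpolation anchored
on 20 ms flanks (overlapping windows merged, record edges extended with
the nearest value).

## Evoked responses

**MEP**: peak-to-peak amplitude in the 20–40 ms post-TMS window after
subtracting the −110 to −10 ms baseline mean. Real TMS trials are valid
above 50 µV; sham trials are valid at or below 50 µV — a successful sham
must not evoke motor activity. Amplitudes stay in µV; the natural log is
taken only inside the mixed-model stage.

**TEP**: the cleaning pipeline runs, in order: epoch (−1400 to 1000 ms)
→ baseline (−110 to −10 ms) → excise −2 to 8 ms pulse samples →
ICA round 1, removing the `n = 3` components with the largest variance
inside −150 to 150 ms (decay artifacts), keeping an unfiltered copy →
band-pass + notch → ICA round 2 on the filtered data with rule-based
artifact classification (ECG-correlated sources, frontal topography
concentration, high-frequency spectral dominance; a `manual_remove`
override is honored), weights applied to the unfiltered copy → cubic
interpolation over −2 to 15 ms, with those samples *flagged in an
exclusion mask that propagates through downsampling and is honored by
every statistic* → band-pass + notch again → mastoid re-referencing →
downsampling to 500 Hz. Each stage logs its parameters in a provenance
list; re-running the pipeline on its own output warns instead of
double-applying stages. Early TEPs are evaluated at 15–60 ms over the
hotspot cluster (C4, CP4, C6, CP6); sham runs the identical pipeline and
is subtracted per phase.

**HEP**: only trials stimulated at least 400 ms after the preceding
R-peak enter, keeping the HEP window clear of stimulation activity. The
TMS artifact inside the −100 to 400 ms R-locked window is estimated by
*mock events*: the R-to-TMS distances of the kept trials are permuted
(uniform random permutations, 10 repetitions, fixed logged seed) and
subtracted from the TMS latencies; epochs around all mock events are
averaged. Whatever is strictly TMS-locked survives this average, whatever
is R-locked is smeared out — the estimate converges at the usual
1/sqrt(N) rate on unstructured background, which the test suite checks
as an energy-reduction bound. Trials are sorted by MEP amplitude per
participant and split into 3 near-equal bins (remainder to the lower
bins, ties stable by trial index); the contrast uses bins 3 vs 1 only,
bin 2 is retained in outputs. Variant selections (previous-cycle HEPs
for early-TMS trials; rest-block R-peaks) reuse the same machinery.

## Time-frequency analysis

Complex Morlet wavelets on a 1 Hz grid from 5 to 40 Hz, cycle count
linear from 4 to 10: `n(f) = 4 + 6 (f − 5)/35`, so `n(10) = 4.857 ≈
4.9`. Wavelets are unit-energy with ±3.5 σ_t support; samples within
half a support of an epoch edge are flagged. Spectral resolution is
reported as the Gaussian FWHM `2 sqrt(2 ln 2) · f/n` (4.85 Hz at
10 Hz). For temporal width two conventions are reported — the amplitude
FWHM (0.182 s at 10 Hz) and the 2-sigma width of the *power* envelope
(`2 σ_t / sqrt 2` = 0.109 s) — because the two figures circulating for
"temporal resolution" differ by exactly this convention; the package
treats only the spectral figure as canonical. ERD is the relative power
change against the per-trial −900 to −100 ms baseline mean (the epoch
runs from −1000 ms, and this window stays clear of both the epoch edge
and the wavelet's smear around movement onset); as a ratio it is
invariant to static channel gain.

## Statistical engine

All of the following are implemented from first principles; base-R
equivalents (`wilcox.test`, `aov`, `mauchly.test`) appear in the test
suite only as independent oracles.

* **Cluster-based permutation t test.** Per-node paired t statistics are
  thresholded at the two-tailed critical value for alpha = 0.05
  (df = n − 1); suprathreshold nodes are clustered by a neighbourhood
  graph — spatial adjacency between channels (a distance-threshold graph
  on the 10–10 grid, user-overridable) combined with chain adjacency
  along time and frequency — separately per sign. Cluster mass is the
  sum of t values; the null is the distribution of the maximum absolute
  mass over within-participant sign flips of the condition difference.
  Monte-Carlo p values use the +1-corrected estimator
  `(1 + #{null ≥ obs}) / (1 + n_perm)`, which is valid by construction;
  exhaustive enumeration (`exact = TRUE`) reports the raw proportion
  over all 2^n flips. Significance is declared at p < 0.025 per tail
  (the two-tailed convention). The +1 correction differs from the raw
  proportion by at most 1/(n_perm + 1).
* **Wilcoxon signed rank.** Zeros dropped, ties mid-ranked, V = sum of
  positive-difference ranks; exact two-sided p by convolution of the
  rank distribution for n ≤ 25 without ties, otherwise a normal
  approximation with tie and continuity corrections.
* **Repeated-measures ANOVA.** Fully-within two-factor decomposition,
  each effect tested against its interaction with subjects; generalized
  eta-squared uses all subject-related error sums of squares in the
  denominator. Mauchly's test runs per within effect with more than one
  numerator df (orthonormal Helmert contrasts); when it rejects at 0.05
  the Greenhouse–Geisser epsilon multiplies both df. Two-level factors
  are never corrected. Degenerate all-equal tables return F = 0 with a
  `flat` flag.
* **Distance models.** `log(MEP) ~ 1 + (1 | participant)` vs
  `+ distance` vs `+ distance^2`, maximum likelihood, likelihood-ratio
  chi-square with 1 df per step; distance is rescaled to seconds
  internally (LRTs are unit-invariant) and singular fits are flagged but
  still reported. With one participant the models reduce to nested OLS.
* **Power analysis.** The two-sided one-sample noncentral-t power
  equation is solved for a continuous n and rounded to the nearest whole
  participant — the convention of the standard a-priori calculators this
  mirrors. At d = 0.48, alpha = 0.05, power 0.80 the continuous solution
  is 36.03 and the returned n is 36 (whose achieved power is 0.7996);
  the strict smallest-integer-with-power-≥-0.80 reading would give 37,
  and the package deliberately follows the calculator convention.
  Monotonicity in d and in the power target holds either way.

## The synthetic-session generator

`synth_config()` defaults describe the study conditions the package
targets: 5 kHz sampling, a 62-channel 10–10 montage plus mastoids, RR
intervals N(900, 50) ms truncated above twice the systole length,
systole length N(350, 20) ms, 416 real and 416 sham pulses at uniform
1.5–2.5 s inter-stimulus intervals, 30 pinch trials. Injected effects —
all knobs — default to: multiplicative systolic MEP gain 1.3 on the log
scale, log-linear decline 5e-4 per ms of distance from the R-peak,
trial-level log-noise SD 0.4, TEP amplitude 5 µV with systolic gain 1.3,
HEP amplitude 2 µV with 0.5 µV per SD coupling to the trial's MEP noise
draw, ERD depth 0.30 (systolic onsets multiplied by 1.3), IBI
deceleration +40 ms for the cycle containing a systolic pulse and −30 ms
for the next, exponential decay artifacts (200 µV, tau 30 ms) and 2 ms
pulse spikes on all channels for real and sham alike. The QRS is a
narrow biphasic deflection; the T-wave is a positive Gaussian whose
analytic end (center + 2.5 sigma) is the ground-truth T-end — an
unambiguous target for the trapezoid detector. Sham pulses share the
artifact model but evoke no MEP or TEP. A trial-statistics layer
(`gen_trial_stats()`) draws the same per-trial model without
synthesizing waveforms, which is what replicated calibration studies
use.

What the generator does **not** emulate: biophysically realistic ECG
morphology, respiratory or slow autonomic modulation, 1/f EEG background
and alpha reactivity outside the injected rhythm, volume-conduction
topographies beyond fixed channel sets, or electrode drift. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative model, not robustness to every property of real
recordings.

Two selection effects inside the generator deserve note because they
shape the parameter-recovery suite. Conditioning on a *diastolic*
classification selects on the beat's own RR (the event offset must fall
in the last L ms of the cycle), so raw phase-conditioned IBI contrasts
over-estimate the injected deceleration by a few ms; recovery is
therefore measured as the systole–diastole contrast on the stimulated
cycle minus the same contrast on matched null sessions, whose CI covers
the injected +40 ms. The −30 ms acceleration carry interacts with
stimulation of adjacent beats and is checked by direction.

## Numerical choices

* Filters are zero-phase (forward–backward) Butterworth throughout. The
  0.5–45 Hz band-pass is realized as a high-pass/low-pass cascade of the
  stated order because the single transfer-function band-pass is
  numerically unstable at 5 kHz with a 0.5 Hz edge; the notch is a
  band-stop over the stated 45–55 Hz stop band, applied after the band
  pass. Downsampling low-passes at 0.45x the new Nyquist (order 6,
  two-pass) before decimation; non-integer ratios use polyphase
  resampling.
* ICA is a symmetric fixed-point iteration with the tanh contrast on
  PCA-whitened data. On noise-dominated subspaces the non-Gaussianity
  landscape is rotationally flat and the iteration has no attractor, so
  after three re-initialisations the best iterate is returned with a
  warning (an `on_fail = "error"` mode preserves strict behavior). All
  seeds are explicit; component selection is deterministic given the
  seed.
* Decay-component ranking uses the variance each component contributes
  inside the decay window (mixing-column energy x windowed source
  variance).
* EDF I/O stores 16-bit integers with per-channel physical scaling; the
  delimited-text bundle (one TSV per channel role plus a JSON sidecar)
  is the lossless plain-text exchange format; events travel as TSV with
  a JSON metadata column.
* Montage coordinates are derived from the 10–10 label grammar (letter
  row, signed digit column) — sufficient for the adjacency graph, not a
  digitized head model.

## Problem sizes in the test suite

The suite exercises full waveform sessions at 250–1000 Hz with 8–10 EEG
channels and 24–120 pulses (the pipeline is rate- and montage-agnostic),
and statistical calibration at 200 replicate studies of 8–12
participants via the trial-statistics layer; parameter recovery runs at
the full study scale of 36 participants x 412 trials on that layer and
once per quantity on waveform data. These sizes are the package's
choices for a thorough default run; every one of them scales up through
the same configuration objects.

## Limitations

* Round-2 ICA component classification is heuristic; expert selection
  cannot be automated faithfully, so the rules are documented,
  overridable, and their component counts logged rather than targeted.
* The cluster test assumes exchangeability of paired differences under
  sign flips; it does not implement TFCE or between-subject designs.
* Source reconstruction, neuronavigation, and hardware control are out
  of scope.
* `run_study()` orchestrates the full analysis graph on synthetic
  sessions; shell-level entry points are intentionally not provided —
  the exported functions, the study orchestrator and
  `scripts/acceptance.R` are the interface.
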