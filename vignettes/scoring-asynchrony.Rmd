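---
title: "Scoring patient-ventilator asynchrony from pressure and flow waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring patient-ventilator asynchrony from pressure and flow waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvascore)
```

## The scoring problem

During non-invasive ventilation in pressure-support mode (PSV) the
ventilator holds the airway at EPAP, raises it to IPAP when it believes the
patient is inhaling, and cycles back to EPAP when inspiratory flow decays.
When machine cycles and patient efforts decouple, asynchrony events appear:

* **IE** (ineffective effort): the patient inhales but the ventilator does
  not respond;
* **AT** (auto-triggering): the machine pressurizes with no underlying
  effort, during the expiratory phase;
* **DT** (double-triggering): two pressure rises are delivered during a
  single inspiratory effort;
* **Bck** (backup cycle): a machine cycle delivered by the backup timer at
  the set backup frequency `f_bck`, without patient triggering.

`pvascore` labels every counted unit of a recording with one of
N / Bck / DT / AT / IE / X (X = discarded) using only the airway-pressure
and flow channels, and summarizes a recording by the asynchrony index

$$\mathrm{AI} = 100\,\frac{N_{DT}+N_{AT}+N_{IE}}{N_{tot}},$$

where $N_{tot}$ counts all units including backup and discarded cycles. A
merged DT pair counts as a single unit, and every IE appends one unit:
$N_{tot}$ is therefore the machine-cycle count minus DT pairs plus IE
units.

## The processing chain

**Ingest and resampling.** Recordings arrive as delimited text with a
`# rate_hz=` header. Analysis runs at 64 Hz, the native rate of the
ventilator data path this scorer mirrors. Resampling is band-limited:
channels are low-pass filtered with a zero-phase Butterworth filter at 90 %
of the target Nyquist frequency and then spline-interpolated onto the new
grid. A polyphase FIR resampler would do equally well; the
filter-plus-interpolation route was chosen because it reproduces a 1 Hz test
tone to better than $10^{-3}$ with the installed filtering stack, which a
short-kernel polyphase implementation did not. Belt channels are advisory
only (human reviewers use them; the classifier never does); `detrend_belt()`
removes drift below 0.05 Hz after subtracting the best-fit line, leaving
the 0.1–1 Hz breathing band within 10 % of its amplitude. All zero-phase
filtering uses odd-reflection padding so edge transients stay outside the
recording.

**Cycle segmentation.** A machine cycle onset is the last sample at the
EPAP baseline (EPAP + 1 cmH2O) before pressure climbs to at least
EPAP + 0.5 (IPAP − EPAP). Cycling-off is the first sample after the
within-cycle pressure peak below EPAP + 0.25 (IPAP − EPAP). Onsets closer
than a 300 ms refractory period are merged. Cycle *k* spans
$[t_k, t_{k+1})$, so cycles partition the recording.

**Leak and discard rule.** The per-cycle leak $\Phi$ is the time-average of
total flow over the cycle (trapezoidal integration on the 64 Hz grid):
because net patient volume over a complete breath is approximately zero,
mean total flow estimates the mask/circuit leak. A cycle is discarded
(label X, kept in $N_{tot}$, excluded from classification and from the
agreement statistics) when $\Phi$ exceeds the threshold $\Phi_t$ (default
18 L/min) **or** when its turbulence index — the RMS of the flow component
above 5 Hz relative to the breathing-band RMS — exceeds 0.4. There is no
standard quantitative definition of an "excessively turbulent" cycle; the
index used here is a heuristic, documented as such and exposed in
`detection_params()`. The discard rule is a logical OR of the two criteria,
with both values reported per cycle.

**Effort detection.** Patient efforts are read from the flow channel as
inspiratory-direction deviations above a locally estimated expiratory
baseline:

* *Unsupported efforts* (IE candidates) are bumps in the smoothed flow
  (2 Hz low-pass) relative to a lagged 0.5 s running median — the window
  ends 0.4 s before the current sample so the baseline cannot track the
  bump itself. A bump must exceed 3 L/min in height and prominence and
  decay again by 30 % of its prominence within 0.7 s ("return toward
  baseline"). Detection starts 0.9 s after cycling-off: the early
  expiratory flow recovery (time constant = resistance × compliance)
  otherwise mimics an inspiratory deflection. Flow-derived onsets lag the
  muscle-pressure onset by the mechanical response; a fixed 45 ms
  compensation recenters them (within ±1 analysis sample of ground truth
  on clean simulations).
* *Supported efforts* are established at each machine onset from the raw
  flow: the mean flow over the last 60 ms before the rise must exceed, by
  3 L/min, the linear extrapolation of the flow trend fitted within the
  current expiratory phase (never spanning the previous insufflation). The
  trend fit matters: a raw median goes stale during the exponential
  expiratory recovery, and zero-phase smoothing spreads the insufflation
  surge backwards over any pre-onset window, both of which masquerade as
  efforts. The extrapolation is conservative for a concave-rising recovery,
  and a guard rejects onsets where flow is still descending toward the
  expiratory trough (the signature of the second rise of a DT pair).

**Classification.** Per machine cycle, in priority order: X if discarded;
DT if the rise pairs with the previous effort-triggered rise (below); Bck
if effort-free and the onset sits within 150 ms of the previous onset +
60/f_bck; AT if effort-free during the previous cycle's expiratory phase;
N otherwise. Each unsupported effort outside X cycles adds an IE unit.

**DT versus AT + N.** Two rises within `dt_max_gap` with one candidate
effort are disambiguated by flow amplitude: the second insufflation of a
true DT starts from a still-inflated lung and draws almost no flow, while
an auto-trigger after a normal cycle starts from a partly deflated lung.
The second/first peak-flow ratio threshold is 0.4; simulated DT pairs sit
near 0, early auto-triggers at 0.55–0.8, so the threshold splits the two
populations with margin on both sides. (Direction of the amplitude
difference is established in the clinical literature; the numeric threshold
is this package's calibration and is config-exposed.) `dt_max_gap` is
1.5 s: with pressure-supported insufflations of 1–1.5 s plus a minimum
expiratory hold, a re-trigger within one effort lands 1.2–1.5 s after the
first rise, so a 1 s guard would reject true DT; the effort-span evidence,
not the gap, is the primary criterion. The first cycle of a DT pair is
mostly insufflation, so its mean flow exceeds $\Phi_t$ even with no leak;
DT candidacy is therefore evaluated before the leak discard and the leak
criterion re-applied to the merged pair, which again spans a complete
breath.

## The simulator

`simulate_psv()` generates PSV recordings with exact ground truth: a
single-compartment patient (resistance 10 cmH2O/(L/s), compliance
0.05 L/cmH2O by default; 0.03 for a restrictive profile) driven by
raised-cosine muscle-pressure pulses, and a ventilator controller with
exponential pressurization (rise time 0.15 s), flow-fraction cycling-off
(25 % of peak), a backup timer, and a trigger on the effort-driven flow
component exceeding 15 L/min. Integration runs at 1,000 Hz (the acquisition
rate of the polygraph chain this emulates) in compiled code, then passes
through the same resampling path as real data. Leak (constant + bursts),
10 Hz turbulence bursts, belt channels (volume split 60/40 across thorax
and abdomen plus slow drifts) and per-channel Gaussian measurement noise
are added downstream of the controller, so injected auto-triggers are
scheduled explicitly rather than arising stochastically — a deliberate
idealization that keeps the ground truth exact.

Event injection: IE adds a 2 cmH2O, 0.8 s effort (below the trigger
threshold, clearly above the 3 L/min detection floor); DT replaces a
breath's effort with a 15 cmH2O, 1.7 s effort that outlasts cycling-off and
re-triggers; AT schedules a spontaneous rise mid-expiration. The standard
scenarios (`scenario_with_events()`) place events in randomly chosen,
well-separated breaths (at least one untouched breath between any two event
slots) with a regular 15 breaths/min effort train under EPAP 4, IPAP 16,
f_bck 12 — a configuration inside the range of the nine published
recordings' settings. Default validation conditions follow the published
study design: 20-min recordings; the noisy IE-sensitivity condition uses
15 injected IEs, constant leak 5 L/min and flow noise SD 2 L/min across 20
seeds.

What the simulator does **not** emulate: nonlinear or two-compartment
mechanics, mask-model leak dynamics, cardiogenic oscillations, real trigger
artifacts (for example the pre-trigger pressure dip), or the statistical
structure of human breathing variability. Perfect recovery on clean
simulations therefore demonstrates internal consistency of the detection
chain under its own physics, not clinical performance; the noisy-scenario
sensitivities probe robustness, not field accuracy.

## Agreement statistics

Two scorings of one recording are aligned by greedy nearest-onset matching
within 0.5 s (equal to brute-force optimal matching on well-separated
units); unmatched units count as added/removed cycles against an implicit
non-event class. Per class, one-vs-rest sensitivity, specificity and PPV
are reported with the second scoring as reference; zero-denominator metrics
are explicit `NA`s, never silent 0s or 1s. Cohen's κ is computed over the
matched pairs on the full label set, excluding X units (discarded cycles do
not enter the statistical comparison). `inter_rater_rotation()` enumerates
every ordered (test, reference) pair and reports mean ± SD, the rotation
scheme used when several human scorers are compared. Cohort summaries use
the arithmetic mean and the n−1 standard deviation; `students_t()` defaults
to the paired variant for per-patient comparisons of two scorers (a
package choice — the flavour is configurable).

## Numerical choices and degenerate inputs

* Time is continuous in seconds; sample *i* (0-based) covers
  `[i/f, (i+1)/f)`.
* Flow is canonically L/min internally (`L/s` headers are converted at
  ingest); the leak threshold lives on the same scale.
* AI is kept at full precision and rounded to one decimal for display;
  an empty recording yields an explicit NA marker, not 0.
* Recordings shorter than two cycles are scored but flagged
  "insufficient data"; a breathing frequency above 24/min attaches a
  warning that AT tends to be over-detected in that regime (the
  classification itself is unchanged).
* Ties and refractory conflicts resolve to the earliest onset.
* All detection is deterministic; the only randomness in the package is
  the simulator's seeded noise.

## Known limitations

Efforts within the first ~1 s after cycling-off are not detectable from
flow alone (the expiratory recovery masks them); IEs there will be missed.
Minor asynchronies (advanced/delayed cycling) and upper-airway obstruction
are out of scope — obstructed backup cycles stay Bck. The DT/AT amplitude
discrimination degrades when breathing is fast and expiration short, which
is exactly the regime where auto-triggering over-detection is flagged. Belt
channels are never used by the classifier, so scorings carry only the
information in pressure and flow.

## Problem sizes used in validation

Unit tests run on 1–10 min scenarios; the validation suite scores one
clean 20-min recording with mixed events (expected: exact per-class
recovery) and twenty noisy 20-min recordings for IE sensitivity, and the
acceptance script repeats the noisy condition from a caller-supplied seed.
These sizes match the published study's 20-min windows while keeping a full
run in the minutes range on one CPU.
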