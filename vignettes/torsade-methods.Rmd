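---
title: "Models and methods behind torsade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind torsade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsade)
```

`torsade` implements an end-to-end analysis of drug-induced torsades de
pointes (TdP) proarrhythmia in the methoxamine-sensitized rabbit: an
alpha-1-agonist (methoxamine) sensitizes the anesthetized rabbit, an IKr
blocker (dofetilide) is infused on top in two doses, and the ECG is mined for
repolarization instability, autonomic balance, baseline irregularity, and
arrhythmic events. Because the underlying animal recordings are not publicly
deposited, the package ships a synthetic cohort generator that reproduces the
statistical structure every analysis stage assumes, with ground truth for
each of them. This vignette explains the models, the defaults, and the
choices made where the methods literature leaves the design open.

## The protocol and the synthetic cohort

`phase_protocol()` encodes the four piecewise-stationary phases: 10 min
drug-free baseline, 10 min methoxamine, then 20 + 20 min of low- and
high-dose dofetilide. The published phase descriptions carry no quantitative
model of the methoxamine reflex-bradycardia dynamics, so phases are treated
as stationary segments with their own RR/QT targets — transitions are
instantaneous. Only the high dose is tabulated in the source data; the
low-dose targets of the stock profiles are set midway between their
neighbours.

`group_profile()` holds per-phase RR and QT means and spreads. The stock
profiles (`profile_yc()`, `profile_ac()`, `profile_ch()`) use the published
group-level means and SDs (e.g. young-control baseline RR 381 ± 66 ms,
QT 220 ± 26 ms) as *beat-level* targets; `generate_cohort()` additionally
draws a per-animal offset of the RR and QTc means with SD equal to half the
phase SD, splitting the tabulated spread between within- and between-animal
variation. That split is a modelling choice — tabulated SDs are
across-animal — made so that single-series tests can use the printed SD as a
beat-level oracle while cohort summaries still center on the printed means.

QT–RR coupling is generated through the *inverse* of the rabbit QT
correction: each beat draws `QTc = QTc_target + jitter` and reconstructs
`QT = QTc + 0.175 * (RR - 300)`. Generated QTc is therefore stationary by
construction and `qtc_rabbit()` recovers it to machine precision — the
round-trip several tests rely on. The default beat-to-beat QTc jitter of
6.8 ms is chosen because i.i.d. Gaussian jitter of SD `s` yields an expected
short-term variability of `s * sqrt(2/pi)`, and 6.8 ms thus targets the
~5.4 ms baseline STV typical of this preparation.

Ectopy is injected as premature inserted intervals at 0.60–0.70 of the
phase-mean RR. The cleaning rule downstream flags deviations above 20% of
the segment mean; injecting at ≥ 25% (actually 30–40%) deviation decouples
generator correctness from detector sensitivity: a missed ectopic is then a
detector bug, never a borderline construction. Event counts are Poisson with
the configured per-minute rates; multiple-ectopic runs draw their length
uniformly from 2–4, matching the MEB definition; one bigeminy episode is
four couplets. TdP episodes are contiguous runs of at least five beats at
0.30–0.45 of the phase-mean RR, rendered as broad complexes with
sinusoidally modulated amplitude and alternating polarity. That is a
morphology *for detector testing*, not a physiological simulation of
re-entrant twisting.

All randomness flows from one integer master seed; per-animal sub-streams are
derived arithmetically from (seed, animal index) so cohorts are reproducible
animal-by-animal and every derived seed stays below 2^31.

### What the generator does not emulate

Real rabbit ECG has respiration and movement artifacts, electrode drift,
P/T-wave morphology changes under drug, AV block (one animal in the source
data — out of scope here), and non-stationary autonomic tone. Passing tests
on this generator therefore demonstrates that the *analysis chain* is
correct under its stated assumptions, not that it is robust to every
real-world recording; the fiducial-bypass mode exists precisely so
downstream stages can be validated independently of waveform-stage
imperfections.

## Beat detection and interval measurement

`detect_r_peaks()` implements the derivative-threshold detector: threshold at
a fraction (default 0.4) of the maximum absolute first difference, localize
the R extremum within a 40 ms search window, enforce a 120 ms refractory.
The published description names the algorithm but no parameters; the
defaults suit rabbit rates of 100–200 bpm. Two additions were necessary to
make the bare rule reliable at realistic noise: a 5 ms moving-average
pre-filter and an amplitude confirmation (detected extremum must reach 25%
of the global maximum deflection). Both are exposed in
`detection_config()`; disabling them reproduces the textbook rule.

`clean_rr()` reads the ectopic rule as: single pass, deviation of more than
20% from the *global mean of the analyzed segment* (not a running mean, not
iterated), linear interpolation between nearest retained neighbours, nearest
value at the boundaries. The simplest reading of an ambiguous sentence,
applied only on the HRV path — interval tables are built from raw RR.
One consequence is worth knowing: the rule is self-normalizing, so a segment
where *every* interval deviates from the mean (e.g. three intervals of
100, 1000, 100 ms) has no anchors and is rejected.

`measure_qt()` prefers ground-truth fiducials when the waveform carries them
(synthetic data), making downstream repolarization analysis exact. In
waveform mode, Q onset is a fixed 35 ms offset before R and T end comes from
the tangent method (steepest T downslope extrapolated to the isoelectric
baseline). The tangent method lands systematically early by roughly half a
T-wave width on this template — a known property of tangent definitions —
which is why the fiducial mode is the default for synthetic data and the
waveform mode is reported as approximate. Unmeasurable beats, including all
polymorphic TdP complexes, are returned as `NA`, never imputed.

Sample indices are 1-based with `time = (index - 1) / fs`, following R
convention; times are seconds, intervals milliseconds, voltages millivolts.

## Repolarization metrics

`qtc_rabbit()` is the rabbit-specific linear correction
`QTc = QT - 0.175 * (RR - 300)` (ms), vanishing at the 300 ms reference RR.
Applied to the printed group means it reproduces eight of the nine published
QTc cells exactly after half-up integer rounding; the ninth (young-control
baseline) computes 205.825 vs a printed 205 — under 1 ms, consistent with
group-averaging order (mean of per-animal QTc vs QTc of means).

`stv()` computes beat-to-beat short-term variability
`STV = sum(|D[n-1] - D[n]|) / (30 * sqrt(2))` over 30 consecutive
differences of the QTc series. "30 consecutive beats" is ambiguous against a
divisor of 30: the default takes 31 beats so the divisor equals the number
of summed differences; `mode = "strict30"` provides the literal 30-beat
(29-difference) reading with the divisor unchanged. Whether the published
value used one fixed window or a sliding mean is also unstated: the default
is the last complete window of the phase, `window = "sliding"` averages all
windows. Report tables round intervals half-up to integer ms, STV to one
decimal.

## Heart-rate variability

`lomb_scargle()` is the classical variance-normalized Lomb–Scargle
periodogram evaluated directly on the unevenly sampled RR tachogram — no
resampling, which is the point of the estimator for beat-interval series.
The tachogram abscissa is the time of each interval's end. The frequency
grid defaults to 0.02–0.5 Hz in 0.005 Hz steps (unstated in the methods
literature; the grid spans the bands with margin and resolves a 5-min
window). Alongside the dimensionless normalized power, a density in ms²/Hz
is attached, scaled so the integral over frequency recovers the series
variance for an evenly sampled record; both scales carry a normalization tag
so band powers are compared only within one convention. LF is 0.04–0.15 Hz,
HF 0.15–0.40 Hz; `band_power()` integrates the density by the trapezoid rule
over the half-open band, so LF + HF equals the total band integral exactly.
The HRV window is the last 5 minutes of baseline, half-open
`[end - 300 s, end)`, with cleaning applied before the spectrum.

## Entropy analysis

`aape()` is amplitude-aware permutation entropy: each embedded vector
contributes `(A/m) * sum |x_k| + ((1-A)/(m-1)) * sum |x_k - x_(k-1)|` to its
ordinal pattern's probability. Defaults m = 4, tau = 1, A = 0.5 (the standard
mixing coefficient of the method), natural log, ties broken by order of
occurrence. The parameters are exposed because the published low-risk
threshold of 1.975 is only meaningful for one parameterization. `repe()` is
the count-based (robust empirical) permutation entropy: invariant under
strictly monotone transforms, blind to the amplitude irregularity AAPE
detects — the pair is asserted against each other in the tests. Entropy runs
on waveform samples decimated to 250 Hz so that an m = 4 window spans
16 ms of signal rather than quantization noise; interval-level analysis is
available by passing a beat series.

`iein_sigma()` — the information-exergy index — is a *reconstruction*: the
original algorithm lives in engineering papers that are not publicly
recoverable, so the package commits to a concrete six-step pipeline
(windowed rePE trace; per-block Hankel trajectory matrix of the trace;
singular values; energy shares `s_i^2 / sum s_j^2`; block exergy = block
energy × Shannon information of the shares; sigma = SD of block exergy).
Its *contract* — stationary records score near zero, records whose
irregularity drifts in time score above the stationary 95th percentile — is
the tested surface, not bit-level identity with the original. Consequently
the published IEIN threshold of 670 lives on a different scale than this
sigma; it ships as a named constant for reproducing the classification rule
but is not numerically validated.

The discrimination claim is tested where it is testable: arrhythmia-prone
synthetic animals receive an 8% per-beat amplitude jitter plus a smooth
multiplicative amplitude wander of the same relative scale at baseline;
AAPE separates jittered from jitter-free records strictly in 50 paired
seeds, and a threshold calibrated on a training split (midpoint between the
classes) attains sensitivity 1 at specificity ≥ 0.9 on a held-out split.
The jitter level is a generator design constant, chosen as "subtle"
(below visual obviousness on the rendered trace) and fixed before the
stratification tests were evaluated at these problem sizes: 15 + 15 animals
per split, 30 s of baseline at 500 Hz per animal.

## Events and outcomes

`classify_runs()` partitions maximal runs of non-normal labels: one ectopic
is an SEB, 2–4 an MEB, ≥ 5 contiguous TdP labels a TdP episode; three or
more isolated ectopics each separated by exactly one normal beat merge into
one bigeminy episode (the ≥ 3 alternation threshold is unstated in the
definitions and chosen here). Runs of five or more plain ectopic labels
exceed the MEB definition and are reported as TdP. Inducibility is ≥ 3 TdP
episodes or any episode strictly longer than 10 s; termination is the first
moment an episode persists 20 s (non-strict), else the protocol end — the
strict/non-strict split follows the wording "more than 10 s" vs "after 20 s
of persistent". SEB/MEB presence flags for outcome tables are evaluated only
before the first TdP onset.

`classify_waveform()` is the waveform-level operationalization (the source
classification was manual): TdP requires ≥ 5 detected complexes with RR
below 0.6 of the record median and polarity alternation across the run
envelope. Broad, slow-rising TdP complexes never cross the 0.4 slope
threshold of plain R detection, so the classifier defaults to 0.15 with a
raised amplitude confirmation of 0.4 — T waves (0.32 of R amplitude on the
template) must stay below the confirmation level while the smallest TdP
complexes (~0.5) stay above.

## Risk statistics

`two_sample_proportion_test()` is the pooled z without continuity correction
(the named test, not a variant); the corrected version is a flag. Its square
equals the uncorrected chi-squared statistic of `prop.test`, which the tests
use as an independent cross-check. `grubbs_test()` uses the standard
t-based critical value, one outlier per pass. One numerical caveat found
while validating: for n = 4 the Grubbs statistic is bounded by 1.5, and a
gross outlier against a tight cluster sits so close to that bound that it
remains significant at *any* alpha — monotonicity in alpha is therefore
demonstrated on larger samples with moderate outliers. `friedewald_ldl()`
is `TC - HDL - TAG/2.2` (mmol/L, comma-decimal sources normalized to
points); negative estimates warn rather than clip, since they flag the
formula's validity limit. Quadrant classification is strict (`<`) on both
thresholds, matching the geometry of points clustered strictly inside the
low-risk quadrant, and `NA` entropy values exclude an animal from
stratification rather than defaulting to either side.

## Numerical conventions and limitations

* Rounding for presentation is half-up (`round_half_up()`), matching how
  the printed tables round; all exact fractions are retained alongside.
* The pipeline is deterministic given (configuration, seed); reruns are
  byte-identical, which the tests assert on the cohort manifest.
* Problem sizes in the test suite (100-seed detection sweep at 30 s per
  record, 120-animal propensity checks, 6000-sample IEIN calibrations) are
  the package's chosen trade-off between statistical resolution and a
  single-CPU run; all are parameters, not limits.
* Known limitations: no multi-lead support, no P-wave analytics beyond the
  fiducial mechanism, no AV-block detection, waveform-mode QT carries the
  tangent method's early bias, and the IEIN sigma scale is specific to this
  reconstruction.
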