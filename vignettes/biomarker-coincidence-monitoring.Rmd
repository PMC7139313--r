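---
title: "Detecting tolerance breakage from serum biomarker coincidences under checkpoint inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tolerance breakage from serum biomarker coincidences under checkpoint inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolbreak)
```

## The monitoring problem

Checkpoint inhibitor (CPI) therapy works by breaking immunologic tolerance:
the blocked PD-1/CTLA-4 pathways release an anticancer immune response, and
frequently also autoimmune tissue inflammation (immune-related adverse
events, irAEs). Both processes shed proteins into the serum. If the immune
response is phasic rather than continuous, the moment of tolerance breakage
should be visible in routine laboratory values as a *temporal coincidence*:
a rise of immune-activation markers (IL-6, CRP) together with a rise of a
tumor marker (S100B in melanoma; LDH) or of organ-damage markers (CK,
myoglobin, ALT). `tolbreak` implements that idea as a tested pipeline:

1. normalize each lab series to percent of its upper limit of normal
   (%ULN, 100 = ULN),
2. segment each series into rise episodes around local maxima and quantify
   them by baseline-subtracted AUC,
3. pair tumor/organ episodes with immune episodes inside a configurable
   coincidence window, classify the pairs (tolerance breakage vs irAE),
   flag the paradox first-cycle decline and autocrine-IL-6 mimicry, and
4. summarize per patient (first TMR day, first irAE day, same-cycle flag).

Because per-patient raw series of the motivating cohort are not deposited,
the package ships a synthetic-cohort simulator whose archetypes reproduce
the qualitative trajectory classes seen in monitored patients, with known
ground-truth event days. Every stage is therefore testable without patient
data.

## Kinetic model behind the simulator

### Tumor mass and marker release

Tumor mass follows exponential net growth punctuated by immune-mediated
kill events,

$$\frac{dM}{dt} = \bigl(g - k(t)\bigr)\,M,$$

where each kill event is a top-hat rate pulse of width one day and integral
$\kappa$ (so an isolated kill leaves the fraction $e^{-\kappa}$). Marker
release has two routes:

* **turnover release** $c\,\varphi\,M(t)$ — melanoma sheds S100B
  continuously through spontaneous cell loss; the cell loss fraction
  $\varphi$ defaults to 0.7, the upper estimate for melanoma;
* **kill release** — the marker content of killed cells,
  $c_k\,k(t)\,M(t)$, drains into serum through a first-order
  tissue-release compartment with time constant $\tau_{rel} = 4$ d.

The release compartment reflects that necrotic tumor debris liberates its
protein content over days, not instantaneously. It is also what makes a
one-day kill observable at weekly sampling: a 2 h-half-life marker driven
by an instantaneous burst would vanish from serum within a day, whereas
observed post-kill S100B elevations span one to two weeks.

### Serum clearance

Every marker obeys one-compartment first-order elimination,

$$\frac{dS}{dt} = \frac{R(t)}{V} - \lambda S, \qquad
  \lambda = \frac{\ln 2}{t_{1/2}},$$

with $t_{1/2} = 2$ h for S100B and $100$ h for LDH (the half-life contrast
that makes S100B the more informative melanoma marker: fast clearance gives
a wide dynamic range and sharp peaks, slow clearance compresses them).
Integration uses the exact per-step exponential update with the release
rate held at its step average, so a release-free series halves in exactly
one half-life and marker mass is conserved to well below 0.5 % (both are
asserted in the test suite). A `deSolve::lsoda` run serves as an
independent numerical oracle in the tests.

### Phasic immune activity

Each dose triggers a pulse of immune activity shaped as a difference of
exponentials (rise 1 d, decay 3 d — oscillations "of a few days"), with
two sub-peaks 4 d apart (the observed double peaks), amplitude growing
geometrically per cycle (booster factor $b = 1.2$, the
every-infusion-stronger IL-6 response), and all pulses from the first
corticosteroid day onward multiplied by a suppression factor
$s \in [0,1]$. Activity is phasic: it returns toward baseline between
doses instead of accumulating. IL-6 and CRP release are affine in
activity; their basal rates are chosen to hold 30 %ULN and 20 %ULN
baselines at steady state.

### Archetypes

`scenario_config()` encodes six patient archetypes: `responder`
(kills shrink the tumor; final S100B ends below baseline),
`non_responder` (no kills, slow growth $g = 0.005$/d), `paradox` (from the
first dose, turnover release and the autocrine IL-6 loop decay with
$\tau = 4$ d to a floor of 5 %; no phasic immune pulses — the steep
parallel S100B/IL-6 decline *is* the phenotype, and the archetype's IL-6
baseline is deliberately autocrine-dominated), `autocrine_progressor`
(growing tumor secreting IL-6, imitating an immune response),
`irae_coupled` (responder plus an organ-marker event scaled by concurrent
immune activity), and `flat_control` (pure measurement noise, the
detection null).

## What the generator emulates — and what it does not

Emulated: weekly sampling starting at a pre-dose day-0 draw; phasic
post-dose immune pulses with few-day oscillation; turnover- plus
kill-driven tumor-marker release; fast vs slow clearance; corticosteroid
suppression with persisting tumor-marker release; the paradox parallel
decline; multiplicative lognormal assay noise (CV 0.15); optional
detection-limit censoring (values below the limit stored at limit/2 with a
flag).

Not emulated: mechanistic immunology (T-cell clones, receptor occupancy),
inter-marker noise correlation, assay batch effects, dose delays driven by
toxicity, multi-organ metastases with mixed response (which can mask
coincidences by opposing release trends), and cfDNA dynamics. Passing
recovery tests on this generator therefore shows the detector is sound
*under the model's assumptions*, not that real-world sensitivity and
specificity meet the same numbers.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rel_rise_rho` | 0.5 | – | episode peak must be ≥ 1.5× baseline; formalizes "clear rise by eye" |
| `abs_rise_delta` | 20 | %ULN | blocks ratio-only artifacts near zero; binding at realistic baselines, which is what keeps CV-0.15 noise from generating episodes |
| `window_w_days` | 7 | d | partner peak may precede the immune peak by one sampling interval |
| `max_lag_days` | 14 | d | accommodates the observed 14-day S100B-after-IL-6 lag |
| `decline_fraction` | 0.3 | – | paradox depth at the first two post-dose draws |
| `sampling_interval_days` | 7 | d | weekly draws; the minimal schedule for few-day oscillations |
| `noise_cv` | 0.15 | – | typical immunoassay total CV |
| cell loss fraction $\varphi$ | 0.7 | – | melanoma upper estimate |
| S100B / LDH $t_{1/2}$ | 2 / 100 | h | the clearance contrast under study |
| S100B ULN (simulator) | 0.11 | µg/L | see note below |

All episode/coincidence thresholds are exposed through
`detection_params()`; all kinetic constants through `tumor_params()`,
`immune_pulse_params()` and `scenario_config()`.

**The S100B ULN note.** The packaged reference table stores the printed
laboratory ULN of 11 µg/L verbatim; the published serum range for melanoma
patients (below 0.11 µg/L to above 10 µg/L) indicates the decimal point
belongs two places left, so the simulator's panel
(`simulator_marker_panel()`) defaults to 0.11 µg/L. Every %ULN-based rule
is unaffected by the choice, and both values are configurable.

**Unstated amplitudes.** Immune pulse and kill release scales are not
published quantities; defaults were chosen once so that simulated %ULN
excursions resemble monitored courses (baselines of tens of %ULN, event
peaks of 100–300 %ULN): tumor-marker turnover baseline ≈ 20 %ULN, organ
basal ≈ 25 %ULN, kill release coefficient 12 with $\kappa = 1$ giving
event peaks ≈ +180 %ULN. Keeping baselines at realistic fractions of ULN
also keeps the absolute episode threshold the binding one, which is why
pure assay noise rarely produces calls.

## Numerical and procedural choices

* **Grid.** Dense trajectories use a 15-minute step (1/96 d), so the 2 h
  S100B half-life is resolved by 8 steps and exactly gridded; the
  exponential-integrator updates are exact for the gridded release, making
  the half-life and steady-state identities hold to float precision.
* **Episode definition.** A peak is a sample strictly greater than both
  neighbors; a plateau counts once at its earliest day; the baseline is
  the start of the maximal non-decreasing run into the peak (the series
  start if it rises from the first sample); the episode ends where values
  stop falling. Consecutive episodes may share a valley sample. The
  implementation is verified against an exhaustive triple-enumeration
  oracle on 1,000 randomized short series.
* **Threshold comparisons** use ≥, so a peak exactly at
  `baseline * (1 + rho)` qualifies.
* **Coincidence tie-breaks.** Each partner episode pairs with at most one
  immune episode: IL-6 preferred over CRP (CRP alone still calls, as in
  monitored patients whose response showed in CRP), then nearest peak,
  then the earlier immune peak.
* **Paradox rule.** "Declined by ≥ 30 % within cycle 1" is evaluated at
  each of the first two post-dose draws, which must both sit below 70 % of
  the day-0 value without rebounding between them. Requiring both draws
  (rather than any one) makes a chance double-dip under flat noise
  vanishingly rare while a genuine shutdown (value ratios ≈ 0.3 and 0.1
  at days 7 and 14) passes with wide margin.
* **Cycle calendar.** Cycles are half-open `[dose_k, dose_{k+1})`, the
  last closing one nominal interval after the final dose; actual dose days
  always take precedence over the nominal schedule when both exist.
  Multi-course patients are analyzed per course with days re-zeroed at
  each course start.
* **Censoring.** Below-detection values are stored at half the detection
  limit with a flag — simple, explicit and reversible; detection operates
  on the stored values.
* **irAE day bookkeeping.** When several irAE calls exist, the earliest
  day is reported.
* **Hormone-axis markers** (TSH, fT3/fT4, electrolytes, creatinine) are
  accepted in input but never drive organ-damage calls: endocrine irAE
  onset attribution is clinical, not marker-peak based.
* **LDH in the simulator.** The default archetype panel simulates IL-6,
  CRP and S100B (plus organ markers when events are configured). LDH is
  fully supported by the marker table and kinetics functions — the
  fast-vs-slow clearance contrast is exercised explicitly in the tests —
  but is not part of the default panel, mirroring its narrow dynamic range
  and limited informativeness in practice.

## Problem sizes in the shipped tests

The test suite exercises: oracle equivalence on 1,000 randomized series of
up to 12 samples; recovery and false-call rates on 100 responders and 100
non-responders (weekly draws, CV 0.15), with recovery required within ±7 d
of the injected kill day; a strict degradation check at 14-day sampling;
paradox flag rates on 100 paradox patients vs 100 flat controls; and
mass-balance closure below 0.5 % on every archetype. Cohort-scale
operating characteristics can be re-derived with
`analysis/04_operating_characteristics.R`.

## Known limitations

* Detection thresholds formalize a judgment that was originally visual;
  they are defaults to be tuned per laboratory, not validated cutoffs.
* The coincidence logic assumes one analyzed course at a time and
  unambiguous dose dates; overlapping courses are rejected by validation.
* Sampling noise is independent across draws and markers; correlated
  pre-analytic error (e.g. hemolysis elevating several markers at once)
  would inflate false coincidences relative to the simulator's estimate.
* With weekly draws the detector cannot localize events more precisely
  than one sampling interval, and sub-weekly oscillations alias; the
  degradation test makes the weekly-minimum argument quantitative but
  says nothing about daily sampling.
* The autocrine-suspect flag needs an outcome label (PD) and therefore
  arrives only retrospectively — exactly the mimicry caveat it encodes.
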