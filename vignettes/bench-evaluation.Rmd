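---
title: "Bench evaluation of reflection-based anaesthetic delivery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bench evaluation of reflection-based anaesthetic delivery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdbench)
```

## The measurement problem

Reflection devices make volatile anaesthetics usable with open-system ICU
ventilators: an activated-carbon reflector between the Y-piece and the
patient adsorbs exhaled agent and desorbs it during the next inspiration,
while a controller injects saturated vapour at early inspiration to hold a
target end-tidal concentration (EC), set as a fraction of the minimal
alveolar concentration (MAC). Evaluating such a device on the bench means
ventilating a test lung through the interface, recording the agent and CO2
concentrations at a sampling port at 10 Hz, logging the device's liquid
reservoir breath by breath, and then asking three questions of the
recordings:

1. *Accuracy and precision* — do the device's per-breath EC values agree
   with an external gas monitor's (Bland-Altman bias and limits of
   agreement)?
2. *Efficiency* — how much liquid agent is consumed per hour at each
   target, and what reflection efficiency does that imply?
3. *Ventilatory sensitivity* — does a very short inspiratory-flow time
   (high constant flow), as seen in spontaneously breathing patients,
   degrade efficiency?

`acdbench` implements this evaluation as a tested pipeline. Because bench
recordings are not deposited data, the package pairs the analysis with a
seeded simulator that reproduces the waveform structure and vapour
bookkeeping the analysis assumes, so every analysis step can be verified
against exact ground truth.

## Ventilation, protocol and timing arithmetic

Volume-controlled ventilation with constant inspiratory flow is assumed
throughout: tidal volume VT = 500 mL, respiratory rate RR = 10 /min,
I:E = 1:1, so each 6 s cycle is 3 s inspiration + 3 s expiration. The
inspiratory-flow time is VT / flow — 2.5 s at 12 L/min ("long"), 0.5 s at
60 L/min ("short") — and the rest of the inspiration is a pause. The target
staircase starts at 0.2 MAC, rises by 0.2 MAC every 10 min to 1.4 MAC,
holds the 1.5 MAC maximum for 20 min, and descends symmetrically; the
terminal 0.0 MAC step ends the recording and contributes no recorded
period. This yields 15 periods, 160 min, 1600 breaths and 96 000 samples
per channel — arithmetic the test suite checks exactly.

```{r}
phase_durations(vent_settings(inspiratory_flow = 12))
sched <- staircase_schedule()
c(periods = nrow(sched), minutes = schedule_duration(sched) / 60)
```

MAC references are fixed configuration constants (isoflurane 1.2 vol%,
sevoflurane 1.9 vol% at a reference age of 40), not computed from an age
model: the delivery device simply assumes them, and so do we. Vapour
factors F (mL vapour per mL liquid: isoflurane 200, sevoflurane 193)
convert reservoir drops to vapour volumes.

## The simulator

### Gas-exchange model

One breath is one bookkeeping step over four vapour stores (all in mL of
vapour): the lung, the reflector, a spill-over "cloud" in the interface,
and the liquid reservoir (mL liquid, scaled by F).

* The test lung is a single perfectly mixed compartment of fixed volume
  3000 mL (a 3 L breathing bag) whose walls take up no anaesthetic. There
  is no physiological uptake, no leak, and no humidity/temperature physics:
  those are exactly the factors a bench cannot show and a clinical reading
  of the results must add back.
* Inspiration: vapour injected within the inspiratory-flow time plus all
  vapour desorbed from the reflector enters the lung mix; the mixed
  concentration is the lung store over lung volume + VT.
* Expiration: one tidal volume leaves at the mixed concentration; the
  spill-over cloud (see below) is pushed against the reflector on top of
  it. Capture is `min(efficiency x exhaled, capacity)` with the cloud
  counting against capacity first; everything not captured is vented
  irreversibly and is the consumption.
* The reservoir falls by injected vapour / F; injections stop with an
  explicit `reservoir_exhausted` status if it empties.

The per-breath bookkeeping gives the invariants the tests enforce: injected
vapour equals the change of lung + reflector + cloud stores plus vented
vapour (to 1e-9 relative), and the reservoir decrement times F equals
cumulative injected vapour. It also yields a ground-truth reflection
efficiency — the fraction of exhaled vapour not vented — against which the
consumption-based analysis value is validated.

### Controller

The real device's injection algorithm is proprietary; the simulated
controller reproduces its observed phenomenology, not its internals. The
controller tracks a smoothed per-breath EC estimate (exponential moving
average, weight 0.3) — the smoothing models the device's measurement
averaging and produces the lag that makes injection *series* emerge. When
the estimate falls a hysteresis (default 0.10 vol%) below target, a series
starts: each breath it requests a gain-scaled fraction (default 0.8) of the
estimated concentration deficit over the lung + tidal gas volume, at least
one minimum pulse (0.5 s at 3 mL vapour/s), and the series ends when the
estimate reaches the target. With the default calibration, a 1.2 MAC
isoflurane target under long flow produces series of roughly 4-6
injections with overshoot in the tens of percent and measured per-peak
injection times of 0.4-3 s and areas of roughly 0.4-3.5 vol%·s — inside
the ranges observed on the bench. These defaults are calibration choices,
not claims about the device.

Injection is rate-limited (3 mL vapour/s): whatever the controller demands
beyond `rate x flow_time` cannot be carried into the lung by the
inspiratory flow. It is still injected — into the stagnant interface gas
during the pause — and forms the cloud that is pushed against the reflector
at the next expiration. Under long flow this is rare; under short flow
(0.5 s) it happens in essentially every injection breath, and at high
targets the cloud plus the exhaled vapour exceed reflector capacity, so
consumption rises disproportionately. This is the mechanism behind the
short-flow efficiency loss the analysis is designed to expose.

A `constant` controller mode injects a fixed volume every breath; started
at its equilibrium concentration it realises an exact steady state, which
the tests use to validate the analysis reflection efficiency to 0.1
percentage points.

### The trace at the sampling port

The sampling port sits between the interface and the test lung, so the
port does not see phase-aligned gas: expired gas retained in the interface
washes past the port for `interface_retention_time` (default 1.0 s) into
the next inspiration. The simulator therefore paints the expirogram
delayed by that time: CO2 ramps (0.4 s) to an end-tidal plateau drawn once
per experiment from 35-45 mmHg (normocapnia), stays there for the 3 s
expiration, and decays (0.3 s) to an inspiratory floor of 5 mmHg — the
reflector reflects a little CO2, so the trace never reaches zero. The
supra-threshold (> 34 mmHg) run is then about 30 samples long and extends
about 1 s into inspiration, which is exactly why the end-tidal window
below must stop early. The agent channel shows the expired plateau at the
lung concentration over the same delayed window, the reflected baseline
during inspiratory flow, the flow-injection peak (rate / inspiratory flow
above baseline) once retained gas has cleared, and the pause cloud as a
second, higher peak (cloud diluted over a 400 mL interface + HME + hose
volume, capped at a 30 vol% saturation ceiling). Gaussian noise (agent sd
0.01 vol%, CO2 sd 0.1 mmHg) is added and channels are quantised to the
monitor's resolution (0.01 vol%, 0.1 mmHg). The device log's EC noise
(sd 0.02 vol%) comes from an independent sub-stream so the trace is
unaffected by it. Identical seeds give bit-identical output.

What the simulator does *not* emulate — real expirogram slopes and
phase-3 morphology, cardiogenic oscillations, humidity and temperature
drift, irregular spontaneous breathing, device bus behaviour — bounds what
green tests mean: they validate the computation on traces with the assumed
structure, not the device itself.

## The trace evaluation

* **Expiration marking.** All CO2 samples strictly exceeding 34 mmHg are
  marked; maximal contiguous runs are breaths. Samples exactly at
  34 mmHg are sub-threshold ("exceeding" read strictly). Runs shorter
  than 0.5 s (5 samples) are debounced as noise — the marking is
  deliberately rough and the debounce makes it robust without changing
  any well-formed breath.
* **End-tidal extraction.** The EC of a breath is the mean of exactly 20
  agent samples starting 0.2 s (2 samples) after the run's first sample.
  On a ~30-sample run this skips the rising edge and stops before the
  retained-gas tail of the run, where inspiratory injection peaks would
  contaminate the average. Runs shorter than 22 samples are flagged
  incomplete: their EC is missing and excluded from means (with the
  delayed expirogram this affects only the final breath, whose window is
  cut off by the end of the recording).
* **Peak quantification.** Over each inter-run window (the inspiration of
  the following breath as seen at the port), the following breath's EC is
  subtracted from the agent samples; the count of positive excesses / 10
  is the injection time in s, their sum / 10 the area in vol%·s, and the
  window maximum is Cpeak. The final breath has no subsequent EC and is
  quantified against its own. A gate (at least 2 positive samples and
  at least 0.05 vol% peak excess) suppresses noise-only "peaks"; raw
  counts are still reported.

All windows are half-open sample-index intervals; time is
`sample_index x 0.1 s`, and the divide-by-ten conversions assume 10 Hz
explicitly (the sample period is carried in the trace object, not
hard-coded).

## Efficiency accounting

Per constant-target period, consumption is the reservoir drop between the
period boundaries (the level "at" a boundary being the last logged value
before it), extrapolated to mL/h. Ascending and descending occurrences of
each target are averaged — the staircase measures during wash-in and
wash-out, not at verified steady state, and averaging the two cancels the
first-order bias; the 20-min 1.5 MAC peak occurs once and passes through
unchanged, counted as a single period. Because steady state is assumed
rather than verified, each period also carries a drift diagnostic (the
absolute EC difference between the last and first fifth of its breaths).
Reflection efficiency then follows from the consumption identity

RE [%] = 100 (1 − 100 · IR · F / (60 · EC · VT · RR)),

with IR the hourly liquid rate. RE can be legitimately negative: with
reflector overload, more vapour is delivered than an open system would
need. Low targets (< 0.6 MAC by default) are flagged because 10-minute
consumption differences there are small relative to reservoir-log
granularity and scatter widely; the flag is applied to RE summaries and
plots, never to the raw tables. The vapour volume per exhaled breath,
EC/100 × VT, is the natural abscissa for comparing reflectors across
ventilation settings.

## Statistics

Device-vs-monitor agreement uses classical Bland-Altman statistics: bias
= mean difference, limits of agreement = bias ± 1.96 × sample SD of the
differences, with incomplete pairs dropped and no repeated-measures
correction (none is standard for this readout). Consumption is regressed
on mean EC with a per-experiment polynomial of degree 2 (degree exposed);
"increasing slopes" is the expected curvature, and the fit warns if the
curve dips negative in the observed range. Group contrasts use a pooled
linear model with the polynomial terms plus a group indicator, testing the
group main effect by an F-test; whether the underlying bench analysis
entered EC linearly or polynomially is not stated anywhere, so this choice
is documented here rather than claimed. When comparing agents, the three
highest sevoflurane targets can be excluded so the compared concentration
ranges match. Significance is read at p < 0.05 with no multiple-testing
correction, and printed p-values from any particular bench are not
reproduction targets — only the machinery and the qualitative orderings
are.

## Numerical and degenerate-input choices

* Breath cycle must be a whole number of 100 ms samples (asserted).
* Incomplete trailing breaths of a schedule are dropped.
* Negative pause times (flow time longer than inspiration) are rejected at
  construction.
* A refilling reservoir is a data error beyond a 1e-6 mL tolerance.
* RE at EC = 0 is undefined and raises an error naming the steady-state
  requirement; `vapour_rate = 0` is the explicit "injector disabled" flag.
* Report CSVs are written atomically (write-then-rename) with derived
  quantities at 4 decimals (agent 2, CO2 1), and re-reading them
  reproduces the tables.

## Problem sizes used by the tests

The unit tests run seconds-to-minutes-scale simulations (tens to hundreds
of breaths); the end-to-end checks run full 160-min experiments (1600
breaths, 96 000 samples), which simulate in a few seconds, and the
steady-state reflection-efficiency validation uses one-hour constant-target
runs with a 40-min evaluation window. The null-calibration check of the
group contrast uses 100 seeded replicates of two 8-point groups. These
sizes were chosen to exercise the full protocol while keeping the whole
suite comfortably fast on one CPU.

## Known limitations

The simulator is a phenomenological stand-in, not a device model: its
controller parameters were calibrated once to the observed injection-series
behaviour and then frozen. Consumption magnitudes depend on that
calibration, so analyses of simulated data support *relative* statements
(orderings, recoveries, agreement behaviour), not absolute consumption
claims about any physical device. The analysis half of the package, by
contrast, is exact arithmetic on whatever traces it is given and applies
unchanged to real recordings in the documented CSV dialects.
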