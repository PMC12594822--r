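---
title: "Modeling closed-loop iontophoretic wound treatment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling closed-loop iontophoretic wound treatment: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontotwin)
```

# The system being simulated

`iontotwin` is a desk-scale digital twin of a wireless, battery-powered
bioelectronic wound actuator. The physical device drives small ionic
currents (0--50 uA per channel, under a 4.7 V supply) from eight
reservoir electrodes arranged on a ring into a wound bed, returning
through a grounded center electrode. Two treatment modalities share the
hardware:

* **EF treatment** — odd channels source current through electrolyte-filled
  capillaries, imposing a radially inward electric field across the wound;
  no drug is delivered. Even channels are held high-impedance (Hi-Z).
* **Fluoxetine (Flx⁺) delivery** — even channels source current through
  cation-selective capillaries loaded with fluoxetine; the ionic current is
  directly proportional to the drug delivery rate. Odd channels and the
  center are grounded to lower the return resistance.

The twin reproduces the computational stack of this device — converter
quantization, two-point calibration, the closed-loop pulsed-current
controller, Faradaic dose accounting, telemetry logging with power-loss
resume, and the energy budget — against a synthetic electrical model of
the wound, so that every control and dosing behaviour can be exercised and
verified without hardware.

# Device model

## Quantized transfer functions

Actuation uses 8-bit current DACs with a 50 uA full scale; sensing uses
12-bit ADCs referenced to the 4.7 V supply, one pair of inputs across each
channel's 10 kOhm sense resistor. The ideal transfer functions are

$$V = \frac{A}{2^{N_{adc}}} V_{CC}, \qquad
  I = \frac{V_{applied} - V_{electrode}}{R_{sense}}, \qquad
  I_{DAC} = \frac{D}{2^{N_{dac}}} I_{max}.$$

Two numerical conventions are deliberate. First, the DAC denominator is
$2^{N}$, matching the ADC convention, rather than $2^{N}-1$; with 8 bits
both round to the printed 0.2 uA actuation step, and consistency between
the two converters is the tiebreaker. The choice is configurable
(`device_config(dac_denominator=)`). Second, ADC quantization is
floor-then-clamp — saturation at the rails is the contract, not an error —
which bounds the voltage round-trip error by one LSB (1.147 mV at the
default configuration, the printed 1.1 mV resolution).

Measurements are taken as bursts of sixteen samples 0.5 ms apart whose
arithmetic mean is stored *without re-quantization*: averages of integer
codes are naturally fractional, and applying the code-to-voltage relation
to the fractional average loses nothing. For i.i.d. noise the burst mean
shrinks the noise s.d. by a factor of four. Burst averages repeat every
100 ms, which is therefore the natural control tick.

The sense resistors carry a ±0.1% tolerance; the twin records it as
metadata and uses the nominal 10 kOhm for code-to-current conversion, as
the firmware itself must.

## Compliance limiting

A channel programmed to current $I$ against a series load $R$ needs
$I(R_{sense}+R) + V_{pol}$ volts of headroom. When that exceeds the 4.7 V
supply the source rails and delivers
$(V_{CC}-V_{pol})/(R_{sense}+R)$ instead. This single mechanism produces
the per-channel dose shortfalls the twin is asked to reproduce: a
high-resistance (faulty) channel simply cannot reach its target.

# Two-point calibration

Each channel of the real board is calibrated by sweeping 2--50 uA in 2 uA
steps through a known 46.13 kOhm resistor and comparing the device's own
burst-averaged reading (200 samples per step) against a precision
multimeter. The twin mirrors this: `sweep_transfer()` drives a simulated
channel with injectable gain/offset/saturation/noise imperfections, the
noiseless network solve plays the multimeter, and `fit_two_point()` fits
`true = gain * raw + offset` exactly through two reference points. The
reference points are the low (2 uA) end and the largest in-compliance set
point — the two ends of the usable range, which minimizes interpolation
error for an affine correction; the hardware documentation does not state
which points the production procedure uses, so this is the package's
choice. For any purely linear distortion the correction is exact at every
point up to quantization, which the test suite asserts as a property.

The DAC output leaves its linear range near 4.2 V, so a calibration
resistor must satisfy $R < 4.2\,\mathrm{V} / 50\,\mathrm{uA} = 84$ kOhm
for the sweep to stay linear (`max_calibration_load()`). The package makes
no attempt to reproduce the physical board's particular error magnitudes
(tens of mV, ~1 uA near full scale): those are properties of specific
parts, not of the algorithm.

# The synthetic wound load

No quantitative model of wound + contact resistance dynamics is published
for this device — only that both vary with fluid and movement. The twin
therefore ships an explicitly synthetic generator, and every magnitude
below is a documented stand-in rather than a measured value:

* **Baseline** 200 kOhm per channel. This puts the fluoxetine target range
  (2.45--5 uA, needing at most ~1.3 V of headroom) comfortably in
  compliance, while EF targets above roughly
  $4.7\,\mathrm{V}/210\,\mathrm{kOhm} \approx 22$ uA compliance-limit —
  qualitatively matching a device whose EF envelope struggles to follow
  high targets while drug delivery holds its setpoint.
* **Drift**: a log-scale random walk scaled to 200 Ohm/sqrt(s) at baseline,
  clipped to 0.2x--5x baseline. Over a ~5 h delivery run this gives
  resistance excursions of order ±30%, enough to exercise the feedback
  loop without routinely leaving compliance.
* **Movement artifacts**: Poisson events (default 6/h per channel) that
  multiply resistance by 2x and decay with a 30 s time constant.
* **Electrode polarization**: one RC pole per channel (50 kOhm, 100 uF;
  tau = 5 s) charging toward $I R_{pol}$ while current flows and relaxing
  toward zero when it stops. This is what gives the 60 s on / 5 s off
  pulse scheme its stated purpose: the 5 s off-phase lets electrodes
  discharge (~63% relaxation at these defaults).
* **Faults**: per-channel resistance multipliers (the `faulty_capillary`
  preset uses 50x on channel 6), which reproduce strictly ordered
  per-channel dose maps.

Grounded outer channels are modeled as carrying zero current: all return
current flows through the center electrode, whose current is minus the sum
of the outer currents at every step (charge conservation is asserted
per-tick in the tests). What the generator does **not** emulate: the
electrochemistry of ion exchange, hydrogel transport, spatial field
distribution in tissue, or any correlation structure between channels
beyond the shared pulse clock. Passing tests therefore demonstrate the
correctness of the *control and accounting stack* under plausible load
dynamics, not predictive accuracy for any real wound.

# Closed-loop control

The controller ticks at the 100 ms telemetry period. Each tick it gates
the pulse (on for the first 60 s of each 65 s period — a 92.3% duty
cycle), deadbeat-adjusts each sourcing channel's DAC code by the measured
current error expressed in DAC LSBs, solves the network, measures with
noisy quantized bursts, accumulates dose, and advances the load. Points
where the design was genuinely open:

* **Tick rate.** The physical feedback loop runs at sub-0.1 ms intervals;
  the twin ticks at the 100 ms telemetry rate because that is the fastest
  observable timescale in the logs it must reproduce. This is a documented
  fidelity limit: sub-tick transients are invisible.
* **Feedback law.** Only "rapid adjustment" is specified for the hardware.
  The twin uses `code += round(error / LSB)`, which is deadbeat on a
  resistive load: from a cold start it reaches the target code in one tick
  and then dithers at most one LSB. Convergence to within one DAC step
  within five ticks on a static load is a test.
* **Quantization granularity.** A 5 uA target maps to code 26 = 5.078 uA,
  so "delivered equals target" holds only to within one DAC LSB
  (0.195 uA); all invariants are asserted at that granularity.
* **Pulse phase** is global — all channels share one schedule clock, as
  synchronized telemetry envelopes suggest.
* **Policy updates** (target or mode changes from the actuation table or
  plan events) are applied at the next pulse-period boundary, never
  mid-pulse, avoiding partial-pulse ambiguity that the hardware sidesteps
  with a sub-second pause.
* **Dose stop** compares the even-channel dose total against the target
  every tick, *after* accumulation; channels ground from the next tick, so
  overshoot is bounded by one tick's charge at the delivered current.
  EF "strength" as a field quantity is never specified for the hardware;
  like the device, the twin controls current only.

Treatment-mode validation is strict at the schedule level (an actuation
table with an even-channel EF target, or a fluoxetine target outside
2.45--5 uA, is rejected row-by-row) and forgiving at the policy level
(out-of-range *requests* are clamped to the range boundary with a logged
warning), matching the split between a validated input artifact and a
live external controller.

# Dose accounting

Delivered dose follows Faraday's law scaled by the HPLC-calibrated
delivery efficiency:

$$Q_i(t) = \int_0^t I_i\,d\tau, \qquad
  D_i(t) = \frac{\eta\, Q_i^+(t)}{F} M, \qquad
  D = \sum_{i \in \{2,4,6,8\}} D_i$$

with $\eta = 0.022$ (s.d. 0.011 carried as metadata only — the mean is
always used in control decisions), $M = 309.33$ g/mol and
$F = 96485.3321$ C/mol. Only positive current moves drug out of the
reservoir, hence the rectified $Q_i^+$; odd channels and the center
accumulate charge but have dose identically zero. Integration is
left-rectangle on the 100 ms grid — the rule a firmware accumulator
implements — and is exact for piecewise-constant traces aligned to the
samples; a trapezoid option exists behind a flag. The ledger integrates
the *measured* (ADC-derived) currents, as the firmware does, so
measurement noise enters the dose estimate; rectification of zero-mean
noise on grounded channels contributes of order 0.02% of the target dose
over a day, which the twin accepts as faithful to a sampling firmware.

Whether $\eta$ is per-channel or global is unstated in the source
material; the twin treats it as global, since the calibration that
produced it reports a single value.

The inverse relation `charge_for_dose()` gives the 0.3544 C of rectified
charge behind the standard 0.025 mg per-wound target, and
`time_to_dose()` the full-compliance delivery time: 10.9 h at the minimum
4 x 2.45 uA fluoxetine target and 5.3 h at the 4 x 5 uA maximum, matching
the device's typical 6--12 h day.

# Telemetry, resume, and the FIFO contract

Session logs are CSV with `#`-prefixed metadata (format version,
JSON-encoded configuration and checkpoints) and one row per channel per
tick, eight consecutive rows sharing each timestamp. Floats are written
with 17 significant digits so the round trip is bit-exact, which in turn
makes offline dose reconstruction from a log *exactly* equal to the online
ledger — same rule, same samples, same accumulation order. A truncated
final row (power loss mid-write) yields the recoverable prefix plus a
truncation flag rather than an error.

Resume checkpoints (timestamp, elapsed duration, mode, targets, ledger
snapshot) are taken once per pulse period (65 s), bounding the loss from a
power failure to one period. A resumed run continues the pulse phase and
the ledger; the gap contributes zero charge, and a stitched interrupted
run matches an uninterrupted one to within one sample interval's charge
per interruption (a paired-run test).

The firmware's two cores exchange records through a ring buffer sized for
the worst-case WiFi latency of a few seconds:
`ceil(rate x latency)` slots with a 2x safety factor (100 slots at
10 records/s and 5 s). A seeded producer/consumer simulation in the test
suite confirms zero loss at that capacity and demonstrable loss below it.

# Experiments, power, and problem sizes

`run_experiment()` simulates a multi-day plan (the bundled
`plan_7day.yaml` mirrors the in vivo protocol: EF-only on Day 0, EF
switching to fluoxetine at the 6-hour mark of Day 1, fluoxetine
thereafter) on one persistent wound load, writing per-day session logs,
dose reports, spatial dose maps and a summary. The dose ledger resets at
each day's window start — the 0.025 mg target is a per-day target, which
is why a day's delivery can ground its channels early and resume fresh the
next morning. All randomness flows from one seed; identical seeds give
byte-identical output files.

The energy calculator represents the four operating modes by the upper
bounds of their published current ranges (10 / 50 / 150 / 170 mA) for
conservative budgets — a 23 h transmission day plus 1 h standby is
3960 mAh, which is why reaching the dose target in 5--11 h and sleeping
for the rest of the day matters on a once-a-day battery swap.

Problem sizes used by the shipped tests and the acceptance script: full
closed-loop dose-to-stop runs simulate ~5.3 h of device time (~191,000
control ticks) and complete in well under a minute; unit and property
tests use windows of seconds to minutes. The scaled time-to-dose
cross-check runs the minimum-target controller against 1/16 of the dose
target and multiplies back, a pure proportionality of the analytic
relation it checks.

# Known limitations

* All wound-load magnitudes are synthetic; only qualitative behaviours
  (compliance shortfall, dose non-uniformity, pulse-discharge) are
  meaningful, not absolute resistances.
* The sub-tick hardware feedback loop is not modeled; the twin cannot
  reproduce transients faster than 100 ms.
* The wound-stage healing algorithm that sets targets on the real system
  is out of scope; it appears only as the policy interface
  (`table_policy()`, `step_policy()`, or any user function).
* Biological endpoints (macrophage ratios, re-epithelialization) are not
  modeled at all — the twin ends at delivered dose.
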