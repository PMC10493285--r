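---
title: "Modeling a conductance-based integrate-and-fire array transceiver"
author: "ifatsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a conductance-based integrate-and-fire array transceiver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifatsim)
```

`ifatsim` is a desk-scale software emulator of an integrate-and-fire array
transceiver (IFAT): a large array of silicon neurons that exchanges spikes
as address events and realizes all synaptic connectivity *virtually*,
through an external routing table.  This vignette explains the model the
package implements, the parameters that matter, the numerical choices, and
what the test suite does and does not establish about real hardware.

## The neuron model

Each neuron has two compartments, *distal* and *proximal*, each a leaky
capacitor with two conductance synapses, coupled by a conductance
$G_{comp}$:

$$C_{mem1} \frac{dV_{mem1}}{dt} = \sum_{j=2,3} G_{syn,j}(E_{rev,j}-V_{mem1})
  + G_{leak1}(E_{leak1}-V_{mem1}) + G_{comp}(V_{mem0}-V_{mem1})$$

$$C_{mem0} \frac{dV_{mem0}}{dt} = \sum_{j=0,1} G_{syn,j}(E_{rev,j}-V_{mem0})
  + G_{leak0}(E_{leak0}-V_{mem0}) + G_{comp}(V_{mem1}-V_{mem0})$$

Each synaptic conductance is first order: it decays exponentially with time
constant $\tau_{syn}$ and jumps by a *conductance step* $\Delta G$ when an
address event arrives.  Spiking is abstracted as threshold-and-reset on the
proximal voltage: the nonlinear positive-feedback current of the physical
spike-generation (axon hillock) circuit is not modeled; when
$V_{mem1} \ge V_{thresh}$ outside the refractory lockout, a spike is
registered and $V_{mem1}$ is reset, leaving the distal compartment and all
conductances untouched.

The synaptic strength carried by an event is one byte: the four LSBs are a
pulse-width mantissa $W$ and the four MSBs a pulse-amplitude exponent $A$,
giving

$$\Delta G = g_0\,(1 + W/16)\,2^{A},$$

a geometric ladder spanning $\log_{10}(1.9375 \cdot 2^{15}) \approx 4.8$
decades, strictly increasing in the byte because the mantissa tops out at
$1.9375 < 2$.  The drive pulse itself (width times amplitude) is collapsed
into this instantaneous step; the within-pulse conductance ramp is not
simulated, since the step constant already integrates the pulse.  The
quantum $g_0$ folds all device prefactors and the base pulse width into a
single configurable constant.

### Default parameters

The source hardware publishes no absolute biases, so defaults are chosen
for biological plausibility and are all overridable through the
configuration file: $C_{mem} = 1$ pF, $G_{leak} = 50$ pS (membrane time
constant 20 ms), $E_{leak} = 0$ V, excitatory $E_{rev} = 1$ V, inhibitory
(shunting) $E_{rev} = 0$ V, $\tau_{syn} = 5$ ms, $G_{comp} = 1$ nS,
$V_{thresh} = 0.5$ V, $V_{reset} = 0$ V, $g_0 = 1$ pS.

One default deserves its own paragraph: the refractory period,
$t_{refr} = 100\ \mu s$.  With a pure threshold-and-reset abstraction and a
sustained suprathreshold conductance (a strong weight at a high input
rate), a zero-dead-time neuron refires at every numerical substep, i.e. its
output rate is an artifact of the step size.  Physical spike generation and
event registration have a dead time; modeling it with a 100 µs lockout
bounds the output at 10 kHz and produces the defining saturation behaviour:
at a 10 kHz input with a saturating weight, every input spike yields
exactly one output spike, so the input-output gain saturates at exactly
one.  An optional lower membrane rail (`V_floor`) models the supply rail of
a silicon membrane; it is off (`-Inf`) by default and used by the vision
demo configuration.

## Event-driven execution

`run_simulation()` processes events in time order from a priority queue.
Between events, conductances decay analytically and membranes advance by
*exponential Euler* substeps of at most `dt` (default 10 µs): per
compartment, the voltage relaxes toward its instantaneous equilibrium
$V_\infty = (\sum_j G_j E_j + G_{leak}E_{leak} + G_{comp}V_{other})
/ G_{tot}$ at rate $G_{tot}/C$, with conductances and the opposite
compartment's voltage frozen over the substep.  Because each update is a
convex combination of the previous voltage and $V_\infty$, voltages can
never leave the convex hull of the reversal potentials and initial values,
for any step size — the scheme is unconditionally stable.  Spikes are
detected at substep ends, so spike times are accurate to one `dt`; the test
suite checks the engine against an independent dense forward-Euler
integrator at `dt/16` (voltage error below 1%, spike times within one
`dt`).  Fired spikes are routed through the table and re-enqueued, with
ties broken deterministically (external events in stream order, then routed
batches in insertion order), so runs are bit-identical for fixed inputs and
seed.

Probe traces are sampled on a fixed grid (default 0.1 ms) rather than at
every internal step, to bound output size.  Rate measurements discard a
100 ms burn-in by default, so the conductance build-up transient (a few
$\tau_{syn}$) does not bias short measurements.

## Address events, routing, splitter and merger

An input event is a 24-bit word: core address in bits [23:21], an 11-bit
in-core neuron address in [20:10] (row = address div 32), a 2-bit synapse
type in [9:8] and the strength byte in [7:0].  The hardware documentation
fixes the field widths but not the order; the core bits are placed on top
so the three-stage splitter can peel one MSB per stage, which is also how
`split_events()` is implemented and tested.  Output spikes are 11-bit
in-core addresses that accumulate one MSB per merger stage, yielding a
14-bit word; at equal timestamps the lower port index wins at every stage,
so ties resolve to the lower core number.  Event conservation through
split and merge is property-tested.  A quadrant holds 8 cores of 2,048
neurons; four independent quadrants give the 65,536-neuron, 131,072-
compartment address space.  A global 16-bit id (`core*2048 + neuron`, plus
quadrant bits in file formats only) identifies neurons in routing tables.

## Pipeline timing

The two-tier service model has a serial front end (handshake latency
$T_{latency}$, default 50 ns — a free parameter, as hardware latencies are
unpublished) and one pulse circuit per row that holds each event for its
pulse width $\Delta t = \Delta t_{base}(1 + W/16)$ (default base 10 µs).
The front end is in-order and non-preemptive: the head-of-line event whose
target row is still busy blocks everything behind it, and its handshake
begins only once the row frees.  Under saturation this yields the
throughput law $1/(T_{latency} + \overline{T}_{wait})$: one busy row gives
$1/(T_{latency}+\Delta t)$ exactly, and interleaving $N$ rows hides the
waits until the front end saturates at $1/T_{latency}$.  Only these
relative/shape properties are asserted — absolute hardware throughput is a
chip measurement, not reproducible in software.  A brute-force state-
machine queue simulation serves as the oracle in the tests.

## Mismatch and calibration

Analog mismatch makes nominally identical neurons respond differently to
the same digital weight.  The package models it per neuron as (i) a
*digital-weight offset*, Normal($\mu_{off}$, $\sigma_{off}$) in code units
(defaults 0 and 8 — the source histogram is only described as "wide", so
the spread is a configurable choice), and (ii) a *response slope* in
decades of output rate per code unit, Normal(0.0185, 0.0068), the
published statistics.  Slopes are truncated at three standard deviations
*and* at a small positive floor: with these defaults the plain 3-sigma
interval dips marginally below zero, so truncation alone would not keep
slopes positive.  The truncation shifts the realized mean by under
$4\times10^{-5}$ and the realized spread by under $10^{-4}$, well inside
the recovery tolerances.

A synthesized weight sweep (`synth_response_curves()`) gives each neuron
the log-linear response $\log_{10}(\mathrm{rate}) =
\log_{10}(0.1\,f_{in}) + s\,(w - w_c - \mathrm{offset})$, capped at gain 1
and floored at gain $10^{-3}$, with Poisson counting noise over the
measurement window.  A constant $g_0$ re-scaling cannot change the
decades-per-code slope (it only shifts the curve), so the per-neuron slope
is realized as this code-axis scaling of the log-linear response around
the offset point; the nominal crossing $w_c = 60$ places the whole
population's linear regime inside the 0–255 code range.  The estimators
mirror the measurement definitions: the offset is the (fractional) code
where the gain crosses 0.1, by linear interpolation in (code,
$\log_{10}$ rate) — at 10 kHz input the criterion rate is 1,000 Hz — and
the slope is the least-squares slope of $\log_{10}$(rate) versus code over
the linear regime.  The linear-regime window is rates between 0.1 and 0.5
of the input rate, i.e. gains from the offset criterion up to half of
saturation; a window defined *above* ten times the criterion rate would be
empty at these operating points.  Calibration is single-point digital
offset compensation: corrections $\mathrm{round}(\overline{o} - o_i)$ are
stored outside the simulated chip and pre-distort routing-table strengths
(the correction is *subtracted* from the applied code: a too-sensitive
neuron, whose crossing sits below the mean, gets its drive reduced),
clamped to 0–255; calibration is idempotent up to the one-code rounding.
Because the offset interpolation for the shallowest-slope neurons is
counting-noise limited (the noise in codes scales as $1/s_i$), the
calibration protocol integrates longer per code (16 s in the end-to-end
recovery test) than the 1 s characterization sweep.

The headline statistical check re-estimates the slope statistics across a
2,048-neuron core with one second of 10 kHz Poisson counting per weight
code and recovers the generative mean and spread within central-limit
tolerances; with ~38 codes in each fit window and counts of
1,000–5,000 per point, the per-neuron estimation noise
($\sim 1.5\times10^{-4}$) is negligible against the population spread.

## The mean-rate ReLU mapping

On time scales of many spikes, a set of weighted input trains is
equivalent to one train at the *effective rate*
$f_{eff} = \sum_n f_n w_n / w_{nom}$, and the output is rectified-linear
in the net drive: $f_{out} = [G_{w_{nom}}(f_{ext,eff} - f_{inh,eff})]_+$,
with a single gain-scaling factor at the nominal weight ($w_{nom} = 80$).
The reduction to an effective rate is exact *in the model*; the fidelity
of the whole mapping is judged against the event engine, not against
notation.

Two reconciliations were needed.  First, the rate model treats weights
linearly while the PWAM code ladder is exponential; `encode_kernel()`
therefore produces *effective linear weights* (proportional to the
realized conductance step, normalized so code 80 carries weight 80)
together with the nearest realizable byte code, so both execution modes
see the same synapse and the quantization error is at most half a
mantissa step (~3%).  Second, a conductance-based neuron with shunting
inhibition and a threshold at half the excitatory reversal is *not* in
the regime the first-order mean-rate reduction assumes.  The demo neuron
configuration (`vision_neuron()`) programs the array into that regime:
reversal potentials at ±10 V (symmetric, far above the operating
voltages, so synapses act as near-ideal current sources and inhibition
subtracts instead of dividing), threshold 0.02 V, leak 5 pS, distal
compartment decoupled, a 1 µs dead time, the membrane floored at the 0 V
rail, and $g_0 = 0.4$ fS so that a 225-synapse patch projection (tens of
kilohertz of effective drive) stays in the linear range.  The gain is
fitted by `fit_neuron_gain()` at a high-exponent code so the calibration
sweep spans the projection's effective-drive range with modest event
counts.  Outside this regime — strong inhibition relative to excitation
with near-rest reversal — the engine shows the expected divisive
(shunting) deviation from the subtractive ReLU model; the surface
agreement test therefore checks the linear regime, and the shunting
behaviour is tested separately as a feature, not a defect.

## Vision demos

Stimuli are 15×15 anti-aliased bright bars (width 3 px) on dark
background, windowed to the patch's inscribed disc so the stimulus
energy is rotation-invariant (an unwindowed bar is longer along the
diagonal of a square patch); kernels are zero-mean (DC-subtracted) Gabor
patches (wavelength 10 px, envelope σ = 4 px, even phase by default —
the source publishes no kernel parameters, so these are package choices
with the documented symmetries: 0°/90° kernels are exact transposes,
45°/135° are symmetric, and all are 180°-periodic).  An even-symmetric
kernel is bar-selective and responds to a step edge a quarter wavelength
off the edge; boundary detection can therefore also be run with
odd-symmetric kernels (`phase = pi/2`), which localize their peak
response on the edge itself.  Pixel intensity maps to 6-bit rate codes
(0–63) worth 31.25 Hz each, so the brightest pixel drives ~2 kHz — the
input range of the mean-rate model; kernel intensity maps to signed
weights with the maximum magnitude at twice the nominal weight.  A patch
projection wires one Poisson train per active pixel to the proximal
excitatory or inhibitory synapse by weight sign.  Orientation tuning
sweeps bar angles 0–180° in 5° steps with repeated trials (the protocol
default is 30 trials of 1 s; the test suite uses 10 angles and a dozen
trials of 0.1 s with a 50 ms burn-in, sizes chosen to exercise the same
statistics at desk scale); boundary detection slides the window at stride
1 over the valid region, producing (W−14)×(H−14) maps normalized jointly
across kernels for writing.  The synthetic scene generator provides a
deterministic 113×75 test image (rectangle, diagonal band, disc) in place
of a photographic input.

## What the tests do and do not show

All inputs are synthetic and self-generated: Poisson/regular trains,
drawn mismatch, generated stimuli.  Passing tests therefore demonstrate
internal consistency — engine versus dense integrator, scheduler versus
queue oracle, estimator versus generator, event mode versus rate mode —
and reproduction of the *published statistics and qualitative patterns*
(slope distribution recovery, threshold-linear versus noise-smoothed
activation, shunting windows, tuning peaks, throughput shapes).  They do
not validate absolute hardware numbers (throughput in Mspikes/s, energy
per spike), transistor-level behaviour, temperature effects, or
per-synapse (rather than per-neuron) variability, none of which the
package models.

## Numerical choices, degenerate inputs, tie-breaks

* Exponential Euler with conductances frozen per substep; default
  `dt` = 10 µs; demo comparisons use 5–20 µs so that substep spike-time
  quantization (half a substep per inter-spike interval) stays below the
  measurement noise.
* Simultaneous events at one synapse add their conductance steps, applied
  in stream order; simultaneous merger inputs resolve to the lower port.
* A refractory lockout ending exactly on a substep boundary is honored
  (comparison slack $10^{-12}$ s) so periodic steady states are exact.
* Zero-rate trains are empty; an all-zero stimulus encodes to all-zero
  rates; an all-zero kernel is rejected; curves that never cross the gain
  criterion are flagged uncalibratable (`NA`) rather than extrapolated.
* Event files store integer microseconds; binary records are two
  little-endian 32-bit words per event.  Both dialects are bit-exact
  round-trips of each other.
* Timestamps, seeds: every stochastic routine takes an explicit seed and
  restores the caller's RNG state.

## Known limitations

The engine is a plain-R reference implementation: fine for the package's
desk-scale experiments (tens of thousands of events per second of
simulated time), not for million-neuron networks.  The pipeline model is
behavioural, not signal-level: four-phase dual-rail handshakes,
metastability and arbiter fairness are out of scope.  The ReLU mapping is
first-order: it ignores variance-driven corrections for Poisson input and
the divisive effect of shunting inhibition outside the demo regime.
Learning and plasticity are not modeled.
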