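---
title: "Methods: intrinsic-excitability analysis and the synthetic-trace model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic-excitability analysis and the synthetic-trace model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the measurement definitions, the synthetic-neuron
model, the numerical choices, and the design decisions that were genuinely
open. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` compute themselves.

## 1. Measurement definitions

All extractors operate on raw sweeps (voltage in mV, current in pA, time in
ms, sample 1 at t = 0; step windows half-open `[onset, offset)`).

- **RMP** — mean voltage over the 50 ms immediately preceding the step
  (configurable), averaged over sweeps with a clean zero-current baseline.
  A baseline containing a suprathreshold excursion is excluded; the mean
  (not the mode) is used as the simplest unbiased estimator under noise.
- **Input resistance** — steady-state deflection over injected current on
  the −100 pA sweep, steady state = mean over the final 20 % of the step.
  The estimator behind the published R<sub>in</sub> values of this
  recording style is not uniquely determined (single step vs ΔV–I fit), so
  both are implemented; the single −100 pA step is the default because it
  is the one amplitude such protocols always contain. For a linear cell the
  two agree exactly, which the tests verify.
- **Sag ratio** — (|peak| − |steady|)/|peak| of the hyperpolarizing
  deflection, both measured from baseline. Pure RC responses give 0.
  **Prominent H-current** means sag ratio strictly greater than 0.05: the
  rule is printed as ">5 %", so the boundary value 0.05 classifies as
  negative.
- **Spike detection** — upward crossing of 0 mV followed by a local
  maximum, refractory until the trace falls back below the criterion. The
  simulator's ground-truth spike times use the same criterion at
  integration resolution.
- **Threshold** — the voltage where dV/dt first reaches 20 V/s
  (≡ 20 mV/ms; the conversion is fixed internally and all slopes are
  reported in mV/ms). The search walks backward from the peak through the
  supra-criterion region; the crossing is linearly interpolated between the
  straddling samples (interpolation can be disabled). Whether the original
  MATLAB analyses interpolated is unknowable from the text; interpolation
  is the default because it makes the estimate sampling-rate-stable (the
  tests demand < 0.2 mV movement when the rate doubles).
- **Half-width** — time between the interpolated upward and downward
  crossings of threshold + amplitude/2. Undefined (NA) when repolarization
  never recrosses half-amplitude.
- **mAHP** — threshold voltage minus the trough over (peak, peak + 100 ms],
  truncated at the next spike's threshold time or the step offset,
  whichever is earlier, so inter-spike troughs belong to the preceding
  spike. The window is anchored at the spike peak (anchoring at the
  threshold recrossing is a configurable alternative); with a 100 ms window
  and ~1 ms spikes the difference is negligible.
- **Rheobase** — smallest ladder amplitude whose sweep spikes; the ladder
  increment is recorded alongside, since the estimate is
  resolution-limited. A lowest-sweep spike is flagged as a ladder floor.
- **7-AP train** — the sweep with exactly 7 spikes at the lowest such
  current; when none exists the nearest count **below** 7 is preferred
  (trains just under the target stay in the adapting regime that the ISI
  analysis assumes) and the result is flagged approximate.
  Accommodation ratio = (ISI₆ − ISI₁)/ISI₆; negative values (speeding
  trains) are legal.

### Rising-phase decomposition

dV/dt is estimated by central differences on the raw trace — the signal
is assumed hardware-filtered (10 kHz) before 50 kHz sampling, and no
smoothing is applied by default (optional Savitzky–Golay-style smoothing
was considered and left out: at 50 kHz the central-difference phase plots
are clean). d²V/dt² is central differences applied twice, and the tests pin
the production second derivative to exactly that brute-force definition.

The breakpoint between the AIS and SD components is the most negative
strict local minimum of d²V/dt² in the open window between the threshold
time and the time of the dV/dt maximum. A monophasic upstroke (no interior
local minimum) leaves the decomposition undefined rather than inventing a
breakpoint. With *b* = max dV/dt of the upstroke:

- **Convention "shoulder" (default)**: *a* = *b* − dV/dt(breakpoint), so
  *b* − *a* is the height of the AIS shoulder and *a* the rise of the SD
  component above it.
- **Convention "local_max"**: *a* = dV/dt at the first phase-plot local
  maximum after the breakpoint, when one exists.

The published figures mark *a* and *b* on phase plots without an equation,
and the operational definition in the antecedent literature is not
recoverable from text; both conventions are therefore implemented and every
result names the one used. The shoulder convention is the default because
it makes *a* and *b* − *a* an exact decomposition of the peak slope into SD
and AIS parts, which is how the two components are treated in the source
analyses.

## 2. The synthetic-trace model

The generator exists so that every extractor can be validated by parameter
recovery; it is a mechanistic stand-in, not a fitted model.

Two compartments, soma (C ≈ 150 pF) and axon initial segment (C ≈ 5 pF),
coupled by an axial conductance. All leak is somatic, so the passive input
resistance is exactly 1/g<sub>leak</sub> and the RC acceptance limits are
closed-form. Currents (units nS, mV, pA, ms):

| current | gating | defaults |
|---|---|---|
| leak (soma) | — | 7.7 nS → 130 MΩ, E = −66 mV |
| Na, AIS | m³h, m∞ midpoint −30 mV (somatic −22 + shift −8), k = 6, τ\_m = 0.05 ms; h midpoint −30 mV, k = 6, τ\_h = 1 ms | 300 nS |
| Na, soma | same form, midpoint −22 mV | 2200 nS |
| K delayed rectifier | n⁴, midpoint −25 mV, k = 7; τ\_n = 1 ms, scaled by 0.25 + 0.75·σ(V; −30, 8) so the channel deactivates fast below ~−40 mV (Kv3-like) | 1200 nS (AIS carries 15 %) |
| SK | conductance g·c/(c + 1); pool c += 0.12 per somatic spike, τ = 120 ms | 25 nS |
| HCN | first-order, activation 1 − σ(V; −82, 9), τ = 50 ms, E = −30 mV | 1.6 nS |

The AIS sodium midpoint sits 8 mV below the somatic one
(`na_halfact_shift`, constrained negative). The AIS therefore escapes
first; its axial current into the soma forms the initial (AIS) component of
the upstroke, and the high-threshold somatic sodium then produces the
steeper SD component — the d²V/dt² trough the phase module requires is
present across the default parameter grid (the acceptance grid finds a
breakpoint in 27/27 cells). The fast-deactivating delayed rectifier is the
one place the kinetics were shaped by a qualitative target: with a plain
fixed τ\_n the spike was either broad (> 1.5 ms) or followed by a deep fast
AHP that masked the SK-driven mAHP; fast closure below −40 mV yields a
~1 ms spike with a trough dominated by SK, which is the feature set the
extractors measure.

Choices a practitioner would recognise as the stated experimental world:
50 kHz sampling, depolarizing steps 50→1,500 pA in 50 pA increments plus a
single −100 pA step (500 ms steps, 100 ms baselines), junction potential
15.2 mV recorded but not corrected. Defaults tuned once to a
regular-spiking layer-5 profile (threshold ≈ −36 mV, amplitude ≈ 80 mV,
half-width ≈ 1 ms, mAHP ≈ 17–19 mV, rheobase 150–200 pA, a/b ≈ 0.84) and
then frozen.

**Integration** — exponential Euler for voltages and gates at the sampling
interval divided into substeps such that the internal step is ≤ 0.01 ms
(two substeps at 50 kHz). Exponential Euler is unconditionally stable for
the gate equations and for the voltage update with frozen conductances;
every sweep is checked for non-finite voltages and aborts naming the
offending parameter set. Cohort or analysis code never sees a silently
broken trace.

**Noise** — optional Ornstein–Uhlenbeck current noise (τ = 5 ms, sd scaled
by the leak so `noise_sd` is approximately the passive voltage sd in mV),
off by default so the analytic limits are exact and runs are bit-for-bit
reproducible from the seed. All randomness (noise, cohort jitter, per-cell
seeds) flows from R's RNG, so one `set.seed` reproduces a cohort.

**Cohorts** — per-cell parameters jitter the group template
multiplicatively (fraction `inter_cell_variability`, default 0.1) on
conductances/capacitances and additively on the leak reversal
(`variability × 10` mV sd). Negative conductances are clipped to zero with
a warning; capacitances are floored at 5 % of template. The shifted
template (see `cohort_templates()`) moves leak 7.7→6.06 nS, leak reversal
−66→−69 mV, SK 25→40 nS and the somatic share of total Na up
(2200/300→2600/240), with HCN trimmed 1.6→1.2 nS so the sag stays
group-matched — the direction profile of the two-hit phenotype with sag
explicitly unchanged.

### What a green test does and does not establish

The generator emulates: biphasic rising phases, SK-dependent mAHP and
accommodation, HCN sag, input-resistance/RMP shifts, and
cohort-level between-cell variability. It does not emulate: channel noise
beyond the OU term, dendritic morphology, temperature effects, electrode
artefacts (bridge imbalance, capacitance transients), or any quantitative
correspondence to published group values. A passing direction-check
therefore establishes that the *pipeline* recovers and tests the planted
parameter differences — not that the model reproduces biological effect
sizes. Two known qualitative mismatches of the stand-in: rheobase runs
150–200 pA (published scale ~110–130 pA) because the model lacks the
subthreshold amplification of real pyramidal cells; and ISI₁ *shortens* in
the shifted group (the published phenotype lengthens it) because the
7-AP-train current rises with SK strength and the higher drive compresses
early ISIs. Neither quantity is part of the graded direction profile.

## 3. Statistical layer

The published analysis states the routing rule but not the normality test;
Shapiro–Wilk at α = 0.05 per group with a both-must-pass rule is the
default (standard small-sample choice, configurable). Groups with n < 3 or
constant values cannot be screened and route to the rank test. The t-test
is the classical pooled-variance Student's test, two-tailed; Mann–Whitney
is exact for small untied samples and uses the normal approximation with
tie correction otherwise. Tests cross-check the rank test against
exhaustive enumeration of all rank assignments for group sizes up to
n₁ + n₂ = 12, and the t route against the closed-form t distribution. No
multiple-testing correction is applied (none is applied in the source
workflow); the report carries the comparison count implicitly as its row
count. Identical constant groups short-circuit to a flagged degenerate
result with p = 1.

## 4. Degenerate inputs and tie-breaks

- Threshold search: first qualifying sample walking back from the peak.
- n-spike sweep: exact count preferred, then nearest below, then nearest
  above; lowest current breaks ties.
- mAHP trough ties: `min()` takes the earliest.
- Missing features propagate as NA with reasons, never as zeros; per-
  parameter n varies accordingly in the comparison tables, and the
  prominent-H subgroup analysis is a pure row filter that cannot alter
  full-cohort numbers.
- Maze debouncing: consecutive identical arm entries are collapsed only
  when timestamps show them closer than 2 s (hardware re-triggers);
  untimestamped sequences count every entry, so `1,1,1` scores 2 errors.

## 5. File format

The sweep archive is a directory: `manifest.json` (units, sampling rate,
junction-potential metadata, step table) plus one CSV per sweep
(`time_ms, voltage_mV, current_pA`). Values are written as `%.17g` so
archives round-trip bit-identically, and the writer is deterministic.
Units declared in the manifest (V/mV/µV, A…pA) are normalized to mV/pA on
load. An HDF5 container was considered and rejected: no HDF5 bindings are
assumed, and a text format keeps archives diffable and portable. Vendor
formats (ABF, NWB) are adapter material behind the same reader contract
and are out of scope here.

## 6. Known limitations

- The model kinetics are stand-ins; parameter values carry no biological
  provenance beyond "plausible for a regular-spiking pyramidal cell".
- Rheobase and the 7-AP current are ladder-resolution-limited by
  construction, like the experiment itself.
- The measured input resistance of an HCN-bearing cell is below
  1/g<sub>leak</sub> (the h-conductance loads the hyperpolarized steady
  state); the ground truth reports the leak-derived value, extractors
  report the measured one — both are meaningful, and the RC acceptance
  test uses a passive cell where they coincide.
- Latency to spike at rheobase depends steeply on the distance to the
  ladder point above true rheobase and is therefore high-variance across
  jittered cells.
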