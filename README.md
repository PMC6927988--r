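# icephys

Intrinsic-excitability analysis for somatic current-clamp recordings from
cortical pyramidal neurons, with a conductance-based synthetic-trace
simulator for validation, behavioural-assay scoring, and a normality-routed
two-group statistical report.

## What it does

Whole-cell current-clamp studies of prefrontal layer-5 pyramidal cells
summarize each neuron by a standard panel of measurements. `icephys`
implements that panel as tested, reusable code:

- **Passive properties** — resting membrane potential (RMP, mean voltage
  with zero injected current), input resistance
  (R<sub>in</sub> = ΔV/ΔI on a −100 pA step), sag ratio
  ((|peak| − |steady state|)/|peak| during hyperpolarization), and the
  prominent-H-current rule (sag > 5 %).
- **Single-AP waveform** — spike threshold as the voltage where dV/dt first
  reaches 20 V/s, peak amplitude above threshold, half-width at half
  amplitude, maximum depolarization/repolarization slopes, and the medium
  afterhyperpolarization (mAHP = threshold − trough within 100 ms of the
  spike), all measured on the rheobase AP.
- **Spike trains** — rheobase, latency, the current evoking a 7-AP train,
  ISI₁/ISI₆ and the accommodation ratio (ISI₆ − ISI₁)/ISI₆, and the I–F
  curve.
- **Rising-phase decomposition** — the somatic AP upstroke has two kinetic
  components: an axon-initial-segment (AIS) potential followed by the
  somatodendritic (SD) potential. A trough of d²V/dt² in the rising phase
  marks the breakpoint; with *b* the peak upstroke slope and *a* the
  maximal SD-component slope, the **Slope_SD ratio a/b** indexes the
  perisomatic sodium contribution.
- **Behavioural scores** — prepulse inhibition
  (PPI = 100 − prepulse/startle-only × 100), radial-arm-maze working-memory
  errors (every re-entry into a visited arm), and open-field jump time
  (bins with Z-axis beam breaks and no X/Y breaks).
- **Group statistics** — per-group Shapiro–Wilk screening routes each
  comparison to a two-tailed unpaired Student's t-test (both groups normal)
  or a two-sided Mann–Whitney U test, reported as mean ± SEM with n and p;
  plus the immunoblot normalization arithmetic (lane/loading-control ratio
  divided by the control-mean ratio).
- **Synthetic traces** — a two-compartment (soma + AIS) Hodgkin–Huxley-style
  model neuron with low-threshold AIS sodium, high-threshold somatic sodium,
  delayed-rectifier K, an SK-like calcium-pool conductance (mAHP,
  accommodation) and an HCN-like current (sag). Every extractor is testable
  by parameter recovery against known ground truth.

Because each module is exposed as plain functions over plain containers
(`icp_sweep`, `icp_recording`, data frames), the package is usable both for
simulated cohorts and for real sweep sets imported through its documented
CSV archive format.

## Worked example

Simulate a two-group cohort (25 cells per group; the shifted template moves
leak, leak reversal, SK and the somatic-Nav share), extract every feature
and build the comparison table:

```r
library(icephys)

tm   <- cohort_templates()
prot <- protocol_spec(step_amplitudes = c(-100, seq(50, 800, 50)))
coh  <- simulate_cohort(tm$control, tm$shifted, n_per_group = 25,
                        inter_cell_variability = 0.1,
                        protocol = prot, seed = 1,
                        labels = c("control", "shifted"))
rep  <- run_pipeline(coh)
print(rep)
```

```
<icp_group_report>
  cells: 50 in groups control / shifted
  prominent-H fractions: control 48.0% (12/25), shifted 64.0% (16/25)
  significant parameters (p < 0.05): rmp, input_resistance, rheobase,
    threshold, mahp, n7_current, isi_1, accommodation_ratio, slope_sd_ratio
```

Selected rows of `rep$comparison` (means, routed test, p):

| parameter        | control | shifted | p        | test         |
|------------------|---------|---------|----------|--------------|
| rmp (mV)         | −64.8   | −67.8   | 4.9e−18  | t-test       |
| input_resistance (MΩ) | 108 | 131     | 1.5e−11  | mann-whitney |
| sag_ratio        | 0.050   | 0.055   | 0.12     | mann-whitney |
| mahp (mV)        | 16.7    | 23.9    | 2.2e−17  | t-test       |
| slope_sd_ratio   | 0.849   | 0.864   | 1.3e−4   | t-test       |

The shifted group shows the expected profile: hyperpolarized RMP, higher
input resistance, larger mAHP and a larger Slope_SD ratio, with the sag
ratio group-matched (not significant). `report_render(rep, "out")` writes
`features.csv`, `comparison.csv`, `subgroup_comparison.csv` (prominent-H
cells only), `prominent_h.csv` and `provenance.json`.

A command-line front end with verbs `simulate`, `extract`, `compare`,
`report`, `all` lives at `inst/scripts/icephys-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the given seed — simulates the
two-group cohort under the default protocol, extracts all features, runs
the routed comparisons — prints the group report, renders the CSV tables
next to the output path, and writes the JSON results file.

## Scope notes

The simulator is a mechanistic stand-in with implementer-chosen kinetics
(documented in the methods vignette); it is not fitted to any particular
data set, and no quantitative correspondence with published group values is
claimed. Vendor acquisition formats (ABF/NWB) are out of scope; recordings
enter through the CSV sweep-archive format described in
`?read_archive`.
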