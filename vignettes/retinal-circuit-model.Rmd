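---
title: "Modeling centrifugal preference and direction selectivity in the retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling centrifugal preference and direction selectivity in the retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retsim)
```

## The circuit and the question

Retinal direction selectivity arises in direction-selective ganglion cells
(DSGCs), which fire strongly for motion in a preferred direction (PD) and
weakly for the opposite (null) direction. The key interneuron is the
starburst amacrine cell (SAC): a radially symmetric, essentially passive
cell whose processes respond more strongly to motion *away* from the soma
(centrifugal, CF) than *towards* it (centripetal, CP), and which inhibits
DSGCs preferentially from the null side. `retsim` implements a compartmental
simulation of this circuit — passive cable neurons driven by structured
visual stimuli through stochastic ribbon synapses — together with the
selectivity metrics and a multi-objective genetic search over the synaptic
architecture that asks: *which spatial and kinetic arrangements of the
excitatory bipolar-cell input are sufficient to make a SAC prefer
centrifugal motion?*

## Model components

### Morphology and discretization

Cells are trees of tapered cylindrical sections, either read from standard
7-column SWC reconstructions (`read_swc()`, with an ad-hoc radius-correction
hook for mislabeled tracings, defaulting to divide-by-two semantics via
`apply_radius_correction()`) or generated synthetically. The synthetic SAC
(`generate_star_sac()`) is a planar, rotationally symmetric star: 6 primary
processes, each bifurcating twice, every tip at 210 µm path distance from
the soma, radii tapering 0.5 → 0.2 µm. These defaults emulate the overall
spatial scale of a reconstructed On-SAC — the same soma-to-tip extent over
which the kinetic rules below are defined — but a synthetic star has far
fewer branches, and therefore less membrane area, than a real arbor; absolute
quantities that scale with membrane area (input resistance ≈ 326 MΩ here,
clamp currents) land in a different range than a reconstructed cell would
give, while ratio-based indices (CSI, RTI, DSI) and the trends built from
them do not depend on that scale. A ganglion-cell stand-in
(`generate_star_dsgc()`: 8 primaries, 150 µm field) plays the DSGC.

`discretize()` cuts every section into compartments of at most 7 µm
(default), placing the electrical node at each compartment's distal end, so
a tip compartment reports the full 210 µm path distance. Membrane area is
conserved exactly (frusta are additive under the piecewise-linear radius
profile). The 7 µm default was chosen so that a full reconstruction would
discretize to on the order of a thousand compartments; halving it changes
the somatic input resistance of the star SAC by well under 1%, so results
are insensitive to the rule.

### Passive cable integration

Membranes are passive: cytoplasmic resistivity 75 Ω·cm, specific capacitance
1 µF/cm², leak conductance 6·10⁻⁵ S/cm², resting potential −60 mV (−52 mV
for the DSGC). The solver (`simulate_circuit()`) integrates the branched
cable equations by backward Euler at dt = 0.025 ms with an O(n) Hines
elimination over the tree; synaptic conductances are evaluated at the
start-of-step voltage, which keeps every step linear and the scheme
unconditionally stable (it remains well-behaved at dt = 0.1 ms, and refining
dt from 0.025 to 0.0125 ms moves response peaks by < 1%). Voltage clamps are
ideal (Dirichlet) constraints; the reported clamp current is the current
required to hold the level, positive into the cell. Units are mV/ms/nS/pA
internally.

### Visual stimuli

`ring_stimulus()` produces expanding/collapsing rings as a *continuous*
radial square-wave grating (450 µm/cycle, 50% duty) drifting at
`spatial_period × temporal_frequency` = 900 µm/s. Two properties motivate
this profile: every point in the field is modulated at exactly the 2 Hz
stimulus frequency, and at the ring center the illumination reduces to the
canonical phase alternation `(t − delay) mod (2·time_c) < time_c`
(`ring_phase()`; collapsing uses the complementary strict `>`, so the exact
boundary instant is dark for both). Crucially the light-onset front travels
outward for expanding and inward for collapsing rings — without a traveling
onset a "collapsing" stimulus would switch on everywhere simultaneously and
carry no centripetal motion signal. A single-disc variant
(`profile = "disc"`) is retained for comparison. Whether the rings should be
square-wave or smooth, and their duty cycle, is a modeling choice; the
square wave is the simplest profile consistent with the drift velocity and
per-point frequency above.

`bar_stimulus()` sweeps a 250 × 600 µm bar at 1000 µm/s across a 500 µm
corridor, reversing every `(perimeter + length)/velocity` = 750 ms so the
bar fully exits before returning. `flicker_noise_spec()` adds 30 bright
spots (25 µm radius) resampled at 15 Hz, combined with the bar by pointwise
maximum. `compile_stimulus()` precomputes per-position intensity series
(default sampling 1 ms — the fastest stimulus feature, the 15 Hz flicker,
is 66.7 ms — replayed bit-exactly by the solver at its own 0.025 ms step).

### The ribbon synapse and its genome

Each bipolar-cell input is a readily releasable pool of 70 vesicles.
Per time step, `Binomial(⌊pool⌋, p)` vesicles are released (each triggering
a 0.89/1.84 ms double-exponential conductance event, reversal 0 mV, peak
`synaptic_conductance`); the pool refills at `r` vesicles/ms, caps at 70,
and resets to 70 at each light→dark transition of its own driving
intensity. The distance rules, with `u = min(d, m)/m` and `m` the kinetic
transition endpoint:

* `p(d) = min(k_tsp + release_probability · u, 1) · V_intensity` — release
  probability *rises* with distance;
* `r(d) = refilling_rate` while `k_tsp > u`, else
  `refilling_rate · (k_tsp + 1 − u)` — refill *falls* with distance.

Proximal synapses are therefore sustained (low p, high r) and distal ones
transient (high p, low r), the spatiotemporal gradient hypothesized to
underlie CF preference; `kinetics_mode = "reversed"` substitutes
`d → 210 − d`, and `"fixed"` freezes both at their somatic values. `p` is a
per-step (0.025 ms) probability, which is what makes the printed bound
(0.01, 0.75) and the sustained–transient table range meaningful. Release is
binomial over the integer part of the pool; refill accumulates fractionally.
A deterministic mode (release = pool·p, expected-count synapse placement) is
provided for noise-free controls.

Synapse *placement* follows the density sigmoid
`max(1 − (scaling_factor·0.5·(1 + tanh(x − atp)) + offset), 0)` per µm
(proximal density `1 − offset`, distal limit `1 − (scaling_factor +
offset)`), drawn as a Poisson process along arc length. The tanh argument is
in raw micrometres, as the rule is defined; a width parameter is exposed for
sensitivity analysis. The eight numbers governing all of this —
distribution (3), kinetics (4) and conductance (1) — form the "genome"
(`genome_params()`) searched by the genetic algorithm.

The sustained–transient index (STI, `compute_sti()`) summarizes a synapse's
kinetics: simulate it for 250 ms under full illumination, average the PSTH
(10 ms bins) over 50 repetitions, and take steady-state (last bin) over peak
(first bin — the bin containing stimulation onset). 1 is fully sustained, 0
fully transient. `build_sti_table()` precomputes a 51 × 51 log-spaced grid
over p ∈ (1.56·10⁻⁴, 0.25) × r ∈ (5.12·10⁻⁵, 1.0) for interpolated lookup.

### GABAergic transmission

SAC release sites sit in the distal third of the arbor. Wherever two cells'
processes pass within 5 µm in the plane (`find_intersections()`, collapsing
multiple hits on the same branch pair to the closest one so contact counts
do not inflate with finer discretization), a GABA synapse may form:
SAC→SAC with τ = 3/30 ms and reversal −75 mV; SAC→DSGC with the same
kinetics, reversal −60 mV and 0.5 nS (≈ the ~9 nS pairwise total divided by
~14 contacts). A synapse fires a 200 Hz event train while its presynaptic
compartment is above −50 mV, the phase restarting at each crossing
(`gaba_event_times()`). The 5 µm SAC–SAC threshold reuses the stated
SAC–DSGC value; whether the 200 Hz trains are crossing-locked or
free-running is a choice — crossing-locked is implemented.

SAC→DSGC contacts are accepted with probability `arccos(u·PD)/π`, where `u`
is the direction of the SAC process at the contact relative to its soma: 0
for parallel to the DSGC's preferred direction, 1 for antiparallel —
null-side wiring. The literal inverse-cosine form is the default;
`(1 − cos θ)/2` is available, both monotone in the angle. `mode = "random"`
accepts every contact with probability 0.5 as the control.

### Metrics

From somatic traces (first stimulus cycle always discarded, remaining
cycles averaged): amplitude = peak − baseline, with the baseline the
resting potential (the stimulus starts at t = 0, so there is no pre-stimulus
window to average); rise time = first 20%-of-peak sample to the peak
sample (ties to the earliest). Then

* CSI = (R_exp − R_col)/(R_exp + R_col),
* RTI = (rt_col − rt_exp)/(rt_col + rt_exp),
* DSI = (R_PD − R_ND)/(R_PD + R_ND) on areas above −60 mV,
* PD activation = area above the spiking threshold (min + 11 mV for
  simulated DSGCs; −49 mV with a −52 mV baseline in the calibration data).

## Assays

* `run_single_sac_assay()` — one SAC, 315 × 315 µm field centered on the
  soma, expanding and collapsing runs with identical release RNG streams,
  1500 ms (three 2 Hz cycles).
* `run_network_assay()` — 13 clones on the two overlaid grids (3×3 from
  (0,0) and 2×2 from (62,67), 125 µm spacing), rings centered on the
  central cell, CSI/RTI of the central cell swept over inhibition weights
  {0, 0.005, 0.01, 0.05, 0.1, 1} nS. Each cell owns a private RNG stream,
  so at weight 0 the central trace replays the single-cell assay
  bit-exactly. The six sweep weights are a log-spaced choice spanning
  "none" to 1 nS with the 0.1 nS plateau included; the individual values
  are not prescribed by the source data.
* `run_dsgc_assay()` — the 13-SAC network plus a DSGC aligned to the
  central soma, bar sweeping PD, ND, PD, ND (the first PD/ND pair is the
  appearance response and is excluded), conditions {random, asymmetric} ×
  SAC-SAC {0, 0.1 nS} × flicker noise on/off. The DSGC receives bipolar
  input through the same genome-defined density and kinetics rules as the
  SACs (applied over its own 150 µm extent): the source circuit gives the
  DSGC's excitatory drive no parameters of its own, and reusing the
  genome's rules adds none. Noise comparisons are seed-matched (same bar
  and noise realization across inhibition conditions) to reduce variance.
* `run_paired_clamp_validation()` — neighboring SAC pairs, presynaptic soma
  clamped to −40 mV (above the −50 mV release threshold), postsynaptic to
  −5 mV, 0.1 nS contacts; the steady holding current is collected across
  pairs. On the synthetic star the mean sits in the high-100s of pA —
  dominated by the ~170 pA leak of holding a small-area cell 55 mV above
  rest — and increases Ohmically with the synaptic conductance.
* `run_bar_symmetry_control()` — left- vs right-moving bars on the
  even-armed star with distance-uniform kinetics, deterministic release and
  deterministic placement. The two runs are related by a 180° rotation of a
  rotationally symmetric model, so |DSI| < 0.01 is a pure consistency check
  on the stimulus/solver chain (measured ~10⁻⁵).

## The genetic search

`run_ga()` maximizes three objectives over the 8-parameter genome:
obj1 = Amp_CF − Amp_CP (maximal voltages, mV), obj2 = RT_CP − RT_CF (ms),
and obj3, a ceiling score that is 0 while the CF peak stays below −10 mV
and −(maxV + 10) above it, discouraging non-physiological depolarization.
The printed description of obj3 is ambiguous as to its exact form; the
implemented penalty is the form consistent with its stated intent. If
obj1 < 0.04 mV all three objectives are set to −50. Weighted total:
1·obj1 + 0.3·obj2 + 0.08·obj3.

The first generation is uniform within the published bounds; later
generations may exceed them within feasibility (all parameters positive,
spatial parameters at most the 210 µm extent). Variation: per-gene uniform
swap with probability 0.4 (a real-valued stand-in for the ambiguously named
bit-flip operator, which cannot act on continuous genes as printed), then
per-gene Gaussian mutation `Normal(g, g/2)` with probability 0.4. Selection:
rank-by-weighted-total (with 2 elites; the default), NSGA-II
(non-dominated sorting + crowding), or IBEA (additive-ε indicator,
κ = 0.05). All three are elitist (µ+λ for the Pareto methods). Runs are
cached per genome and fully deterministic in the seed.

`inclusion_filter()` defines "CF-preferring": obj1 ≥ 4 mV, rise-time
criterion ≥ 0, voltage score ≥ 0. The source text prints the rise-time
inclusion sign as RT_CF − RT_CP ≥ 0 while the search *maximizes*
RT_CP − RT_CF; since CF preference means a shorter CF rise time, the filter
defaults to RT_CP − RT_CF ≥ 0, with `rt_criterion = "printed"` available
(and announced loudly when used). An optional anatomical filter restricts
the density transition to the inner 2/3 of the arbor.

## Desk-scale problem sizes

The full study ran populations of 100 for 20–45 generations on reconstructed
morphologies. This package's defaults and test suite use desk-scale sizes,
chosen once as the smallest configurations that still express each trend:
population 16–20 for 8–10 generations on the synthetic star, 1000 ms ring
assays inside the search (two cycles: one discarded, one analyzed) and
1500 ms elsewhere, two seeds per kinetics mode for the search, three seeds
for the DSGC trends, and five CF genomes (a search result plus four nearby
variants) for the network inhibition sweep. At these sizes the qualitative
results reproduce: the search finds CF-preferring SACs under the standard
sustained-proximal/transient-distal arrangement and none under the reversed
arrangement; reciprocal inhibition raises RTI monotonically from 0 to
0.1 nS; asymmetric SAC→DSGC wiring alone produces positive DSI where random
wiring does not; and SAC–SAC inhibition improves DSI more on a flickering
background than on a clean one, seed-matched.

## What the synthetic model does and does not show

The synthetic star reproduces the *geometry class* (planar, radial,
210 µm), not a reconstruction: branch statistics, caliber profile, total
membrane area and contact microanatomy all differ. Consequently passing
tests demonstrate that the mechanisms — input-kinetics gradients, distal
release, null-side wiring, reciprocal inhibition — produce the documented
trends in a passive compartmental circuit of realistic scale; they do not
certify point predictions for any particular reconstructed cell (input
resistance, absolute clamp currents, absolute index magnitudes). Active
conductances, the Off pathway, cholinergic co-transmission and
photoreceptor/bipolar populations as explicit cells are out of scope.

## Numerical choices

Backward Euler is first-order; at dt = 0.025 ms the discretization error is
far below the release noise. Compartment nodes at distal ends make path
distances exact at tips. GABA events are snapped to the integration grid;
the 200 Hz phase accumulates in exact multiples of dt. Binomial draws use
per-cell `splitmix64` streams with cached CDF tables (probabilities only
change when the driving intensity does), so every simulation is
bit-reproducible from (configuration, seed) on any platform, and a cell
embedded in a network replays its isolated trajectory exactly when its
couplings are zero. Degenerate inputs (empty synapse tables, zero
conductances, all-dark stimuli) are exercised in the test suite; flat
traces yield NA indices rather than divisions by zero.
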