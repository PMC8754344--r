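# retsim

Compartmental simulation of the retinal direction-selective circuit:
passive multicompartment neurons driven by structured visual stimuli
through stochastic ribbon synapses, wired into starburst-amacrine-cell
(SAC) networks and SAC → ganglion-cell (DSGC) circuits by retina-specific
connectivity rules, with a multi-objective genetic search over the synaptic
architecture.

It is written for computational neuroscientists studying how SACs acquire
their **centrifugal (CF) preference** — stronger, faster depolarization for
motion expanding from the soma than for motion collapsing onto it — and how
that preference, together with asymmetric SAC→DSGC wiring, produces
direction selectivity in DSGCs.

## The model

Cells are passive branched cables (Ra = 75 Ω·cm, Cm = 1 µF/cm², g_pas =
6·10⁻⁵ S/cm², E = −60 mV), integrated by backward Euler (dt = 0.025 ms)
with an O(n) Hines tree solve. Bipolar-cell input is a stochastic ribbon
synapse: a 70-vesicle pool releasing `Binomial(⌊pool⌋, p)` vesicles per
step and refilling at rate *r*, each vesicle triggering a 0.89/1.84 ms
double-exponential conductance (reversal 0 mV). With distance *d* from the
soma, `u = min(d, m)/m`:

```
p(d) = min(k_tsp + release_probability · u, 1) · V_intensity
r(d) = refilling_rate,                    if k_tsp > u
       refilling_rate · (k_tsp + 1 − u),  otherwise
```

so proximal inputs are sustained and distal inputs transient. Synapse
density along the arbor follows
`max(1 − (sf·0.5·(1 + tanh(x − atp)) + offset), 0)` per µm. The eight
parameters (3 distribution, 4 kinetics, 1 conductance) form a *genome*
searched by a genetic algorithm maximizing CF preference:
`(Amp_CF − Amp_CP, RT_CP − RT_CF, voltage ceiling)` with weights
(1, 0.3, 0.08) and a −50 penalty when Amp_CF − Amp_CP < 0.04 mV.

Selectivity is quantified by CSI = (R_exp − R_col)/(R_exp + R_col),
RTI = (rt_col − rt_exp)/(rt_col + rt_exp),
DSI = (R_PD − R_ND)/(R_PD + R_ND), and the sustained–transient index
STI = steady-state/peak of a synapse's averaged release PSTH.

GABAergic synapses (τ = 3/30 ms; −75 mV SAC→SAC, −60 mV and 0.5 nS
SAC→DSGC) form at planar process intersections (≤ 5 µm), release from the
distal third of the SAC arbor, fire 200 Hz event trains while the
presynaptic compartment is above −50 mV, and connect to the DSGC with
probability `arccos(u·PD)/π` — null-side wiring.

## Worked example

```r
library(retsim)

# a centrifugal-preferring synaptic genome on the synthetic star SAC
assay <- run_single_sac_assay(genome_params(), seed = 1)
assay
#> <sac_assay: CSI 0.044, RTI 0.452, 514 synapses>
```

The expanding rings drive a stronger response (positive CSI) with a faster
rise (positive RTI) than the collapsing rings — a centrifugal preference
arising purely from the spatiotemporal arrangement of the excitatory input.
Embedding clones of the same cell in the 13-SAC two-grid network and
switching on reciprocal inhibition sharpens the response kinetics:

```r
net <- run_network_assay(genome_params(), inhibition_weights = c(0, 0.1),
                         seed = 3)
net$summary[, c("weight", "csi", "rti")]
#>   weight         csi       rti
#> 1    0.0  0.04277685 0.1420884
#> 2    0.1 -0.07421941 0.7303549
```

Inhibition strongly delays the centripetal response (RTI 0.14 → 0.73); the
amplitude index of this particular genome drops slightly, as happens for
cells with denser distal input. At weight 0 the central cell's trace is
bit-identical to the single-cell assay. Adding a DSGC with asymmetric
(null-side) wiring produces direction selectivity that random wiring does
not:

```r
run_dsgc_assay(genome_params(), "asymmetric", sac_sac_weight = 0.1, seed = 1)
#> <dsgc_assay: asymmetric wiring, SAC-SAC 0.1 nS, noise FALSE; DSI 0.221, PD activation 1972.6 mV ms>
run_dsgc_assay(genome_params(), "random", sac_sac_weight = 0.1, seed = 1)
#> <dsgc_assay: random wiring, SAC-SAC 0.1 nS, noise FALSE; DSI -0.018, PD activation 14.9 mV ms>
```

The genetic search itself:

```r
run <- run_ga(ga_config(population = 16, generations = 8, seed = 11))
nrow(inclusion_filter(run))   # genomes with a clear CF preference
#> [1] 1
```

Running the same search with `kinetics_mode = "reversed"` (transient
proximal, sustained distal) finds none.

See the vignette (`vignettes/retinal-circuit-model.Rmd`) for the model's
assumptions, parameter meanings and the desk-scale problem sizes.

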