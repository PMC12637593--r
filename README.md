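# fsephys

Analysis and simulation of whole-cell recordings from fast-spiking (FS)
cortical interneurons and of the inhibitory synapses they make onto
pyramidal neurons.

Fast-spiking, parvalbumin-positive interneurons fire narrow action
potentials at hundreds of Hz, and both their spike waveform and their
short-term synaptic depression depend sensitively on the complement of
voltage-gated potassium channels they express — in particular on "silent"
Kv subunits that conduct no current alone but assemble with Kv2
delayed-rectifier subunits into heteromeric channels whose voltage
dependence of inactivation is shifted 30–40 mV hyperpolarized. This
package implements the measurement pipeline used to characterise such
effects, together with seeded generators that produce synthetic cohorts
with the same statistical structure, so every stage can be validated end
to end without proprietary acquisition files.

## What it computes

**Action-potential waveform features** (current clamp). Spike threshold
uses the dV/dt criterion: the membrane potential at which dV/dt first
exceeds 4% of the maximum slope during the upstroke. From there, height
(peak − threshold), half-width (width at threshold + height/2, with
linear interpolation at the crossings), maximum slope, interspike
potential (most negative V between consecutive spikes), interspike
intervals, rheobase, I–V and f–I curves, sag, train AHP, and adaptation
metrics (ΔISI = ISI₍₄₉₋₅₀₎ − ISI₍₂₋₃₎ and AP₅₀ − AP₂ changes, for trains
of ≥ 50 APs). Group analysis standardises across cells by selecting the
first trace containing at least 10 APs and reporting the 2nd and 10th AP.

**IPSC / short-term plasticity analysis** (voltage clamp). IPSC peaks
against a local pre-stimulus baseline; paired-pulse ratios with overlap
correction — the residual decay of the first IPSC is fitted with a
baseline-anchored mono-exponential and subtracted from the second peak,
so `PPR = |I(peak₂) − fit(peak₂)| / A₁`; 5-pulse train curves normalised
to the first pulse (deliberately uncorrected, matching the convention of
the protocol this emulates); passive properties (R_series, R_membrane,
τ, C_m) from a test pulse; and pointwise conversion of current to
inhibitory conductance via

    I_i(t) = g_i(t) (V(t) − E_i)
    V(t)   = V_hold − I(t) R_series
    I(t)   = I_i(t) + (V(t) − E_rest) / R_membrane

with V_hold = −70 mV, E_rest = −16 mV, E_i = −2.5 mV by default.

**Group statistics.** One-way ANOVA with Tukey–Kramer post hoc
comparisons, unpaired two-tailed (pooled) t tests, mixed repeated-
measures ANOVA with Greenhouse–Geisser correction (ε from the pooled
within-subject covariance), bootstrap of sample means, mean ± SEM
summaries.

**Generators.** A single-compartment conductance-based FS neuron (Na
with fast and slow inactivation, Kv3-like fast K, and a Kv2-like
delayed rectifier split into homomeric and heteromeric populations; the
heteromer fraction `f_het` is the genotype knob, with `f_het = 0`
representing a silent-subunit knockout) and a Tsodyks–Markram-style
depressing synapse (release fraction `U`, recovery τ_rec; amplitudes
follow `R₁ = 1`, `Aₙ = U·Rₙ`,
`Rₙ₊₁ = Rₙ(1−U) + (1 − Rₙ(1−U))(1 − exp(−Δtₙ/τ_rec))`). Cohort-level
wrappers reproduce the two study designs (intrinsic: 18/16/20 cells,
current steps −200…200 pA by 40 and 200…1200 pA by 100; synaptic: 11/10
pairs, paired pulses at Δt = 10…1000 ms plus 5-pulse trains), and
`run_intrinsic_study()` / `run_synaptic_study()` take either generated
cells or on-disk sweep bundles (JSON metadata + per-sweep CSV).

## Worked example

```r
library(fsephys)

# a wild-type-like cell (half its Kv2 conductance in heteromers)
par <- fs_neuron_params(noise_sd_pA = 0)
sw  <- simulate_fs_neuron(par, step_protocol(600), dt_ms = 0.02)
ap_events(sw)[c(2, 10), c("peak_V_mV", "threshold_V_mV", "height_mV",
                          "half_width_ms", "interspike_potential_mV")]
#>    peak_V_mV threshold_V_mV height_mV half_width_ms interspike_potential_mV
#> 2      37.55         -43.61     81.16        0.2045                  -68.09
#> 10     26.88         -43.71     70.59        0.1957                  -65.98

# paired-pulse depression at a 10 ms interval, decay-corrected, with
# conductance conversion through the measured passive properties
syn <- synapse_params(U = 0.60, tau_rec_ms = 50, noise_sd_pA = 0)
sw2 <- simulate_ipsc_train(syn, stim_train(c(50, 60)))
ppr(sw2, params = conductance_params(R_series_MOhm = 19,
                                     R_membrane_MOhm = 211))
#>   delta_t_ms A1_pA A2_raw_pA A2_corrected_pA ppr_i ppr_raw tau_decay_ms
#> 1         10  1200      1083             604 0.503   0.902         10.1
#>   A1_nS A2_corrected_nS ppr_g
#> 1  32.5            18.6 0.572
```

The second spike of the 600 pA train is ~81 mV tall and ~0.2 ms wide at
half height, typical FS values. For the synapse, the raw second/first
ratio (0.90) is inflated by the overlap with the first IPSC's decay;
the corrected ratio (0.503) matches the resource model's closed form
`1 − U·e^(−Δt/τ_rec) = 0.509` at this interval, and the conductance-
domain ratio differs because a ~1.2 nA current through a 19 MΩ series
resistance produces a sizeable voltage-clamp error that the conversion
removes.

A command-line front end is installed with the package
(`inst/cli/fs-ephys`): `fs-ephys simulate`, `validate`, `features`,
`intrinsic`, `synaptic`, `run`.

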