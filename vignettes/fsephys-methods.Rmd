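---
title: "Models and methods behind fsephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fsephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside the package: the measurement
conventions, the generative models and their calibration, the numerical
choices, and the decisions taken where the underlying experimental
conventions leave room. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement problem

Fast-spiking (FS), parvalbumin-positive cortical interneurons sustain
very high firing rates with sub-millisecond action potentials. Their
waveform is shaped by a division of labour among potassium currents:
fast Kv3-type channels repolarise each spike, while slower Kv2-type
delayed rectifiers accumulate across a train. Silent Kv subunits (such
as Kv6.4) conduct nothing alone but co-assemble with Kv2 subunits into
heteromers whose steady-state inactivation sits 30–40 mV hyperpolarized
of the homomer's, effectively removing part of the delayed-rectifier
reserve in cells that express them. Loss of the silent subunit therefore
predicts narrower spikes, deeper interspike potentials, and — through
increased Na-channel availability — lower thresholds and faster
upstrokes, with all effects amplified during repetitive firing; on the
output side, a narrower presynaptic spike predicts reduced GABA release
and hence less paired-pulse depression at short intervals.

The package measures exactly those quantities from whole-cell
current-clamp and voltage-clamp sweeps, and ships generators that encode
the mechanism so the complete pipeline can be validated.

## 2. Waveform feature conventions

* **Detection.** An AP is a local maximum above 0 mV with ≥ 1 ms to the
  previously accepted event. Both constants are arguments; the
  underlying acquisition convention is not standardised in this field,
  so the criterion is deliberately minimal.
* **Threshold.** The voltage at which dV/dt (central differences) first
  exceeds 4% of the maximum upstroke slope. The upstroke window runs
  from the preceding interspike minimum (2 ms before the peak for the
  first AP) to the peak. Note a property of this *relative* criterion
  that matters for interpretation: uniformly scaling the Na current
  moves the measured threshold only weakly, because the 4% line scales
  with the maximum slope.
* **Height** is peak minus threshold. Printed group values in this
  literature (~85 mV heights with ~−42 mV thresholds, implying ~+43 mV
  peaks) are consistent with the threshold-referenced definition, and it
  is invariant to baseline offsets.
* **Half-width** is measured at threshold + height/2 with linear
  interpolation between the bracketing samples of both crossings.
* **Interspike potential** is the most negative sampled voltage strictly
  between consecutive peaks.
* **Trace selection.** Cells differ in rheobase, so group analysis uses
  the first sweep (in ascending step order) with ≥ 10 APs and reports
  the 2nd and 10th AP plus the mean over APs 1–10. Adaptation metrics
  (ΔISI = ISI₍₄₉₋₅₀₎ − ISI₍₂₋₃₎, AP₅₀ − AP₂) analogously use the first
  sweep with ≥ 50 APs; with ISIᵢ defined as the interval preceding
  AP(i+1), a train whose intervals grow by 0.1 ms per interval gives
  ΔISI = 4.7 ms.
* **Train AHP** is defined threshold-to-trough in a 50 ms window after
  the last spike (the per-AP and train-average readings can be built
  from `ap_events()`; the post-train trough is the default
  interpretation of a "train AHP", and the choice is flagged here
  because conventions differ).
* **Sag** is measured on the −200 pA step as steady state (final 20%)
  minus the early minimum (first 200 ms), and is ~0 for a pure RC
  response.

Every extractor is tested against an independent brute-force oracle
(dense scan or closed form) on ≥ 100 randomised synthetic spikes, to
1 sample in time, 0.1 mV in voltage and 2% in widths/slopes.

**Discretisation caveat.** At 50 kHz a sub-0.25 ms spike leaves ~10
samples above half height; half-width interpolation is stable to ≪ 2%,
but the maximum slope of a very fast upstroke is systematically
underestimated by a few percent at coarser sampling. The rescaling
invariant (halving dt changes widths and slopes by < 2%) is therefore
verified on spikes whose dV/dt transient is resolved at both rates;
comparisons of maximum slope across recordings should use a common
sampling rate.

## 3. IPSC analysis conventions

* **Peaks** are inward extrema in a (0.5, 20] ms post-stimulus window
  against the mean of the preceding [−5, −0.5] ms; the first 0.5 ms is
  blanked as stimulus artifact.
* **Paired-pulse correction.** Overlap of the second IPSC with the decay
  of the first is removed by fitting a baseline-anchored
  mono-exponential to the first decay over [peak₁ + 1 ms, stim₂ − 0.5 ms]
  (capped at 50 ms — beyond that the residual is numerically zero and
  only noise would be fitted) and subtracting its extrapolation at the
  second peak time. A mono-exponential is the minimal model for the
  "residual decay"; fits with τ outside (0.5, 500) ms fall back to the
  uncorrected amplitude with a warning. The bias this correction removes
  is exactly `e^(−Δt/τ_d)` of the first amplitude for idealised kernels,
  which the tests verify analytically.
* **Ratios are computed per sweep, then averaged** over the 3–5 repeats
  of an interval. Averaging traces first is more sensitive to slow
  drift; a config flag is not offered because the per-sweep route
  subsumes it for the synthetic data.
* **5-pulse trains are deliberately uncorrected** (per-pulse peak minus
  the pre-train baseline, normalised to pulse 1), matching the protocol
  convention this package reproduces; the resulting upward bias of later
  pulses at short intervals is quantified in the tests by a
  geometric-series oracle rather than removed.
* **Conductance conversion** solves the three-equation system (synaptic
  current with driving force to E_i; series-resistance voltage error;
  leak through R_membrane to E_rest) pointwise for g_i(t) and takes
  amplitudes as peak-minus-baseline on the conductance trace. The
  pointwise form subsumes a peak-only conversion. E_rest = −16 mV and
  E_i = −2.5 mV are treated as fixed constants of the recording
  condition (high-chloride cesium internal at V_hold = −70 mV).
  Conversion refuses to divide when |V − E_i| < 1 mV inside an analysed
  window. One consistency note: with E_rest = −16 mV and
  R_membrane ≈ 210 MΩ the baseline holding current implied by the leak
  equation is ≈ −235 pA, slightly beyond the nominal 200 pA
  quality-control bound; the generator synthesises the self-consistent
  baseline, `qc_cell()` still reports the 200 pA rule, and the synaptic
  pipeline excludes by default only on the series-resistance rule.
* **Passive properties** come from a test pulse: R_series = ΔV/I_peak,
  R_membrane = ΔV/I_ss − R_series, τ from an exponential fit of the
  transient (log-linear start, `nls` refinement), and
  C_m = τ·(1/R_series + 1/R_membrane), the capacitance consistent with
  the parallel-resistance relaxation time.

## 4. The neuron generator

A single-compartment conductance model (units mV, ms, nS, pF, pA):

* leak (13 nS to −75 mV; input resistance ≈ 75 MΩ, rest ≈ −75 mV);
* transient Na (10 µS to +68 mV) with activation m³ (τ = 15 µs),
  fast inactivation h, and a slow inactivation gate s (τ = 35 ms,
  partial: floor 0.5) whose steady state is steep around −63 mV — s
  integrates the interspike potential over several intervals and is the
  channel through which a deeper trough translates into higher Na
  availability, lower threshold and faster upstroke;
* Kv3-like fast K (1.4 µS, n², activating near −8 mV with sub-0.1 ms
  deactivation) — sets the sub-0.25 ms half-width;
* Kv2-like delayed rectifier (1 µS to −80 mV) split into homomer and
  heteromer populations by `f_het`. Both share a steep activation gate
  (half-voltage −20 mV, τ = 0.6 ms); the heteromer's activation is
  shifted by `d_act = −20 mV` and its (partial, floor 0.15, fast
  τ = 4 ms) inactivation by `d_inact = −40 mV`.

Genotype mapping: wild-type cells default to `f_het = 0.5`,
heterozygous knockouts to 0.3, homozygous knockouts to 0. The knockout
thereby gains delayed-rectifier current at spike voltages (narrower
spikes, deeper troughs) while the wild type carries extra heteromer
conductance in the narrow pre-takeoff voltage band (raising its measured
threshold relative to the knockout). These two shifts are how the
mechanism — a hyperpolarized shift of heteromer availability — is
expressed in a single compartment; the inactivation shift magnitude sits
at the edge of the reported 30–40 mV range and the activation shift is
a documented additional assumption of this model, supported by
heterologous characterisation of silent-subunit heteromers.

Calibration was done once, against bands rather than fitted: resting
potential in [−80, −70] mV, 2nd-AP height in [75, 95] mV and half-width
in [0.15, 0.35] ms at a 600 pA step, sustained firing without
depolarisation block up to 1200 pA, and consistent knockout effect
directions (half-width, interspike potential, 10th-AP threshold,
10th-AP maximum slope) across the whole 200–1200 pA family. Two
structural lessons from that calibration are recorded here because they
explain the model's shape: (i) per-interval gating memory with time
constants near the ISI produces chaotic step-to-step sign flips of
per-spike metrics, so all fast gates are quasi-steady and the only
slow memory is the s gate, which averages over several ISIs; (ii) a
pure availability (Na) difference barely moves the 4%-criterion
threshold because the criterion is relative, hence the heteromer
activation-shift load in the pre-takeoff band.

Integration is exponential Euler for the gates and for the
conductance-form voltage equation, sub-step ≤ 5 µs (unconditionally
stable; halving the sub-step moves spike times by < 0.4%, and the
recorded ionic currents balance C·dV/dt to first order, both asserted in
the tests). Background noise is an Ornstein–Uhlenbeck current (default
SD 20 pA, τ 1 ms) driven by R's RNG, so cohorts are bit-reproducible
from a seed.

**What the generator does not emulate:** dendritic/axonal compartments,
an H-current (sag is ~0 by construction; the sag extractor is validated
on constructed fixtures), seal/electrode artifacts, and the full
diversity of FS subtypes. Group means of the synthetic cohorts land near
typical FS values by construction of the calibration bands, but the
heights at near-rheobase selected traces run ~10–15 mV lower than at
600 pA, and knockout effect sizes on slope are larger than is typical
of real recordings. Passing tests therefore demonstrate correctness of
the measurement pipeline and statistical machinery on data with the
right structure, not fidelity of the model to any particular recording.

## 5. The synapse generator

Resource depletion with utilisation `U` and recovery `tau_rec_ms`:
R₁ = 1, Aₙ = U·Rₙ, Rₙ₊₁ = Rₙ(1−U) + (1 − Rₙ(1−U))(1 − e^(−Δtₙ/τ)).
Events are difference-of-exponential kernels (rise 0.5 ms, decay 10 ms)
normalised to unit peak and scaled by `scale_pA` (2000 pA, so a
wild-type first pulse is ≈ 1.2 nA, a realistic unitary FS→pyramidal
IPSC under high-chloride conditions); currents are inward. Facilitation
is omitted: the phenomenology being reproduced is depression-only.
Binomial release draws Binomial(n_sites, U·Rₙ)/n_sites around the
mean-field trajectory, so the mean over repeats converges exactly to the
deterministic amplitudes (asserted within 3 SE over 1000 repeats).

Genotype enters through `U`: 0.60 (wild type) vs 0.45 (knockout), with
a between-pair SD of 0.08 — values chosen once so that group mean ratios
and their SEMs at the 11/10-pair design size land in the observed range
for this synapse (ratios near 0.5 vs 0.67 at 10 ms with SEM ≈ 0.03).
`tau_rec_ms = 50` so that recovery is essentially complete by 200 ms:
the genotype difference is then confined to short intervals, vanishing
(< 0.01 ratio units) beyond 200 ms, which is the qualitative structure
the paired-pulse profile must reproduce. A slower recovery (e.g.
τ = 200 ms) would leave a several-percent group difference at 200 ms,
contradicting that structure. The presynaptic spike waveform is not
modelled; genotype effects enter only through `U`, because the
waveform→calcium→release chain is outside what paired-pulse
measurements constrain.

The eleven stimulation patterns of the emulated protocol are the seven
paired-pulse intervals plus 5-pulse trains; only two train intervals are
documented explicitly in the emulated study, so the train interval list
defaults to {10, 20, 50, 100} ms and is configuration, not an assertion.

## 6. Statistics

* One-way fixed-effects ANOVA (via `lm`/`anova`), with Tukey–Kramer
  post hoc comparisons using the studentized range (`ptukey`) and the
  Kramer standard error for unequal n (reducing to Tukey HSD at equal
  n).
* Unpaired two-tailed t tests are pooled-variance by default (the
  classical reading of an unadorned "unpaired t test"); Welch is
  available via `var_equal = FALSE`.
* The repeated-measures analysis is a mixed (split-plot) two-way ANOVA:
  genotype between subjects, interval within, `aov` with an
  `Error(subject)` stratum. The Greenhouse–Geisser ε is computed from
  the group-pooled covariance of the within-subject profiles
  (ε = (Σλ)²/((k−1)Σλ²) over the double-centred eigenvalues, clamped to
  [1/(k−1), 1]; ε ≡ 1 for k = 2) and multiplies the within-stratum
  degrees of freedom. ε and the interaction test agree with the
  multivariate-model route (`car::Anova`, type III) to 10⁻⁶; under
  unequal group sizes the *within main effect* can differ between
  sum-of-squares conventions, which is documented rather than hidden —
  the scientifically loaded tests here are the genotype and
  genotype × interval effects, which agree exactly.
* No multiple-testing correction is applied across metrics: each metric
  is reported with its own ANOVA, mirroring the per-metric reporting
  convention of the studies this reproduces.
* The bootstrap resamples *cells* (not APs) with replacement, 1000
  iterations, because the visualised quantity is the sampling
  distribution of the group mean over cells.

All four tests are calibrated by simulation in the acceptance suite:
null rejection rates within [0.03, 0.07] at α = 0.05 over 1000
replicates (AR(1) within-subject covariance for the repeated-measures
case).

## 7. Problem sizes

The acceptance suite and `scripts/acceptance.R` run the full designs:
18/16/20 cells × 22 steps for the intrinsic study, 11/10 pairs × 7
intervals × 3 repeats for the synaptic study, 100 replicate studies for
power/type-I of the paired-pulse comparison, and 1000 null replicates
per statistical test. The unit-test suite exercises the same code paths
at reduced sizes (fewer steps, intervals and replicates), which is a
choice about where the computational budget buys the most checking: the
full-scale properties are asserted once, in the acceptance suite.

## 8. Known limitations

* The neuron model is phenomenological; its parameters were chosen to
  land in literature-typical FS bands, not fitted to recordings, and
  several quantities (maximum slope, f–I gain at high drive) sit at the
  fast edge of physiological ranges.
* Sag and AHP group comparisons on synthetic cohorts are uninformative
  by construction (no H-current; AHP shaped entirely by the K
  conductances).
* The wild-type population can optionally be generated as a mixture of
  silent-subunit-expressing and non-expressing cells
  (`kcng4_fraction < 1`), reflecting the biological caveat that only a
  subset of wild-type FS cells express the subunit. The default is 1
  (all cells express): mixture variance otherwise dominates the
  between-cell spread and caps the attainable effect size of
  wild-type-vs-knockout comparisons regardless of the per-cell effect,
  which would make cohort-level power assertions meaningless. Analyses
  of mixed cohorts should compare heterozygous against homozygous
  knockouts, which is also the cleaner comparison biologically.
* Voltage-clamp sweeps are generated directly in current units with an
  ideal clamp plus the algebraic series-resistance error; dynamic
  clamp-escape transients are not modelled.
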