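# spinephys

Electrophysiological feature extraction and unsupervised classification of
spinal dorsal horn neurons from whole-cell patch-clamp recordings.

Studies of spinal projection neurons (for example spinoparabrachial neurons,
identified by retrograde labelling and compared against unlabelled
interneurons) characterise each cell by a standard battery: passive membrane
properties from a seal test, a family of 1-s depolarising current steps in
20-pA increments from −70 mV, a voltage-clamp protocol for subthreshold
currents (−70 → −100 mV for 1 s, then −40 mV for 200 ms, with P/N leak
subtraction), and ≥30 s of spontaneous EPSCs at −70 mV. `spinephys`
implements that battery as a tested, reusable pipeline:

- **Membrane features** — input resistance and capacitance from averaged
  −5 mV seal-test sweeps (Rin = |ΔV/ΔI_ss|, Cm from the capacitive-transient
  charge), resting potential, rheobase, spike detection at the
  dV/dt = 15 mV/ms criterion, AP waveform features (peak amplitude, rise,
  base width, AHP amplitude and latency, all measured against the AP
  threshold), and discharge metrics (latency, ISIs, mean and instantaneous
  frequency, adaptation = last/first instantaneous frequency,
  attenuation = last/first AP peak amplitude in %).
- **Discharge classification** — rule-based assignment of the seven
  patterns: tonic (TF), delayed (DF), gap (GF), initial-burst (IB),
  single-spike (SS), phasic (P) and reluctant (RF) firing, evaluated at
  rheobase + 40 pA, plus the three AHP profiles (monophasic, ADP, slowed
  repolarisation) and the initial depolarising hump.
- **Subthreshold currents** — P/N leak subtraction, classification of the
  dominant transient as fast A-type (latency to peak < 15 ms), slow A-type
  (> 15 ms), T-type-like inward, or no current, and Ih sag detection.
- **Synaptic events** — sliding-template (optimally scaled least-squares)
  sEPSC detection with amplitude, 10–90% rise, decay τ, charge and
  excitatory drive (charge × frequency) from the averaged event.
- **Clustering** — Euclidean/Ward hierarchical clustering of a 20-feature
  panel with silhouette-based cluster-number selection (s(i) = (b−a)/max(a,b);
  k grows until an additional cluster introduces negative silhouettes),
  min–max heatmap normalisation, Newick dendrogram export, cluster purity.
- **Statistics** — unpaired t tests, χ² incidence tests, one-way ANOVA with
  Tukey HSD, and proportion arithmetic for reporting.
- **Liquid junction potential** — a Henderson-equation calculator with a
  bundled limiting-mobility table and salt-dissociation dictionary.
- **Synthetic recordings** — a single-compartment conductance-based neuron
  model (Hodgkin–Huxley spike currents plus inactivating fast/slow A-type
  potassium, T-type-like calcium, persistent sodium, Ih and a slow
  adaptation conductance, RK4 at 0.01 ms) that generates every protocol
  with ground-truth labels, so each analysis stage is validated against
  planted truth.

## Worked example

```r
library(spinephys)

# simulate a gap-firing cell and classify its discharge
spec <- discharge_presets()$GF
sim  <- simulate_current_clamp(spec, seed = 1)
rheo <- find_rheobase(sim$sweeps)
call <- classify_discharge(sim$sweeps, rheo)
rheo$rheobase_pA
#> [1] 160
call
#> <discharge_call> GF
# evidence: n_spikes = 34, first_latency_ms = 3.6, first_isi_ratio = 91.6

# junction potential of the K-gluconate internal against ACSF at 22 °C
as.numeric(kgluconate_acsf_ljp(22))
#> [1] 15.16487
```

The rheobase (160 pA) is the smallest step in the 20-pA family that evokes
a spike; the gap-firing call rests on an onset spike within 50 ms whose
first interspike interval is ~92× the median of the later ones; the 15.2 mV
junction potential is the usual correction magnitude for a 135 mM
potassium-gluconate internal against bicarbonate ACSF.

A full end-to-end run over a labelled synthetic cohort —
`simulate_cohort()` → `extract_cell_features()` → `assemble_feature_table()`
→ `minmax_normalize()` → `ward_linkage()` → `silhouette_select_k()` →
`build_report()` — is shown in the methods vignette
(`vignettes/spinal-neuron-classification.Rmd`).

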