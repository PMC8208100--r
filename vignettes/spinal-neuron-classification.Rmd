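---
title: "Classifying spinal dorsal horn neurons from patch-clamp recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying spinal dorsal horn neurons from patch-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinephys)
```

`spinephys` turns the standard whole-cell characterisation battery for
spinal dorsal horn neurons into a tested pipeline: trace-level feature
extraction, rule-based discharge and AHP-profile classification,
subthreshold-current decomposition, synaptic-event statistics, and
Euclidean/Ward clustering with silhouette-based cluster-number selection.
Because raw recordings from such studies are rarely deposited, every stage
is validated against a synthetic recording generator with planted ground
truth. This vignette explains the science and the design decisions; it
states no result that the test suite does not itself compute.

## The measurement model

A recording is a set of uniformly sampled sweeps (default 0.1 ms, i.e.
10 kHz) grouped by protocol:

* `passive_5mV` — repeated −5 mV voltage-clamp seal tests. Input resistance
  is $R_\mathrm{in} = |\Delta V / \Delta I_{ss}|$ with the steady state
  taken over the final 20% of the step; capacitance is the charge of the
  leak-subtracted capacitive transient divided by $\Delta V$
  ($Q/\Delta V$, in pF when $Q$ is in pA·ms and $\Delta V$ in mV). Charge
  integration is robust to access resistance, which a single-exponential
  fit is not; the integration window is 5 ms (many hundreds of access time
  constants) so baseline noise contributes little.
* `passive_60s` — a long current-clamp recording at 0 pA bias. The resting
  potential is the mean of spike-free samples (±5 ms around each spike
  excluded); spontaneous activity is `none`, `bursting` (≥2 clusters of ≥3
  spikes, intra-burst intervals < 100 ms, silences > 1 s), `tonic`
  (ISI coefficient of variation < 0.5) or `irregular`.
* `step_family` — 1-s depolarising steps in 20-pA increments from −70 mV.
  Spikes are detected where the centered-difference dV/dt reaches
  15 mV/ms. Two robustness guards matter in practice: a strong step
  charges a 13-pF membrane faster than 15 mV/ms, so (a) an excursion only
  counts as a spike if its peak exceeds −20 mV, and (b) the threshold is
  anchored at the *last* upward crossing of the criterion before the peak,
  which coincides with the first for a spike rising out of a subthreshold
  baseline but not for one riding a fast step onset.
* `subthreshold_VC` — holding −70 mV, 1 s at −100 mV, 200 ms at −40 mV,
  with P/4 leak subtraction. Every trace is referenced to its pre-step
  baseline before scaling, so a purely ohmic cell cancels exactly
  regardless of its resting conductance.
* `sepsc_VC` — ≥30 s of continuous voltage clamp at −70 mV.

All sweeps carry explicit units (mV or pA); an operation handed a sweep in
the wrong units refuses it rather than rescaling.

## Discharge classification

The taxonomy is qualitative in origin; the classifier operationalises it
with declared constants (`discharge_rules()`), applied to the response two
20-pA steps above rheobase in fixed precedence RF → SS → GF → IB → P → DF →
TF (most specific first):

* **RF** — no spikes at any step, but the family repeated from a more
  depolarised holding potential does fire. A silent family without a firing
  retest is reported as unclassifiable, never silently RF.
* **SS** — exactly one spike at the evaluation step and at most one at
  every suprathreshold step.
* **GF** — onset spike within 50 ms whose first interspike interval exceeds
  3× the median of the later ones.
* **IB** — ≥2 spikes in the first 100 ms with mean intra-burst interval
  < 40 ms and no spikes in the final half of the step.
* **P** — ≥2 discharge episodes separated by gaps > 3× the median ISI
  (a leading single-spike episode alone is GF geometry and is excluded).
* **DF** — first-spike latency > 100 ms after a rising (depolarising ramp)
  trajectory.
* **TF** — discharge spanning ≥80% of the step.

AHP profiles: `ADP` when a local depolarising maximum of ≥0.5 mV prominence
appears after fast repolarisation (with an `on_slow_ahp` flag when the
post-bump trough is deeper than the pre-bump one); `slowed` when the fall is
monotone but its slope collapses below 25% of the initial rate (a shoulder);
otherwise `monophasic`.

## Subthreshold currents

After P/N subtraction, the dominant transient during the −40 mV step is
classified by sign and latency: outward with latency < 15 ms → fast A-type;
outward at ≥15 ms → slow A-type (the boundary value itself is slow, since
the fast definition is strictly "< 15 ms"); inward → T-type-like. Peaks are
measured on a 2-ms running-mean trace; the no-current floor is 4× the
pre-step baseline sd, scaled analytically to the smoothed trace. Ih is a
slow monotone inward development during the hyperpolarising step, measured
between the early plateau (20–100 ms) and the step end, called present above
3× the baseline sd.

## Synaptic events

Detection follows the optimally-scaled sliding template approach: at every
offset a difference-of-exponentials template (rise 0.5 ms, decay 4 ms,
length rise + 3 decay constants) is fitted by least squares with free scale
and offset; the statistic is scale / SE(scale). Defaults: criterion 4.5 and
a 2-pA minimum fitted amplitude. These were calibrated against the
detector's own operating characteristics: at 10 kHz a pure-noise trace
produces local criterion maxima above 3.5 roughly ten times per 30 s, and
refits of an event's decay score 3.5–4.6, whereas true events of
physiological amplitude score ≳8 — so 4.5 keeps false positives below about
one per 30 s without costing recall. Candidates are local maxima of the
statistic with non-maximum suppression over half a template length, plus a
matched-filter sidelobe rule (a candidate within one template length of a
≥2× stronger one is its decay refit) and a polarity check that the trace at
the template-peak lag actually drops below the onset level. The offset term
makes detection invariant to DC shifts; outward events are rejected by the
polarity check. Event statistics (amplitude, 10–90% rise, decay τ by
log-linear fit over the 10–90% decay span, charge, drive = charge ×
frequency) are measured on the onset-aligned average.

## Clustering

The 20-feature panel (`default_feature_panel()`) spans passive, AP
waveform, discharge, synaptic and subthreshold parameters; categorical
pattern and profile calls annotate the dendrogram but do not enter the
distance. Features are min–max normalised before Euclidean distances are
computed — the same convention as the heatmap display, and a guard against
unit dominance. Ward linkage follows the standard Lance–Williams convention
(singleton pairs merge at their Euclidean distance; height² = 2 × SSE
increase); the test suite checks the tree against a brute-force greedy
SSE-minimisation oracle on 100 random instances of up to 8 points.

Cluster number selection computes per-sample silhouettes
$s(i) = (b-a)/\max(a,b)$ for each cut $k = 2..8$ and chooses the largest
$k$ for which no cut up to $k$ contains a negative silhouette while the
$k+1$ cut does. If no negative appears at all, the mean-silhouette
maximiser is reported with a flag; if negatives already appear at $k=2$, a
single cluster is reported. Two geometric caveats, documented because they
shaped the synthetic benchmark below: the rule's "negative at $k+1$" signal
comes from boundary misassignments when a genuine cluster is split, which
requires reasonably dense clusters; and exactly equidistant cluster
centroids make every coarser cut a knife-edge with near-zero minimum
silhouettes.

## The synthetic generator: what it emulates, and what not

The neuron model is a single compartment with explicit Hodgkin–Huxley
sodium and delayed-rectifier currents (full AP waveforms, not
integrate-and-fire resets, so waveform features are measurable), plus
optional channels chosen for the phenotypes they support: fast and slow
inactivating A-type potassium conductances, a transient low-threshold
calcium conductance, a persistent sodium conductance, an
hyperpolarisation-activated cation conductance, and a slow sigmoidal
adaptation conductance. Integration is fixed-step RK4 at 0.01 ms,
downsampled to the 10-kHz recording grid; membrane noise is an injected
Ornstein–Uhlenbeck current (τ = 5 ms) scaled so the subthreshold voltage
fluctuation has approximately the requested sd (0.5 mV by default).
Ground-truth spike times are the model's own upward crossings of −20 mV.

The presets express the qualitative phenotype definitions, not calibrated
biophysics (no quantitative channel kinetics are claimed anywhere): delayed
firing uses a fast A-type conductance whose slow inactivation produces the
onset ramp; gap firing a slow A-type conductance that spares the onset
spike; initial bursting a T-type conductance over a strongly adapting cell;
single spiking a large non-recovering adaptation conductance; phasic
discharge a strong slow A-type conductance whose slow activation lets a
short onset episode through and whose inactivation later releases a second
sustained episode; reluctant firing a large, very slowly inactivating
A-type conductance available at −70 mV but inactivated at depolarised
holding (the generator also emits the depolarised-holding retest family the
RF rule requires). Voltage-clamp responses are computed analytically
(exponential gate relaxation within constant-command epochs — exact, no
integration error), with P/N subsweeps emitted as averages of 4 repeated
acquisitions, the standard amplifier practice without which the ×4
rescaling amplifies subsweep noise 2.2-fold and the no-current floor
false-triggers. The seal test is generated analytically with bin-averaged
currents (charge is exact at 10 kHz) around a 1-MΩ access resistance.
sEPSC trains are Poisson events with difference-of-exponentials kinetics;
defaults (6 Hz, −21 ± 5 pA, rise τ 0.6 ms, decay τ 5 ms, 30 s, 2 pA
baseline noise) reflect typical dorsal horn values.

Planted feature tables place cluster centroids on a nested binary
hierarchy — the closest pair exactly `separation` within-cluster sds apart,
each higher level 3× the span of what it joins, in random orientation —
because real multi-parameter panels separate subpopulations less than major
populations, and because this geometry keeps coarse dendrogram cuts
unambiguous for the silhouette rule (see above). The clustering benchmark
runs at separation 10 sd with 80 cells per cluster in 6 features; note that
demanding a *perfect* partition at separation exactly 6 sd is statistically
impossible for Gaussian clusters of this size (the per-point Bayes
misassignment rate Φ(−3) ≈ 0.13% already implies ~28% of 240-point data
sets contain at least one straddling point).

What passing these tests does **not** show: the generator's traces are far
cleaner than real recordings (no series-resistance drift, no electrode
artifacts, no overlapping spontaneous activity during steps, no
temperature or pharmacology effects), its phenotypes are archetypal rather
than graded, and its cluster structure is planted rather than discovered.
Recovery rates on synthetic data are upper bounds on real-data performance.

## Liquid junction potential

`henderson_ljp()` implements the generalised-valence Henderson equation

$$V = \frac{RT}{F}\,
  \frac{\sum_i \mathrm{sgn}(z_i)\,u_i\,(c_i^{b} - c_i^{p})}
       {\sum_i |z_i|\,u_i\,(c_i^{b} - c_i^{p})}\,
  \ln\frac{\sum_i |z_i|\,u_i\,c_i^{p}}{\sum_i |z_i|\,u_i\,c_i^{b}}$$

with mobilities represented by limiting equivalent conductivities (bundled
table, user-overridable; gluconate — the value that dominates the result
for potassium-gluconate internals — from the electrophysiology
junction-potential literature). `dissociate_recipe()` dissociates strong
electrolytes fully, gives HEPES its pH-7.3 anion fraction (pKa 7.55),
carries MgATP as Mg²⁺ + MgATP²⁻, treats sugars as neutral, and can add a
titrant cation (KOH) to restore electroneutrality, which is then checked
with 5% slack for unmodelled titrants. The sign convention
(bath − pipette) is positive for potassium-gluconate internals, matching
how the correction is quoted. Agreement with published values is expected
within about 1 mV, not exactly, since the mobility compilation and the
handling of the weak species differ between calculators.

```{r ljp}
as.numeric(kgluconate_acsf_ljp(22))
```

## End-to-end example

```{r cohort, eval = FALSE}
cohort <- simulate_cohort(c("TF", "DF", "GF", "TF", "DF"),
                          identities = c("SPBN", "SPBN", "SPBN", "UN", "UN"),
                          seed = 1)
recs  <- lapply(cohort, extract_cell_features)
tab   <- assemble_feature_table(lapply(recs, `[[`, "features"))
norm  <- minmax_normalize(tab$values)
tree  <- ward_linkage(norm)
sel   <- silhouette_select_k(norm, tree)
report <- build_report(tab,
                       identities = vapply(cohort, `[[`, "", "identity"),
                       calls = vapply(recs, function(r) r$calls$pattern, ""),
                       cluster_labels = cut_tree(tree, max(sel$chosen_k, 2)))
export_dendrogram_newick(tree)
```

## Numerical choices and problem sizes

* Integration: RK4, 0.01 ms internally; simulations blow up loudly (error
  with diagnostics) rather than returning garbage.
* Spike detection: raw-trace centered differences (no smoothing; stable at
  10 kHz), −20 mV peak floor, threshold at the last criterion crossing.
* Ties: a transient peaking at exactly 15.0 ms is a slow A-current; Ward
  merge ties are broken as `stats::hclust` does (documented determinism).
* The validation suites use: 20 seeds per discharge phenotype (full 15-step
  families), 10 seeds per subthreshold class, 6 × 30-s sEPSC trains,
  60 planted feature tables, a 5 × 5 passive grid, and 100 random Ward
  oracle instances — sizes chosen to give stable pass/fail statistics at
  desk scale.

## Known limitations

* The discharge rules are threshold-based operationalisations of a
  qualitative taxonomy; cells near rule boundaries (e.g. a gap-firing cell
  whose pause barely exceeds 3× the median ISI) will flip categories.
* The spontaneous-activity taxonomy thresholds are declared constants, not
  derived from a published criterion set.
* The silhouette selection rule is fragile for sparse or equidistant
  cluster structure (discussed above); the fallback paths and flags make
  this visible rather than silent.
* NWB ingestion is not provided; the documented JSON + CSV bundle layout
  (`write_cell_bundle()` / `read_cell_bundle()`) is the interchange format.
* The Henderson calculation ignores activity coefficients and exact
  (Planck) junction solutions.
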