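---
title: "Methods: models, corrections, and the oscillation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, corrections, and the oscillation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`astroCaSim` is a reimplementation-and-comparison harness for four published
ODE models of single-astrocyte Ca²⁺ excitability. This vignette records the
scientific and numerical decisions behind the package: the model equations
and the corrections we apply, how missing or ambiguous published values were
resolved, the operational definitions behind every oscillation statistic,
and the points where our reconstruction is known to diverge from the
originally reported behavior.

## The models and their assumptions

All four models are deterministic, well-mixed ("point astrocyte") ODE
systems: no spatial Ca²⁺ or IP₃ diffusion, no gap-junction coupling, no
membrane-potential dynamics, no stochastic channel gating. Stimuli enter as
prescribed scalar time courses — a glutamate concentration (µM) for the
evoked models, an IP₃ production rate X_IP₃ (µM/s) for the Riera model.

**Lavrentovich–Hemkin** (`lavrentovich`): three pools (cytosolic Ca²⁺, ER
Ca²⁺, IP₃). CICR is a product of two Hill functions of Ca²⁺ (activation and
inhibition, exponent n = 2.02) and one of IP₃ (m = 2.2), scaled by the ER
gradient; SERCA and PLCδ are Hill functions of Ca²⁺; the ER leak is linear
in the gradient. Spontaneous oscillations arise from the interplay of the
membrane fluxes v_in − k_out·Ca with CICR. Because the model tracks both
sides of the ER membrane without a volume ratio, the identity
d(Ca + Ca_ER)/dt = v_in − k_out·Ca holds exactly, and forcing the membrane
balance to zero (`zero_membrane_flux`) makes Ca + Ca_ER a conserved
quantity — a strong integrator test. The `beta_er` option multiplies the
whole ER balance by an effective cytosol/ER volume ratio (e.g. 35, the
value used in related astrocyte models); with the published parameters this
silences the oscillator, which we keep as an expected outcome rather than
an error.

**Riera** (`riera`): a Li–Rinzel-type receptor model with the gating
fraction h as a state, plus the total free Ca²⁺ concentration as a fourth
variable fed by membrane influx, capacitative Ca²⁺ entry (CCE), and efflux.
The ER concentration is eliminated algebraically,
Ca_ER = (Ca_free − Ca)/c1. As printed, the h equation reads
dh/dt = α_h(1 − h) **+** β_h·h: its right-hand side is positive at h = 1,
so h grows without bound — plainly a typographical sign error, since β_h is
the Ca²⁺-dependent *inactivation* rate. The package defaults to the
corrected dh/dt = α_h(1 − h) − β_h·h (`modified_h`); the original form
remains selectable and is exercised in the test suite as a demonstration
that it escapes the unit interval.

**De Pittà** (`depitta`): Li–Rinzel core (the kernel is exported separately
as `li_rinzel_gates()`) with a constant total free Ca²⁺ of 2 µM, plus an
IP₃ balance with three production/degradation routes: receptor-driven
production saturating in Glu^0.7 with a Ca²⁺-shifted affinity K_γ,
Ca²⁺-activated PLCδ damped by IP₃ itself, and IP₃-3-kinase degradation
(Hill exponent 4 in Ca²⁺) plus linear 5-phosphatase decay. We treat h as
the fraction of *active* (non-inactivated) receptors, as in the Li–Rinzel
original from which the variable is taken.

**Dupont** (`dupont`): an mGlu5R signaling cascade — ligand-bound receptor
dimers (DIM) drive PLC, producing IP₃ and DAG; DAG activates PKC, which
phosphorylates dimers (negative feedback); Ca²⁺ inactivates a receptor
fraction R_i with fourth-order kinetics. Two reconstructions were forced by
typography lost in the source tables:

* `R2 = K_aff · DIM / Glu²` — the only dimensionally consistent reading
  (µM² · µM / µM² = µM). It implies the model is undefined at exactly zero
  glutamate while dimer is present; `rhs_dupont()` raises a domain error
  with the remediation hint to use a small positive baseline (0.002 µM for
  the published "2 nM").
* `DIMP = (R_tot − √(k_di · R2) − 2·R2 − 2·DIM)/2` — reading the lost
  radical as a monomer–dimer equilibrium (monomer = √(k_di·R2), µM) and the
  trailing 2 as the divisor from receptor conservation
  R_tot = monomer + 2·R2 + 2·DIM + 2·DIMP. This parse reproduces the
  expected limiting behavior (DIM = 0 ⇒ R2 = 0, DIMP = R_tot/2) but could
  not be cross-checked against the model's precursor publications here; it
  is the least certain ingredient of the package (see *Known divergences*).

As printed, the Dupont Ca²⁺ balance reads
dCa/dt = v0 + k_i(b1 + IRa) − V_MP·Ca²/(Ca² + K_P²) − k_l·Ca and produces
only nanomolar ripples. The corrected default (`modified_ca`) restores the
store-driving factor of the model's own precursor line,
k_i(b1 + IRa)·(Ca_tot − (α + 1)Ca), which yields the published
large-amplitude oscillations. Dimensional bookkeeping across the two forms:
the printed table gives b1·k_i = 7.5×10⁻⁴ µM/s and k_i = 7.5; in the
corrected equation k_i acts as 7.5 s⁻¹ (the store factor carries the µM)
and b1 = 10⁻⁴ is dimensionless.

## Units and ambiguous printed values

The source tables render compound units with a lost solidus; we adopt the
grammar `1s → s⁻¹`, `µMs → µM·s⁻¹`, `1µMs → µM⁻¹·s⁻¹`, `1µM4s → µM⁻⁴·s⁻¹`,
which is consistent across all four tables and matches the magnitudes of
the upstream literature models (hence k_f = 0.5 s⁻¹, k_deg = 0.08 s⁻¹,
v_M3 = 40 s⁻¹, r̄_5P = 0.04 s⁻¹, k_PLC = 1.25 s⁻¹, k_i+ = 25 µM⁻⁴s⁻¹, …).
Two Riera values remain genuinely ambiguous under this grammar:

* **v_δ**: the printed token admits 0.15 and 0.152 µM/s. The package ships
  0.15 as the default with 0.152 one override away
  (`ca_model("riera", params = list(v_delta = 0.152))`). The choice is
  immaterial in practice: under both values the clamped pulse scenario
  produces the same qualitative picture (sustained ~57-peak Ca²⁺ spiking
  during the X_IP₃ pulse, h confined to ≈0.61–0.79), and the one-by-one
  parameter-substitution results below are unchanged.
* **j_in** is read as 0.065 µM/s.

The two spontaneous models print slightly different Li–Rinzel constants
(d5 = 0.082 vs 0.08234 µM); we keep each model's printed value rather than
harmonizing.

Initial conditions follow the published values where given
(Lavrentovich: 0.1, 1.5, 0.1 µM) and the values recoverable from the
published trajectories otherwise (Riera: Ca 0.09 µM, Ca_free 2 µM, h 0.79,
IP₃ 0.14 µM; De Pittà: Ca 0.09 µM, h 0.78, IP₃ 0.22 µM; Dupont: Ca 0.1 µM,
DAG 0.025 µM, DIM 0.014 µM, IP₃ 0.2 µM, PKC 0.2, R_i 0.9898).

## Stimulus conventions

Pulse trains are high-first: the value is `high` on
[onset + k·period, onset + k·period + duration) and `baseline` elsewhere,
with half-open intervals resolving the boundary deterministically. The
published stimulus descriptions say "alternating" without fixing the phase;
`onset` makes the alternative one flag away. The original description of
the Riera pulse experiment leaves the pre/post-pulse X_IP₃ level ambiguous
(a zero baseline lets h and IP₃ collapse before the pulse; a 0.2 µM/s
baseline keeps them high, matching the published curves), so both are
first-class scenarios (`riera_fig4b_baseline0`, `riera_fig4b_baseline02`).

## Integration

The default solver is lsoda (stiff-capable, adaptive) at rtol 10⁻⁸ and
atol 10⁻¹⁰ µM, sampling every 0.05 s. The originals report stiff solvers;
no tolerances are published, so ours are chosen to pass a convergence gate
with margin: a tenfold tolerance refinement moves every reported Ca²⁺
extremum by far less than 0.1 % (asserted in the test suite), and doubling
the sampling rate does not change detected peak counts. Integration is
restarted at every stimulus discontinuity (`stimulus_breakpoints()`), so no
pulse edge can be stepped over, and the stimulus is evaluated at each
segment's midpoint — it is constant within a segment, and the midpoint
avoids floating-point ambiguity at the edges themselves. While a pulse
train is active the internal step is additionally capped at one tenth of
the shorter pulse phase. States the solver reports in [−atol, 0) are
clipped to zero; anything below −atol aborts the run. A fixed-step forward
Euler mode exists for pedagogy only. Nothing in the integration layer is
random.

## What counts as oscillating

The originals never define "oscillating"; the package uses one operational
definition everywhere (`oscillation_criteria()`):

* A **qualifying peak** is an interior local maximum whose topographic
  prominence reaches max(0.005 µM, 1 % of the variable's range over the
  analysis window) for concentrations, or 1 % of range for dimensionless
  fractions (which live on [0, 1] and get no absolute floor). Every
  threshold is additionally bounded below by a noise floor of 10⁻⁹ so that
  a variable resting at a machine-flat steady state is never classified as
  oscillating on double-precision ripples — the floor sits orders of
  magnitude below any genuine fraction oscillation seen in these models
  (the smallest is ≈0.016) and orders of magnitude above solver round-off
  (≈10⁻¹⁶).
* A variable is **sustained** when at least 3 qualifying peaks fall in the
  final two thirds of the run (the first third absorbs the initial-state
  transient).
* **Cessation** is declared when the trailing peak-free gap exceeds twice
  the mean inter-peak interval; the cessation time is the time of the last
  qualifying peak. A trailing-range criterion ("the trace stays within the
  prominence band after the last peak") turns out to be unusable as
  stated: the segment after the last peak always contains the descent from
  that peak itself, and in the ring-down regimes the decaying sub-threshold
  ripples keep the post-minimum range marginally above the threshold. The
  gap rule is scale-free, matches visual judgment on every scenario we
  inspected, and reproduces the reported cessation times (93.9, 274.9 and
  504.8 s at 8, 4 and 3.8 µM glutamate against the reported "around
  100/300/500 s", all within the stated ±15 %).

Band extraction over a glutamate scan takes the longest contiguous run of
non-all-oscillating levels, ties broken toward lower glutamate.

## The synthetic-trace generator

`make_synthetic_trace()` produces sinusoids, damped sinusoids and constants
(optionally with seeded Gaussian noise) so the metrics can be validated
against closed forms independent of the models: a sinusoid of period T over
[0, L] must yield L/T peaks, and the last qualifying peak of a damped
sinusoid must sit at t* = τ·log(A(1 + e^(−T/2τ))/p) — the prominence-
corrected envelope crossing — to within one period. These fixtures exercise
peak detection, classification and cessation logic, but they are smooth,
single-frequency and noise-free by default; passing them says nothing about
multi-scale or bursting dynamics, which is why the model scenarios
themselves are also under test.

## Scenario durations and problem sizes

The published figures do not print their time axes, so durations are
package decisions, recorded per scenario: 600 s for Lavrentovich, De Pittà
and Dupont conditions (long enough for ≥4 slow Lavrentovich cycles and for
every reported cessation), 1200 s for the Riera pulse scenarios (the
[100, 900) s pulse must end well inside the run). The acceptance script
integrates 600-s runs at 0.05-s output resolution (12 001 samples per
trajectory), 16 levels for the De Pittà threshold scan and 40 for the
Dupont band scan.

## Known divergences and limitations

* **Dupont non-oscillatory band, upper edge.** Our reconstruction yields a
  band of 1.8–3.7 µM, against the reported 1.8–3.4 µM. Between 3.5 and
  3.7 µM, DAG, DIM and IP₃ show only decaying micro-transients (amplitudes
  8×10⁻⁵ – 5×10⁻³ µM, late-window amplitude ratios 0.006–0.1) that fall
  below the 0.005 µM prominence floor — and would be invisible on any
  plot. A purely relative rule does not recover the reported edge either:
  it misclassifies machine-flat steady states throughout the band. We
  attribute the discrepancy to the DIMP/R2 reconstruction above and keep
  the honest 3.7.
* **Simultaneous parameter substitution.** Replacing all six shared
  Lavrentovich parameters by their Riera values at once yields sustained
  ~106-s-period oscillations here, whereas the original comparison reports
  at most one excursion in 600 s; the six one-by-one substitutions do
  reproduce the reported stalling (≤1 qualifying window peak each). No
  defensible re-reading of the printed values removes this divergence, so
  the scenario ships with its observed behavior documented rather than
  forced.
* The frequency-modulation regime of the De Pittà model and comparisons
  against digitized curves from the original figures are out of scope; the
  percent-change engine is instead validated by self-consistency (a run
  re-integrated at tenfold tighter tolerance must agree in every extremum
  to < 0.1 %).
* The models share no validated link to a specific astrocyte subtype; the
  package reproduces and compares their mathematics, it does not arbitrate
  their biology.
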