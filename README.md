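# astroCaSim

Astrocytes respond to synaptic activity not with action potentials but with
cytosolic Ca²⁺ oscillations, driven by IP₃-receptor-mediated Ca²⁺-induced
Ca²⁺ release (CICR) from the endoplasmic reticulum, SERCA pump reuptake, and
plasma-membrane fluxes. Several well-known ODE models describe this
excitability, but they were published with varying completeness — missing
initial conditions, ambiguous units, and in two cases outright sign or
factor errors in the printed equations — and they behave very differently
under one another's stimuli. `astroCaSim` reimplements four of these
single-astrocyte models in one harness so they can be simulated, corrected,
and compared side by side:

| model | type | state variables |
|---|---|---|
| `lavrentovich` | spontaneous | Ca, Ca_ER, IP₃ |
| `riera` | spontaneous, X_IP₃-driven | Ca, total free Ca, h, IP₃ |
| `depitta` | glutamate-evoked (Li–Rinzel core) | Ca, h, IP₃ |
| `dupont` | glutamate-evoked (mGlu5R cascade) | Ca, DAG, DIM, IP₃, PKC, R_i |

The shared machinery is classical: the Li–Rinzel gating kernel

    m_inf = IP3/(IP3 + d1),  n_inf = Ca/(Ca + d5),
    h_inf = Q2/(Q2 + Ca),    tau_h = 1/(a2 (Q2 + Ca)),
    Q2 = d2 (IP3 + d1)/(IP3 + d3)

with CICR flux `r_C m_inf³ n_inf³ h³ (Ca_free − (1+c1) Ca)`, Hill-type SERCA
pumps `V Ca²/(Ca² + K²)`, and Ca²⁺-activated PLCδ IP₃ production. Two
corrected equation variants are the defaults because the originals as
printed cannot reproduce their own published figures:

* **Riera** `modified_h`: dh/dt = α_h(1−h) − β_h·h (the printed `+ β_h h`
  lets the gating fraction escape \[0, 1\]);
* **Dupont** `modified_ca`: the release term carries the store factor
  (Ca_tot − (α+1)·Ca), restoring large-amplitude Ca²⁺ oscillations.

On top of the models sit piecewise-constant stimulus protocols (constant
levels, glutamate pulse trains, the X_IP₃ rate pulse), a stiff adaptive
integrator (deSolve/lsoda) that restarts at every stimulus edge, oscillation
metrics (prominence-based peak detection, period, amplitude, cessation
time), the percent-change statistic `(y − x)/x × 100`, glutamate regime
scans, and a registry of 22 named scenarios covering every comparison
condition.

## Worked example

How quickly does the De Pittà model stop oscillating under a strong
sustained stimulus (the Dupont model's native 8 µM glutamate)?

```r
library(astroCaSim)
traj <- integrate_model(ca_model("depitta"), stimulus_constant(8),
                        t_end = 600)
summary(traj)
#> <oscillation_summary> window [200, 600] s
#>   Ca       --- peaks(win)   0, amplitude 1.196e-05, period 7.58 s, ceased at 93.9 s
#>   h        osc peaks(win)  12, amplitude 1.57e-06, period 7.6 s, ceased at 289.4 s
#>   IP3      --- peaks(win)   0, amplitude 1.134e-05, period 7.48 s, ceased at 92.0 s
```

The Ca²⁺ trace spikes every ~7.6 s and falls silent after 93.9 s — the
"ceased to oscillate around 100 s" regime. Scanning the stimulus shows
where that regime begins:

```r
scan <- glu_scan(ca_model("depitta"), levels = seq(3.0, 4.5, by = 0.1))
cessation_threshold(scan)
#> [1] 3.8
```

Below 3.8 µM the oscillation is sustained for the whole 600 s; from
3.8 µM upward it dies, and the higher the glutamate, the sooner. The
same scan over the corrected Dupont model exposes the opposite pathology —
an interior glutamate band in which most of its six variables sit still:

```r
oscillation_band(glu_scan(ca_model("dupont"), levels = seq(0.1, 4, 0.1)))
#> lower upper
#>   1.8   3.7
```

Every published comparison condition is a named scenario:

```r
list_scenarios()$id
run_scenario("lavrentovich_vm2_5p8", out_dir = "out/")  # CSV + JSON bundle
```

or, from a shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/astrosim simulate depitta_fig12am --out out/ --plot
Rscript inst/cli/astrosim scan dupont --glu-from 0.1 --glu-to 4.0
```

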