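Package: astroCaSim
Title: Simulation and Comparison of Single-Astrocyte Calcium Excitability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements four published ordinary-differential-equation models of
    calcium excitability in single astrocytes: two spontaneous oscillators
    (Lavrentovich-Hemkin and Riera) and two glutamate-evoked models (De Pitta
    and Dupont), together with the corrected equation variants that make the
    Riera and Dupont models reproduce their published behavior. Provides the
    Li-Rinzel IP3-receptor gating kernel and the single-cell Hofer flux
    kernels the models are built from, piecewise-constant glutamate and
    IP3-production stimulus protocols, a stiff adaptive integrator with exact
    handling of stimulus discontinuities, oscillation metrics (peak detection
    with topographic prominence, period, amplitude, cessation time), a
    percent-change comparison engine, glutamate regime scans, and a named
    registry of simulation scenarios for systematic side-by-side comparison
    of the models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
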