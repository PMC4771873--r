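Package: fluxgate
Title: Ion-Flux Gating of Two-Pore-Domain Potassium Channels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative model of selectivity-filter ("check valve") voltage
    gating in two-pore-domain (K2P) potassium channels. Implements Nernst and
    Goldman-Hodgkin-Katz electrochemistry, a four-state filter kinetic scheme
    driven by the electrochemical driving force (Vm - Erev), the linear-field
    decomposition of the equivalent gating charge carried by ions loading into
    the filter, desk-scale trajectory statistics (per-site S1-S4 occupancy and
    permeation-event detection), and the full patch-clamp measurement pipeline:
    exponential time-constant fits, tail-current extraction,
    conductance-voltage curves, Boltzmann gating-charge fits, rectification and
    fold-change statistics, and Hill dose-response fits. Ships calibrated
    channel presets and seeded synthetic-data generators so every stage runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
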