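Package: hscompete
Title: Agent-Based Simulation of Growth-Factor Competition for Heparan
    Sulfate Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic lattice (agent-based) model of angiogenesis
    regulation as competitive binding of three growth-factor affinity
    classes (low, medium, high heparan-sulfate affinity; VEGF-like,
    PDGF-B-like, PF-4/TSP-1-like) to a finite pool of heparan-sulfate
    binding sites on stromal cells, with class-ordered cleavage by a
    stochastically fluctuating per-patch heparinase field. Includes a
    six-event per-step scheduler, a replicate runner with averaged bound
    time series, presets for one-shot release (wound healing) and
    continuous stimulator inflow (tumor) experiments, a qualitative
    pattern classifier distinguishing resolved sequential signaling
    from unresolved stimulation, CSV serialization and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
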