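Package: uniCycle
Title: Nonequilibrium Thermodynamics of Reversible Uni-Uni Enzyme Catalytic Cycles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Steady-state analysis of reversible Michaelis-Menten catalytic
    cycles with two, three, or four enzyme functional states. Computes
    occupancies and net cycle flux by the King-Altman/Hill diagram
    (spanning-tree) method with an independent master-equation oracle,
    thermodynamic step forces, total and partial entropy production,
    Shannon entropy of state occupancies, and the kinetic performance
    parameters kcat, KM and kcat/KM. Ships curated literature parameter
    sets for ten uni-uni enzymes (triosephosphate isomerase, ketosteroid
    isomerase, carbonic anhydrase I/II/T200H, three A-class beta-lactamases,
    beta-galactosidase and glucose isomerase), Box-Muller noise exploration
    of rate-constant space under thermodynamic constraints, deterministic
    stepwise and concentration scans, efficiency-dissipation fitting and
    fold-improvement reports, and a discrete stochastic (agent-based style)
    simulator of the catalytic cycle with strict mass conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'noise.R'
    'steadyState.R'
    'observables.R'
    'exploration.R'
    'registry.R'
    'abm.R'
    'io.R'
    'cli.R'
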