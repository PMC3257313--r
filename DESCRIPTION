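Package: CalvinSim
Title: Kinetic Modeling and Diagnostics for the Calvin-Benson Cycle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for kinetic modeling of the Calvin-Benson cycle and its
    coupling to adjacent carbon metabolism. Provides a reaction-network data
    model with non-integer stoichiometry and element bookkeeping, the special
    rate-law families used in published Calvin-cycle models (transketolase,
    chloroplast phosphate translocator, RuBisCO oxygenase, starch
    phosphorylase, including documented defective variants), stiff ODE
    simulation with steady-state detection and flux matching, a library of
    corrected model variants for cyanobacteria with lumped or explicit
    photorespiration, diagnostic analyses (stability test, energy-charge scan,
    sink-output analysis, sink-implementation comparison, paired-model ratio
    series), and SBML Level 2 import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: SystemsBiology, MetabolicNetworks, Pathways, MathematicalBiology
RoxygenNote: 7.3.3
Collate:
    'parameter-set.R'
    'AllGenerics.R'
    'CalvinSim-package.R'
    'rate-laws.R'
    'model.R'
    'fixtures.R'
    'serialize.R'
    'simulate.R'
    'analyses.R'
    'model-library.R'
    'patches.R'
    'sbml-io.R'
    'run.R'
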