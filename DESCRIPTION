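Package: drumr
Title: Dynamic Reduction of Unbalanced Metabolism (DRUM) Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, reduce and simulate dynamic metabolic models under
    non-balanced growth with the DRUM approach: a metabolic network is split
    into sub-networks assumed individually at quasi-steady state, each
    sub-network is reduced to macroscopic reactions through elementary flux
    mode enumeration, and the macroscopic reactions are assembled into a
    low-dimensional kinetic ODE model in which a chosen set of metabolites
    (storage pools and pathway branch points) is allowed to accumulate.
    Includes parsing and elemental bookkeeping for plain-text reaction
    tables, an exact-arithmetic elementary flux mode engine for sub-network
    scale problems, chemostat simulation under day/night light forcing,
    multistart Nelder-Mead calibration of kinetic rate constants, and a
    packaged day/night carbon-storage model of the microalga Tisochrysis
    lutea together with a synthetic observation generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
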