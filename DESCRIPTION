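Package: p53mdmx
Title: Dynamics of the p53-Mdm2-MdmX DNA-Damage Response Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action kinetic models of the p53-Mdm2-MdmX negative
    feedback network in its simple (14-species) and full (16-species)
    variants, with the DNA-damage, Nutlin and MdmX-pulse simulation
    protocols, switch-like and oscillation-dampening response metrics,
    steady-state continuation and Hopf bifurcation analysis with limit-cycle
    shooting, a two-stage kinetic-parameter-space search driven by
    cross-correlation fitness against oscillation targets, and local
    sensitivity ranking of rate constants. Includes a synthetic-target
    generator emulating published p53 oscillation patterns, Nutlin
    fold-change curves and total-protein ratios so that fitness and search
    are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
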