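Package: agspace
Title: Abundance-Growth Space Analysis of Microbial Community Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compartmentalized community metabolic models from
    single-organism genome-scale models (shared pool compartment,
    abundance-scaled flux bounds, balanced-growth coupling, optional
    biomass-recycling pseudo-reactions), discretizes the space of relative
    abundances and community growth rates, classifies every reaction's flux
    variability range into qualitative plasticity states, partitions and
    clusters the space into metabolic phenotypes, and computes quantitative
    two-reaction flux-coupling envelopes under environmental scenarios
    (substrate availability splits, organic-matter recycling fractions,
    amino-acid supplementation, energy-efficiency constraints). Linear
    programs are solved with a built-in deterministic bounded-variable
    simplex; models are read and written as SBML Level 3 with flux-bound
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
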