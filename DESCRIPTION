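Package: bpatriage
Title: Descriptor Profiling, CNS-MPO Scoring and SAR Triage for
    Benzylphenoxyacetamide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational triage of benzylphenoxyacetamide (BPA) variants as
    anti-glioblastoma drug candidates. Parses and enumerates BPA-family
    structures from SMILES, computes a physicochemical descriptor panel from
    open published contribution schemes (Ertl topological polar surface area,
    Wildman-Crippen logP, Miller additive polarizability, ESOL solubility,
    minimal projection area from a deterministic 3D embedding), scores
    compounds for central nervous system penetrability (six-component CNS-MPO
    desirability score and a linear logBB blood-brain-barrier model), applies
    property-based triage thresholds, performs region-wise matched-pair
    structure-activity analysis with pharmacophore-rule induction, fits
    four-parameter logistic dose-response curves, and generates synthetic
    compound libraries with planted activity rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
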