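Package: molgraft
Title: Fragment-Based Molecular Structure Generation from Interchangeable-Fragment Databases
Version: 0.1.0
Authors@R: person("Maintainer", "Molgraft", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds databases of interchangeable molecular fragments from a
    SMILES corpus by matched-molecular-pair style fragmentation with
    canonicalized radius-r attachment-point contexts, and generates
    chemically valid new structures by MUTATE, GROW and LINK replacements.
    Includes evaluation metrics (Tanimoto novelty and diversity on hashed
    circular fingerprints, corpus novelty, a physicochemical property panel,
    Bemis-Murcko scaffold analysis, SMARTS-based substructure screening,
    synthetic accessibility scoring), stochastic chemical-space exploration
    with molecular-weight binning, and greedy goal-directed optimization
    with adaptive fragment-size windows and three patience levels. The
    molecular toolkit (SMILES parsing, sanitization, canonicalization,
    fingerprints) is self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
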