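Package: drugrules
Title: Drug-Likeness Rule Violation Counters and Random Forest Surrogates for Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic violation counters for Lipinski's Rule of Five, the
    beyond-Rule-of-Five peptide extension, and Muegge's drug-likeness criteria,
    operating on physicochemical descriptors computed from SMILES. Includes a
    descriptor-space sampler and a peptide SMILES assembler for building
    labelled training data, Random Forest classifier and regressor surrogates
    that predict violation counts from descriptors or Morgan-style circular
    fingerprints, multiclass micro-averaged evaluation metrics with pooled
    one-vs-rest ROC curves, and tooling to compare predictions against
    reference violation counts from external platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    ranger,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
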