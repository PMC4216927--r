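Package: affreg
Title: Affinity Regression Linking Signaling Proteins to Transcription Factor Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a bilinear interaction model between upstream signaling
    protein measurements (reverse-phase protein arrays) and downstream
    transcription-factor target-gene sets so that the learned interaction
    matrix explains tumor gene expression. The trained model maps protein
    profiles to inferred transcription-factor activities and expression
    profiles to inferred signaling-protein activities. Downstream tools cover
    cross-validated evaluation against a nearest-neighbor baseline,
    permutation-based subtype association testing with empirical false
    discovery control, elastic-net drug-sensitivity signatures with stability
    selection, and Cox risk stratification with log-rank validation, together
    with a synthetic cohort generator that emulates the statistical structure
    of matched expression/protein tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    survival,
    glmnet,
    mclust,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
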