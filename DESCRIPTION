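Package: ieegfc
Title: Re-Referencing and Functional Connectivity Pipelines for Intracranial EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates intracranial EEG functional-connectivity
    networks under combinations of re-referencing (common average, bipolar)
    and connectivity measures (Pearson, squared Pearson, cross-correlation,
    magnitude-squared coherence, phase locking value, relative entropy)
    across seven canonical frequency bands. Provides signal cleaning
    (notch and band-pass filtering, artifact channel rejection, epoch
    selection), montage algebra, the 48-pipeline suite, edge-wise pipeline
    similarity with hierarchical clustering and bootstrap stability,
    node-strength reliability under channel subsampling, a common-reference
    spurious-correlation simulator, seizure-onset-zone lateralization
    statistics, and a seed-reproducible synthetic cohort generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Electrophysiology, Network, Preprocessing
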