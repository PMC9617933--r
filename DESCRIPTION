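Package: dbsteer
Title: Algorithm-Guided Programming of Directional Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("dbsteer", "maintainers", email = "dbsteer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for iterative, algorithm-guided programming (AgP) of
    directional deep brain stimulation leads. Models the 8-electrode
    (1-3-3-1) segmented lead and maps continuous stimulation-space
    coordinates (vertical position, rotation angle, amplitude) to electrode
    current fractionalizations; combines multiple 0-4 symptom scores into a
    total weighted score; maintains inverse-distance-weighted score maps
    with side-effect amplitude boundaries; runs a two-stage (ring, then
    directional) explore-then-exploit optimization loop with a
    distance-threshold convergence rule; quantifies similarity between
    stimulation settings via amplitude ratio, normalized electrode
    configuration distance, a simplified voxel volume-of-tissue-activated
    model with Jaccard overlap, and score similarity; and generates
    synthetic in-silico patients so that the full programming loop can be
    exercised and validated without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
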