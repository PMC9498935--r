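Package: streamseg
Title: Simulation and Analysis of Feature-Based Auditory Stream Segregation
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-experiment auditory streaming study design: parametric
    difficulty ladders for intensity, spectral-envelope and temporal-envelope cues;
    an adaptive deviant-detection task with signal-detection (d-prime) scoring;
    synthetic observers with known ground truth for both the detection task and
    pairwise dissimilarity ratings; SMACOF multidimensional scaling with
    bootstrap confidence ellipsoids and procrustean alignment to a physical
    reference space; regression of perceptual dimensions on physical features and
    remapping of task difficulty onto a common dissimilarity scale; and the
    study's inferential toolkit (mixed-effects omnibus models, Bonferroni pairwise
    comparisons, and a two-one-sided-tests equivalence procedure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
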