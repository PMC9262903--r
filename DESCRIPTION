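Package: flowgaze
Title: Simulation and Scoring of Gaze Responses to Radial Optic Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developmental eye-tracking studies of radial optic
    flow. Generates expansion/contraction random-dot flow stimuli with a
    translating focus of expansion, scores 60 Hz gaze streams against a
    moving circular area of interest (looking time, first-entry latency,
    whole-screen looking time, expansion/contraction asymmetry index,
    analytic chance levels), simulates synthetic gaze cohorts across age
    groups with controllable expansion/contraction bias, and runs the
    group-level inferential stage: factorial linear mixed-effects ANOVAs
    with Kenward-Roger or Satterthwaite degrees of freedom, simple effects
    via least-squares means, Bonferroni-corrected pairwise post hocs, and
    one-sample tests on the asymmetry index.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
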