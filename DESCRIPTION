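Package: eagmdbn
Title: Bidirectional Dynamic Bayesian Network for Collaborative Assessment
    of Embodied Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a bidirectional discrete Dynamic Bayesian Network over
    a four-layer nested task representation (Environment, Activity, Goals,
    Meaning) with cross-layer "c4" edges.  A top-down pass predicts the
    expert's orientation (current goal and interpretation) and drives an
    information-seeking probe-action policy; a bottom-up pass symbolizes
    action-conditioned observations and filters candidate edges through a
    three-gate pipeline (compatibility, coherence, observability) with
    refinement, an error list, and a confidence-plus-expert validation gate.
    Hierarchical prefix-count histograms with Dirichlet smoothing supply the
    coherence prior.  The network is instantiated for ARAT-style upper-limb
    rehabilitation assessment: span-consistent segmentation decoding,
    cumulative-logit ordinal segment and exercise ratings, binary movement
    quality elements, logit-space prediction fusion, and 0-57 session
    scoring.  A seeded synthetic-data module generates planted networks and
    session streams with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
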