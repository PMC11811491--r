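Package: senadapt
Title: Adaptive Social-Engagement Intervention Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and learning engine for adaptive social-skill
    interventions in children with autism spectrum disorder. Implements
    attention-weighted engagement scoring over behavioral cues, a gated
    latent interaction-state model with decaying memory, a dynamic state
    transition mechanism with regularized least-squares fitting, a
    discounted reward stack, a tabular temporal-difference intervention
    policy with epsilon-greedy exploration, confidence-based intervention
    frequency and intensity adjustment, and a seeded synthetic cohort
    simulator with known ground-truth effects for policy evaluation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
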