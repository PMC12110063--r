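Package: vipassim
Title: Agent-Based Simulation of Attentional Dynamics in Focused-Attention Meditation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates focused-attention (Vipassana-style) meditation as a
    three-level agent-based dynamical system. Five competing attentional
    agents ("thoughtseeds") drive four emergent meditation states
    (breath_control, mind_wandering, meta_awareness, redirect_breath) under
    winner-takes-all dominance and state-dependent meta-awareness regulation.
    Provides a rule-based training phase that learns a state-transition matrix
    and state-conditioned weight matrix over a simulated session, pairwise
    lagged Granger-causality extraction of the signed thoughtseed interaction
    network, a trained-model simulator with momentum dynamics, and analytics
    for dwell times, activation bands, and novice/expert contrasts, with
    reproducible seeded runs and a small command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
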