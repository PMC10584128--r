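Package: pdsched
Title: Individualized Levodopa Intake Schedules for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A framework for building individualized oral levodopa/carbidopa
    intake schedules for Parkinson's disease patients. Provides a
    compartmental PK/PD virtual-patient simulator with a sigmoid-Emax effect
    law on the Treatment Response Scale (TRS), synthetic medication-day
    generation, neural patient-response models (a feed-forward "history"
    model and a recurrent LSTM "impulse" model) trained by whole-day rollout
    with transfer learning to individual patients, constrained schedule
    optimization by genetic algorithm, differential evolution and exhaustive
    search, and a reinforcement-learning dosing environment with a PPO
    trainer. All components are testable on synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
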