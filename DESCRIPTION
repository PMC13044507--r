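Package: lapsenet
Title: Personalized Adherence-Lapse Prediction with Source-Free Domain Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts day-level adherence lapses in computerized cognitive
    training from the previous week's engagement features (play duration,
    session count, maximum level, tasks completed) using small personalized
    1D convolutional networks. Implements the full experimental pipeline:
    a synthetic multi-study cohort simulator with habit-formation dynamics
    and controllable between-study domain shift, sliding-window dataset
    preparation with chronological splits, supervised source training and
    target-study fine-tuning, source-free adaptation of the fine-tuned model
    to each target participant by local structure clustering over nearest
    neighbors in feature space, and evaluation that compares the adapted
    models against per-participant no-source baselines with paired one-tailed
    t and Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
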