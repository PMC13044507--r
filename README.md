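# lapsenet

Day-level adherence lapses — days on which a participant in a computerized
cognitive-training program fails to reach the prescribed engagement dose —
are predictable from the previous week's play behavior, and predicting them
a day ahead creates a window for just-in-time support. `lapsenet` implements
a complete, reproducible pipeline for studying this problem when each
participant contributes only a short labeled history (30 days) and raw data
cannot be shared across clinical studies:

* **Personalized 1D-CNN classifiers.** For each participant, a small
  convolutional network maps the previous *N* = 7 days of four engagement
  features — play duration (min), session count, maximum level achieved,
  tasks completed — to the probability that day *N* + 1 is adherent
  (play duration ≥ 10 min). The architecture is two convolutional blocks
  (valid 1D convolution + ReLU + max pooling), a linear feature layer, and a
  2-class output head.
* **Source-free domain adaptation (SFDA) by local structure clustering
  (LSC).** Privacy constraints allow only a *model* trained on another study
  to cross the study boundary, never records. The source model is fine-tuned
  on the target study excluding the target participant, then adapted to that
  participant *without labels*: memory banks cache L2-normalized extractor
  features and soft predictions of the participant's windows; each step
  minimizes
  `L = -(1/B) Σ_i Σ_{k∈N_i} p_i·p_k + λ Σ_c m_c log m_c`,
  pulling every window's prediction toward its K nearest neighbors in
  feature space while the marginal-entropy term prevents collapse to a
  single class.
* **A no-source baseline and paired inference.** The comparison arm trains
  each personalized model from scratch on the participant's own ~19 retained
  training windows. Arms are scored per participant (accuracy, precision,
  recall, F1 on identical test windows), averaged unweighted across
  participants, and compared with a one-tailed paired *t* test and the
  Wilcoxon signed-rank test.
* **A synthetic multi-study cohort generator.** The clinical datasets this
  design targets are private, so the package ships a generative stand-in:
  a latent AR(1) habit process on the logit scale with day-of-week structure
  and slow drift drives Bernoulli adherence; activity magnitudes follow
  log-normal/Poisson models; three-study benchmarks with controllable
  between-study distribution shift are built with `make_benchmark_suite()`.

## Worked example

```r
library(lapsenet)

suite <- make_benchmark_suite(master_seed = 1, shift_strength = 1)
exp_ab <- run_experiment(suite, source = "A", target = "B", seed = 1)
exp_ab
#> Source A -> target B (24 target participants)
#>   no_source  accuracy 0.529 (0.213)  precision 0.426 (0.370)  recall 0.264 (0.328)  f1 0.235 (0.249)
#>   finetuned  accuracy 0.686 (0.171)  precision 0.540 (0.296)  recall 0.547 (0.313)  f1 0.525 (0.285)
#>   sfda       accuracy 0.681 (0.152)  precision 0.546 (0.285)  recall 0.594 (0.310)  f1 0.544 (0.267)
#>   SFDA vs no-source accuracy: mean gain +0.151, t = 3.325 (p = 0.001474), Wilcoxon W- = 29.5 (p = 0.001458)
```

Read: with 24 synthetic target participants, models trained on each
participant's own 30 days alone average 52.9% test accuracy; transferring a
source-study model (fine-tuned on the rest of the target study, then adapted
source-free to the participant) raises the average to 68.1%, a paired gain
of 15.1 points that both paired tests call significant (p ≈ 0.0015). The
`finetuned` row is the fine-tuned-but-unadapted model, kept as a
diagnostic. `plot(exp_ab)` draws the per-participant paired accuracies.

Lower-level entry points: `simulate_study()` / `simulate_participant()` for
data generation, `make_windows()` for labeling and splits,
`train_source_model()`, `finetune_on_target_study()`,
`train_no_source_baseline()` for the training tiers, and
`adapt_to_participant()` for LSC adaptation of a checkpoint.

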