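# tapcrnn

Automatic recognition of holosystolic murmurs — the hallmark of a
ventricular septal defect (VSD) — in phonocardiogram (PCG) recordings,
using a convolutional recurrent neural network with **temporal attentive
pooling** (TAP-CRNN), together with CNN and CRNN baselines, the full
evaluation protocol (subject-exclusive 70/30 split, fourfold
cross-validation, per-auscultation-site breakdown), and a seeded synthetic
phonocardiogram simulator so everything is testable without clinical data.

The package is aimed at researchers in biomedical audio / computer-aided
auscultation who want a transparent, dependency-light reference
implementation: the networks (convolutions, LSTMs, attention, dense head,
Adam, backpropagation) are written directly in R on BLAS matrix
operations, with every gradient verified against finite differences in the
test suite.

## The model

Each 10-second clip is transformed by an STFT (frame length 512, shift
256) into `N` frames of 257-dimensional log-power features
`X = [x(1), ..., x(N)]`. Convolutional layers produce per-frame features
`y(n)`; stacked LSTM layers produce the final recurrent state `h(N)`.
Temporal attentive pooling then weighs the frames twice:

    c(n)            = [W_c y(n); W_r h(N)]
    alpha_global(n) = softmax_n( u' tanh(c(n) + b_global) )
    z(n)            = alpha_global(n) y(n)
    beta_local(n)   = softmax_n( v' tanh(W_l z(n) + b_l) )
    f_hat           = (1/N) * sum_n alpha_global(n) beta_local(n) y(n)

and the dense head classifies `s = [f_hat; W_g h(N)]` through tanh layers
and a softmax (murmur vs normal). The per-frame product
`EPL(n) = alpha_global(n) beta_local(n)` — the *event presence
likelihood* — shows where in time the model pools its evidence.
Performance is reported as accuracy, sensitivity, specificity, PPV, NPV
(murmur = positive class) and the ROC/AUC of the murmur posterior.

## Worked example

```r
library(tapcrnn)

# a seeded synthetic cohort: 8 VSD-like and 8 normal subjects,
# 2 clips at each of the 5 auscultation sites
cohort <- synthesizeCohort(8, 8, 2, synthConfig(seed = 42, murmurSnrDb = 10))

# desk-scale TAP-CRNN (reduced widths; modelConfig("tap_crnn") is full-size)
config <- modelConfig("tap_crnn",
    convSpec = list(c(2L, 1L, 4L), c(2L, 1L, 4L)),
    rnnSpec = c(24L, 24L), denseSpec = c(24L, 24L))

plan <- splitTrainTest(cohort$manifest, 0.7, seed = 1)
trIdx <- which(cohort$manifest$subject_id %in% plan$trainSubjects)
teIdx <- which(cohort$manifest$subject_id %in% plan$testSubjects)

features <- clipFeatures(cohort$clips, config)
fit <- trainModel(features[trIdx], cohort$manifest$label[trIdx], config,
                  epochs = 8, seed = 1)
ev <- evaluateModel(fit$weights, features[teIdx],
                    cohort$manifest$label[teIdx],
                    sites = cohort$manifest$site[teIdx])
round(ev$metrics, 1)
#>    accuracy sensitivity specificity         ppv         npv
#>         100         100         100         100         100
ev$auc
#> [1] 1
```

At the default +10 dB murmur-to-background SNR the synthetic task is
cleanly separable, so a correctly working pipeline reaches perfect
held-out metrics; at 0 dB the classes genuinely overlap and accuracies
drop into the 85–100% range depending on architecture and seed. The
attention trace of a clip comes from `extractEpl(fit$weights, clip)` and
can be written/plotted with `writeEplTrace()` / `plotEpl()`.

A command-line interface wrapping the same functions ships in
`inst/scripts/tapcrnn-cli.R`:

```sh
Rscript inst/scripts/tapcrnn-cli.R synth --seed 1 --out data/
Rscript inst/scripts/tapcrnn-cli.R train --data data/ --out run/
Rscript inst/scripts/tapcrnn-cli.R eval  --data data/ --checkpoint run/checkpoint.rds --out eval/
```

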