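# dalan

Patient-level deep Cox survival modelling from bags of lesion images.

## The problem

In imaging-based survival analysis a patient often contributes *several*
region-of-interest (ROI) images — multiple lesions, multiple slides —
while the survival label (observed time `Y = min(T, C)`, event indicator
`δ`) belongs to the patient. Image-wise deep Cox models emit one hazard
per image and leave patient-level aggregation to a post-hoc rule
(average / min / max / median of the ROI hazards). **dalan** implements a
learned alternative: a deep attention-LSTM aggregation network (DALAN)
that encodes every ROI with a weight-shared CNN, aggregates the embedding
sequence through two attention-LSTM blocks (multi-head self-attention,
then co-attention whose query is the raw embedding sequence), and emits a
single patient-level log-hazard from an MLP Cox head.

All models minimise the negative Cox partial log-likelihood

```
l(θ) = − Σ_{i∈U} [ h_θ(x_i) − log Σ_{j∈R_i} exp(h_θ(x_j)) ],
```

with `U` the uncensored subjects and risk sets `R_i = {j : Y_j ≥ Y_i}`
formed within each minibatch, and are evaluated with the concordance
index over admissible pairs. The package also provides:

* the naive aggregation baselines (same encoder, same training budget, so
  comparisons isolate the aggregation rule);
* an image-conditioned survival simulator: an ROI with pixels `I` gets
  latent time `T = exp(mean(I ⊙ M) + 0.001 ε)`, `ε ~ Lognormal(0,1)`,
  where the uniform pixel-weight mask `M` is drawn once per replicate;
  patient time is the mean over ROIs, followed by 50% random censoring
  and an 80/20 split. Procedural "digit-like" and "texture" image
  generators make the benchmark fully self-contained;
* survival utilities: Kaplan-Meier curves, log-rank tests, risk
  normalization, tertile stratification, and rank-based covariate
  reports;
* experiment drivers (`runComparison()`, `runAblation()`) with
  deterministic per-replicate seeding, and a thin CLI
  (`inst/scripts/dalan-cli.R`).

The neural layers (im2col convolution, multi-head scaled-dot-product
attention, stacked LSTM, AdamW, gradient clipping) are implemented in
base R with exact analytic gradients, verified in the test suite against
finite differences and a naive direct convolution.

## Worked example

Simulate a two-ROI cohort, run the two-stage training, and inspect the
patient-level results:

```r
library(dalan)
set.seed(42)

cfg <- simulationConfig("two_roi_digit", nPatients = 120, seed = 42)
cohort <- buildSimulation(cfg)
cohort
#> BagCohort (two_roi_digit): 120 patients (96 train / 24 test), 240 ROIs total

enc <- encoderConfig("small_cnn", embeddingDim = 64,
                     inputShape = c(28, 28, 1), channels = c(8, 16, 32))
roiModel <- fineTuneRoiLevel(enc, trainBags(cohort),
                             trainingProfile("desk")$stage1)

dalanCfg <- dalanConfig(encoder = enc, nHeads = 4, bagSampleSize = 10)
model <- trainDalan(initDalan(dalanCfg, roiModel), trainBags(cohort),
                    trainingProfile("desk")$bag)
model
#> DalanModel: 177601 parameters (small_cnn encoder, 4-head attention, 2-layer LSTM)
#>   trained 30 epoch(s); final loss 0.9411

pred <- predictRisk(model, testBags(cohort), seed = 1)
outcome <- survivalData(cohort)
test <- outcome[outcome$split == "test", ]
concordanceIndex(pred$log_hazard, test$time, test$event)
#> [1] 0.9558824

evaluateBaseline(roiModel, testBags(cohort), "average")
#> [1] 0.9705882

predAll <- predictRisk(model, bags(cohort), seed = 1)
riskGroupReport(predAll$log_hazard, outcome$time, outcome$event)
#> Risk-group report (tertiles of normalized risk):
#>   low  n =  40, median survival 1.107
#>   mid  n =  40, median survival 1.093
#>   high n =  40, median survival 1.081
#>   log-rank chi-square = 93.023 (df 2), p = 6.31e-21
```

The test c-index says the trained model orders the 24 held-out patients
almost perfectly by risk; the report shows the risk tertiles separate the
cohort's survival sharply (simulated times live on a narrow scale, so the
median gaps are small but the log-rank separation is decisive). On a
single small split the average-aggregation baseline can edge out DALAN,
as here — single-split c-indices at n = 24 are noisy. The systematic
comparison is the replicated one: `runComparison()` over five replicates
of 500 patients, where DALAN's mean test c-index exceeds every naive
rule (see below).

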