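---
title: "Patient-level deep Cox survival modelling from lesion image bags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-level deep Cox survival modelling from lesion image bags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In histopathology-based survival analysis a patient rarely contributes a
single image. A glioma patient, for instance, may have several curated
regions of interest (ROIs) cut from one or more whole-slide images, while
the survival label -- observed time $Y_i = \min(T_i, C_i)$ and event
indicator $\delta_i$ -- attaches to the *patient*, not to any individual
image. Deep Cox models that score one image at a time therefore emit
several hazard predictions per patient and leave the aggregation to an
ad-hoc post-processing step (averaging, taking the extreme, or the median
of the ROI-level hazards).

This package implements a learned alternative: a deep attention-LSTM
aggregation network (DALAN) that performs feature extraction and
aggregation inside one model, emitting a single patient-level log-hazard.
It also ships the naive aggregation baselines, a fully synthetic
image-conditioned survival simulator used to benchmark them, and the
survival machinery (partial-likelihood loss, concordance index,
Kaplan-Meier curves, log-rank tests, risk-tertile reports) that the
experiments need.

## Model

### Survival head

All models are Cox-style: the network output $\hat h_\theta(x_i)$ is a log
relative hazard, trained by minimising the negative partial
log-likelihood

$$\ell(\theta) \;=\; -\sum_{i \in U}\Big(\hat h_\theta(x_i) -
\log \sum_{j \in R_i} e^{\hat h_\theta(x_j)}\Big),$$

with $U$ the uncensored subjects and $R_i = \{j : Y_j \ge Y_i\}$ the risk
set. Three conventions in `coxPartialLikelihood()` deserve a note:

* **Tied times.** $R_i$ includes subjects with $Y_j = Y_i$
  (Breslow-style). This is asserted by tests against hand-expanded
  two-sample forms.
* **Reduction.** The sum over events is divided by $|U|$ by default so
  that minibatch size does not rescale gradient magnitudes; the raw sum is
  available with `reduction = "sum"`.
* **Stability.** The log-sum-exp is always computed with max
  subtraction; shift-invariance of the loss holds to $10^{-9}$ relative.

Minibatches that contain no event contribute nothing and are skipped with
a warning. Risk sets are formed *within* each minibatch, the standard
practice for stochastic deep Cox training.

### Concordance

`concordanceIndex()` implements the pairwise definition literally: over
admissible pairs (uncensored $i$, any $j$ with $Y_j > Y_i$) it counts the
pairs where the predicted survival ordering is strict and correct. Under
this strict-inequality reading a tied prediction earns 0; because most
survival software scores ties 0.5, a `ties = "half"` variant is provided
and cross-checked against `survival::concordance()`. The strict form is
the default and is what every number in this package reports.

### Architecture

Per patient bag:

1. `bagSampleSize` (default 10) ROIs are sampled **with replacement**,
   augmented (training only) and shuffled; sampling with replacement lets
   bags of any size, including bags smaller than 10, fill the input
   sequence.
2. A **weight-shared CNN** maps each ROI to an embedding (256-d at paper
   scale). Two backbones exist: `small_cnn` (three stride-2 3x3
   convolution blocks, global average pooling, linear projection) and
   `residual_cnn` (a stem plus two residual blocks for larger inputs).
   There is no framework dependency: convolution is im2col + GEMM with
   exact analytic gradients, verified against a naive direct convolution
   and finite differences.
3. **Block 1 (self-attention):** 4-head scaled dot-product attention over
   the embedding sequence, then a 2-stacked LSTM.
4. **Block 2 (co-attention):** attention whose *query* is the original
   CNN embedding sequence and whose keys/values are block 1's output,
   then a second 2-stacked LSTM. The query wiring is the natural reading
   of "uses the visual lesion embeddings as the query"; it is a config
   choice, not hard-wired.
5. The final LSTM hidden state (default; mean-pooling over the sequence
   is the config alternative `summary = "mean"`) passes through an MLP
   whose last linear layer emits the scalar log-hazard.

Attention scores are scaled by $\sqrt d$ (head width $d$), the standard
convention; the literal division by $d$ that sometimes appears in print
is available via `scaleMode = "linear"`. Both are exposed because the
choice measurably changes the softmax temperature.

At inference the log-hazard is averaged over `inferenceDraws` (default 8)
independent ROI samplings, which suppresses the sampling noise of step 1;
a fixed seed makes predictions reproducible.

### Two-stage training

Stage 1 (`fineTuneRoiLevel()`) trains the encoder plus a temporary scalar
Cox head on ROI-level data in which every ROI inherits its patient's
$(Y, \delta)$. After stage 1 the front half of the encoder's parameter
groups is frozen. "Half of the front layers" is ambiguous for any real
backbone; this package defines it as the first
$\lfloor \texttt{frozenFraction} \cdot G \rfloor$ of the $G$ parameter
groups in forward order, with `frozenFraction` configurable (0.5
default). Stage 2 (`trainDalan()`) trains the aggregation network with
the frozen trunk, AdamW (decoupled weight decay), global-norm gradient
clipping at 1.0 (a standard value; none is dictated by the protocol), and
optional per-epoch exponential learning-rate decay.

The naive baselines reuse the *same* encoder architecture and stage-1
training budget, so comparisons isolate the aggregation rule. At baseline
evaluation every ROI of a bag is scored (no sampling) and the patient
risk is the mean / min / max / median of the ROI log-hazards.

## The simulator

`buildSimulation()` creates fully synthetic cohorts in which the image
content *determines* survival:

* A weight mask $M$ with i.i.d. $\mathrm{Uniform}(0,1)$ entries is drawn
  **once per replicate** and shared by all ROIs. An ROI with pixels $I$
  gets the latent survival time
  $T = \exp\big(\mathrm{mean}(I \odot M) + 0.001\,\varepsilon\big)$ with
  $\varepsilon \sim \mathrm{Lognormal}(0,1)$, and a patient's true time is
  the arithmetic mean of its ROI times.
* Sharing one mask per replicate is a deliberate reading of "a random
  uniform weight": with an independent mask per ROI the times would be
  noise with respect to the images and no method could learn anything. A
  `maskPerRoi` switch exists for exactly that ablation.
* **Censoring:** exactly $\lfloor n/2 \rfloor$ subjects (configurable
  fraction) are chosen without replacement; a censored subject observes
  $C \sim \mathrm{Uniform}(0, T)$. The protocol says only "randomly
  censored"; the uniform law is this package's choice and is documented
  here so it can be criticised.
* **Split:** 80/20 at the patient level, disjoint by construction.

Two designs are built in. The *two-ROI digit design* gives each patient
one "zero-like" and one "six-like" 28x28 grayscale image; these are
procedurally drawn rings and tailed rings (`synthDigitImages()`) with
randomized radius, stroke width, jitter and noise -- synthetic stand-ins
for handwritten digits so that no dataset download is needed. The classes
differ in expected total ink, which is what creates class-linked survival
signal through the weighted mean; a calibration test asserts the
difference is rank-sum-detectable at $p < 0.01$. The *multi-ROI texture
design* gives each patient several three-channel smooth random-field
images whose per-image brightness spans a wide range
(`synthTextureImages()`), emulating heterogeneous tissue tiles.

What the generator does **not** emulate: real histology morphology, stain
variation, spatial correlation between ROIs of one patient, informative
censoring, and nonlinear (non-monotone) links between image content and
hazard. Passing the simulation benchmarks therefore demonstrates that the
architecture can learn and aggregate an image-determined risk signal
under heavy label noise from censoring -- not that it transfers to
clinical data.

## Training profiles and the desk scale

`trainingProfile()` bundles three named profiles. `sim_digit` (bag stage:
100 epochs, lr 5e-5, weight decay 1e-3, batch 32, decay 0.995) and
`histology` (50 epochs, lr 1e-6, weight decay 1e-2, batch 32) reproduce
the full-scale published protocols, with the shared stage-1 setting of 30
epochs, lr 1e-5, weight decay 1e-6, batch 64. The `desk` profile is this
package's scaled-down testing condition: `small_cnn` with channels
(8, 16, 32) and 64-d embeddings, stage 1 of 20 epochs at lr 1e-3, bag
stage of 30 epochs at lr 1e-3 / weight decay 1e-4. The learning rate is
three orders larger than the full-scale profiles because the desk network
is four orders smaller and trains from scratch rather than from
pretrained weights; 30 epochs suffice for convergence at this size. The
bundled experiments and the test suite run 5 replicates of 500 patients
under this profile; the ablation driver (`runAblation()`) uses the same
protocol and is exercised at small scale in the tests.

A full-scale ImageNet-pretrained 50-layer residual network is outside
this package's scope (it would require external weight files); the
`residual_cnn` backbone provides the deeper-encoder configuration point
for larger inputs, trained from scratch.

## Numerical choices

* Weight initialisation is He-style fan-in scaling; LSTM forget-gate
  biases start at 1.
* All randomness flows through R's RNG, so a single `set.seed()` makes
  simulation, training and inference bit-reproducible on CPU; mask
  generation and prediction take explicit seeds and restore the caller's
  RNG state.
* Tertile stratification resolves ties at a cut point by stable sort
  order (`rank(..., ties.method = "first")`): deterministic, and group
  sizes differ by at most one in the absence of ties.
* The Kaplan-Meier median is the first observed time with
  $\hat S(t) \le 0.5$, `NA` when never reached.
* Per-replicate seeds derive from the master seed as
  `master * 10000 + replicate + 1000 * stage (mod 2^31 - 1)`, recorded in
  every result row together with a config fingerprint.

## Known limitations

* Right censoring only; no interval censoring, time-varying covariates or
  competing risks.
* The CPU implementation is practical at the desk scale (minutes per
  replicate) but not at 256x256x3 histology scale with 20 replicates.
* Baseline and DALAN arms share stage-1 weights within a replicate; this
  mirrors the comparison's intent (isolate aggregation) but means the
  arms are not statistically independent across methods.
* The strict-inequality concordance is not defined when predictions are
  all tied; the reported value is then 0, which is the literal reading
  but arguably harsh -- use `ties = "half"` for comparability with other
  software.
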