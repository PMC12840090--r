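---
title: "Multiscale spatial-temporal EEG networks for depression screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale spatial-temporal EEG networks for depression screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseegnet)
```

## The problem

Resting-state EEG carries spectral signatures that differ between healthy
controls (HC, label 0) and people with Major Depressive Disorder (MDD,
label 1), most prominently in the gamma band (30--100 Hz). `mseegnet`
implements a compact convolutional classifier for this binary screening
problem, together with the protocol pieces that make such a claim
trustworthy: subject-level cross-validation, sliding-window augmentation, an
ensemble-like voting rule over sub-trials, frequency-band ablation, and a
correlation-based interpretability analysis. A trial is an $m \times n$
matrix: $m$ electrodes by $n = \mathrm{SR} \cdot T$ samples, 2-s windows by
default.

## The architecture

The network $f(x;\theta)$ composes five mappings:

1. **Hemispheric integration.** One spatial kernel per hemisphere spans all
   of that hemisphere's channels ($m_r \times 1$ and $m_l \times 1$, "valid"
   across channels), collapsing the montage to a 2-row signal. Channels must
   therefore be ordered right block then left block.
2. **Spatial analysis.** $F_1 = 8$ spatial filters of extent $2 \times 1$
   fuse the two hemispheric rows into $F_1$ temporal feature channels,
   followed by activation and group normalization.
3. **Multiscale temporal bank.** Three parallel depthwise temporal
   convolutions with kernels $S_1 = \lfloor\mathrm{SR}/2\rfloor$,
   $S_2 = \lfloor\mathrm{SR}/4\rfloor$, $S_3 = \lfloor\mathrm{SR}/8\rfloor$
   and depth multiplier $D = 2$, each activation + batch normalization,
   concatenated in scale order (this fixes the feature indexing used by the
   interpretability module) and average-pooled by 4.
4. **High-level feature learning.** Two separable blocks (depthwise kernel
   $S_3$, then pointwise), widths $48 \to 96 \to 96$ and $96 \to 192 \to 48$
   under the defaults, plus an unconditional pointwise projection skip
   ($48 \to 48$, no normalization) added elementwise; global average pooling
   yields the 48 learned features.
5. **Classifier.** A fully connected layer to 2 units and a softmax.

Under the default configuration (16+16 channels, 250 Hz, 2-s windows) the
model has exactly 34,812 learnable parameters; `count_parameters()` verifies
architectural closed forms against an exhaustive enumeration of the built
parameter containers on every call and errors on any disagreement.

```{r}
model <- mseegnet(mseegnet_config(), seed = 1)
summary(model)
```

### Design choices in the architecture

Several points were genuinely open and were fixed as follows.

* **Spatial filter extent.** The spatial-analysis filters span the 2
  hemispheric rows (extent $2 \times 1$). This is the only extent consistent
  with the layer's 40 learnable parameters
  ($8 \cdot 2$ weights $+ 8$ biases $+ 2 \cdot 8$ affine terms).
* **Length-preserving padding.** Temporal convolutions pad with $K-1$ zeros
  split evenly; even kernels put the extra zero on the right. This keeps the
  temporal length through every convolution and makes the layer geometry
  deterministic.
* **Activation/normalization order.** Layers compose as convolution →
  activation → normalization by default (`norm_after_activation = TRUE`);
  the conventional order is available as a flag. Parameter counts are
  unaffected.
* **Group count.** Group normalization defaults to a single group (any
  divisor of $F_1$ yields identical parameter counts); the affine terms are
  always per channel, so all three normalization kinds carry $2C$ learnable
  parameters, and running statistics of batch normalization are not counted
  as learnable.
* **Skip projection.** The pointwise skip is applied unconditionally, with
  2,352 parameters and no normalization.
* **Initialization.** Glorot-uniform weights, zero biases, unit/zero
  normalization affine, from a caller-supplied seed. Two forward passes with
  the same parameters are bitwise identical in evaluation mode.
* **Depth multiplier.** $D$ multiplies the output maps of every depthwise
  convolution; this reading reproduces all per-layer counts simultaneously.

## Training

Training minimizes cross-entropy plus an L2 penalty $\lambda\|\theta\|^2$
($\lambda = 10^{-4}$, applied to all parameters, gradient $2\lambda\theta$)
with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\alpha = 10^{-3}$,
$\varepsilon = 10^{-8}$, bias-corrected moments). The learning rate drops by
a factor of 0.1 every `lr_drop_period_epochs` (default 10 -- one drop inside
the default 25-epoch budget); validation loss is checked once per epoch, and
training stops after `validation_patience = 5` epochs without improvement,
restoring the parameters (and normalization statistics) of the best
validation epoch -- the standard pairing with a patience rule. The default
batch size is 4 x SR (1000 at 250 Hz), overridable for desk-scale runs. A
single Adam step is unit-tested against the scalar closed form, and the full
backward pass is finite-difference-checked across all activation and
normalization variants.

The forward/backward passes are written in R with C++ kernels (via Rcpp) for
the depthwise temporal convolutions, the channel-mixing (pointwise/spatial)
convolutions as BLAS `dgemm`, and a fused ReLU+normalization fast path for
the default recipe; the generic R implementation covers every other
activation/normalization combination and serves as the reference in the
gradient tests.

## Evaluation protocol

* **Cross-subject cross-validation (CS-CV).** Classes are first balanced by
  seeded downsampling of the majority class (the matched-control design of
  the emulated studies). Subjects are shuffled within class and dealt
  round-robin into 10 folds, so per-fold class counts differ by at most one.
  Rotation $r$ tests on fold $r$ and validates on fold $r+1 \pmod k$ -- the
  validation fold is otherwise unspecified, and a deterministic rotation
  keeps runs reproducible. A leakage guard asserts on every rotation that no
  subject appears in more than one of train/validation/test, including
  through augmented trials.
* **Augmentation.** Training subjects only are windowed with a 0.3-s stride
  (about a 6.6x trial multiplication); validation and test use
  non-overlapping windows. Augmenting evaluation data would leak overlapping
  samples into the score and inflate it.
* **Ensemble-like classification.** At inference a 10-s trial is cut into
  2-s sub-trials, each classified independently, and the hard labels fused
  by majority vote. Ties (possible only for even counts) break toward the
  class with the larger mean probability, then toward HC -- a screening tool
  should not default to the disease label. The trial-level score for ROC
  analysis is the mean MDD probability across sub-trials. Sub-trials do not
  overlap at inference.
* **Metrics.** Accuracy, sensitivity, specificity and F1 from the confusion
  counts, as percentages; a zero-denominator metric reports 0 with a
  warning (degenerate bands do produce such rows). AUC is the rank-based
  Mann--Whitney statistic with tie averaging, equal to the trapezoidal area
  under the empirical ROC; fold metrics are computed at trial level and
  aggregated as mean ± sd.

## Interpretability

Band ablation filters every test trial into one canonical band (delta
0.5--4, theta 4--8, alpha 8--13, beta 13--30, gamma 30--100 Hz; upper edges
clipped to $0.45 \cdot \mathrm{SR}$) with a 4th-order Butterworth applied
forward-backward (zero phase), then evaluates the unchanged classifier.
"Gamma energy" is not standardized in the literature; here it is the mean
squared amplitude of the zero-phase gamma-filtered trial over channels and
time (scale-free in the trial length; a sum-of-squares variant is a flag).
Pearson correlations between gamma energy and each of the 48 learned
features are computed per class within each fold's test set, categorized as
strong ($|r| \ge 0.7$), moderate ($0.3 \le |r| < 0.7$) or weak, with the
sign reported separately. A *marker feature* is one whose correlation sign
is opposite between classes in **every** fold; the package reports the count
and identity of qualifying features rather than hard-coding indices, because
which features qualify depends on training randomness. For markers, the
per-class mean ± sd of activations and an interval-overlap flag are
reported. Correlations use test trials only (the analysis is about
generalization, not fit), and Pearson's $r$ is affine-invariant, so
standardization before correlation is immaterial.

## The synthetic cohort

The generator emulates five-minute resting-state recordings: each channel is
a sum over the five bands of band-limited Gaussian noise -- white noise
passed through the same zero-phase filters the analysis uses (so generator
and analyzer agree on band definitions by construction), rescaled to unit
RMS, and scaled by a per-band amplitude. Class 1 multiplies the gamma
amplitude by `gamma_effect` (default 2, i.e. a fourfold gamma power
elevation). A lognormal per-subject amplitude factor (sd 0.2) is shared
across that subject's channels and trials, creating exactly the
subject-specific structure that CS-CV must not be allowed to exploit;
per-channel jitter (sd 0.1) and broadband white noise (amplitude 0.5)
complete the signal. Baseline band amplitudes (20/10/15/5/2 for
delta/theta/alpha/beta/gamma) follow the usual resting-EEG ordering of
band power. Every recording is reproducible from (seed, subject index,
label) alone.

What the generator does *not* emulate: 1/f spectral slopes, event-related
structure, artifacts (ocular, muscular), nonstationarity, or volume
conduction between channels. Passing tests on this cohort therefore
demonstrate that the implementation learns, votes, cross-validates and
attributes correctly when a band-limited class effect exists -- they say
nothing about clinical performance on real recordings, whose headline
accuracies require the original datasets.

## Problem sizes and numerical choices

The end-to-end acceptance experiments run a deliberately reduced study: 10
subjects per class, 60-s recordings at 250 Hz with 32 channels, batch 64,
two training epochs per fold (validation accuracy plateaus within two epochs
at this effect size), full 10-fold CS-CV, 10-s inference trials. A matched
null run (`gamma_effect = 1`) must score inside the chance band [35%, 65%],
certifying the absence of subject leakage end to end. Normalization uses
$\varepsilon = 10^{-5}$; batch-normalization running statistics use momentum
0.1 and evaluation falls back to batch statistics only when no running
statistics exist yet. Softmax is computed with max-subtraction;
cross-entropy clips probabilities at $10^{-12}$. Fractional windows and
strides are floored to whole samples with a warning.

## Known limitations

* **Band ablation on this synthetic cohort is structurally degenerate.** The
  cohort's class effect is a spatially uniform multiplicative gamma-amplitude
  factor, so a single-band-filtered trial differs between classes only by an
  overall scale — the two classes' gamma content has the identical
  (filter-shaped) spectrum. The spatial block's group normalization computes
  per-trial statistics and removes exactly that scale, which makes
  band-ablated inputs class-exchangeable: every band is expected to score at
  chance and gamma can "rank highest" only by tie. Choosing a
  scale-preserving spatial normalization (`spatial_norm = "batch"`) lets the
  trial scores of gamma-filtered inputs separate the classes again, though
  hard labels remain miscalibrated because the decision threshold was fitted
  to full-spectrum inputs. On real EEG the gamma-band class differences are
  not a pure global scale, which is why the ablation analysis is informative
  there. The marker-feature analysis inherits the same limitation on this
  cohort: the subject factor scales all bands equally, so composition-based
  learned features are nearly constant within class while gamma energy varies
  with the subject factor, leaving within-class feature-energy correlations
  near zero; the marker machinery is therefore validated against a generative
  simulation with class-opposite couplings instead.
* Binary classification only; no severity grading.
* The EDF reader/writer covers continuous equal-rate recordings (the common
  resting-state case), not annotations or variable-rate signals.
* Training is single-threaded CPU; the implementation favors exactness and
  auditability over throughput, and desk-scale configurations are provided
  throughout for experimentation.
* The marker-feature criterion (strict sign opposition in all folds) is
  conservative; with many folds and weak effects it can return an empty set.
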