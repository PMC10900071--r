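---
title: "Latent-likelihood OOD detection for 3D volumes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-likelihood OOD detection for 3D volumes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ltmood)
```

## The problem

A segmentation network deployed on clinical 3D imaging will eventually be
handed inputs unlike anything in its training set: wrong modality, broken
preprocessing, severe artefacts. Task networks degrade unpredictably on such
data, and their built-in uncertainty measures (softmax confidence, deep
ensembles, Monte Carlo dropout) can fail catastrophically far from the
training distribution — confidently wrong predictions. `ltmood` implements
the complementary approach: an unsupervised *filter* that estimates the
likelihood of each incoming volume under a generative model of the training
data, and rejects low-likelihood inputs before they reach the task network.

## The model

The filter is a latent transformer: a two-stage generative model.

**Stage 1 — vector-quantising autoencoder.** An encoder built from stride-2
convolutions and residual blocks maps a volume $x \in [0,1]^{H \times W
\times D}$ to a latent grid $z \in \mathbb{R}^{h \times w \times d \times
n}$, where each spatial dimension shrinks by $2^{\text{levels}}$. Every
$n$-dimensional latent vector is replaced by the index $k$ of its nearest
codebook entry under the L2 norm (ties to the lowest index), giving a
discrete code grid. A mirrored decoder (residual block, stride-2 transposed
convolution per level) reconstructs the input. The codebook of $K$ entries
is learned by exponential moving average over the latents assigned to each
entry (decay $\gamma = 0.99$, Laplace smoothing $\varepsilon = 10^{-5}$);
no gradient flows into the codebook. The encoder is trained with
straight-through gradients plus a commitment term $\beta\,\lVert z -
\mathrm{sg}(e)\rVert^2$ with $\beta = 0.25$, the standard VQ-VAE choice.
Entries that fall below 5% of their expected share of assignments are
restarted on random latents from the current batch, which keeps the codebook
from collapsing onto a few codes.

The reconstruction loss is a weighted sum of voxel MSE, an optional spectral
term (the mean squared modulus of the difference of the 3D discrete Fourier
transforms, divided by voxel count), an optional perceptual term (mean
squared difference of features from a pluggable extractor;
`random_conv_extractor()` provides frozen random convolutional features), and
an optional adversarial term from a small patch discriminator trained with a
hinge loss. A remark worth making explicit: by Parseval's identity the full
complex-DFT spectral term as defined above is numerically *equal* to the
voxel MSE for real inputs, so with default weights it is reported for
monitoring rather than contributing an independent signal; it would differ
only under variants such as comparing magnitude spectra. The perceptual and
adversarial components default to off: the ablation interest is in how they
shape the latent space, and the desk-scale acceptance experiments do not
depend on them.

**Stage 2 — autoregressive likelihood.** The code grid is flattened to a
sequence $s = (s_1, \dots, s_N)$ in a fixed raster order (first axis
slowest, last axis fastest). A causal transformer models

$$p(s) = \prod_{i=1}^{N} p(s_i \mid s_{<i}),$$

trained by next-token cross-entropy, so $\log p(s)$ is *exact*, in nats.
Design choices here:

* **Exact attention.** At desk-scale sequence lengths (512 tokens for a
  $32^3$ volume at 2 levels) quadratic attention is cheap, so the model uses
  exact causal self-attention rather than a linear-attention approximation;
  the approximation only matters for memory at much longer sequences, and
  the attention backend is isolated behind the forward/backward functions.
* **Begin-of-sequence token.** The vocabulary is $K + 1$: a BOS token
  conditions the first position, giving every position a well-defined
  conditional that sums to 1 over the $K$ real codes.
* **Order is part of the model.** Likelihoods are order-dependent. The
  raster order is fixed package-wide and documented in `flatten_codes()`;
  `unflatten_codes()` inverts it exactly.
* **Positional information** is a learned absolute embedding per position.

A volume is flagged OOD by a one-sided rule: $\log p(s) <$ threshold, with
the threshold either absolute or a percentile of the training-set
log-likelihoods (`threshold_policy()`). Per-token conditionals reshaped back
to the latent grid and nearest-neighbour upsampled give a spatial map that
localises *where* the model found the input surprising
(`spatial_likelihood_map()`).

## The synthetic phantom family

The clinical CT that motivates this pipeline cannot ship with a package, so
`phantom_spec()` defines a seeded synthetic family with the structural
features the corruptions act on: a bright ellipsoidal shell ("skull",
intensity 0.95), a mid-intensity interior ("brain", 0.4) carrying smoothed
Gaussian texture, optional compact bright lesions (0.75) with voxel-exact
masks, and a background of exactly 0. The intensity scale follows the
clamp-to-$[-15, 100]$ HU then rescale-to-$[0,1]$ preprocessing convention
for head CT: bone near the top, soft tissue mid-range, acute blood between.
Texture sd 0.05 corresponds to a few HU of tissue heterogeneity and quantum
noise. Geometry is jittered per seed (axis ratios within ±15% of
$(0.8, 1.0, 0.8) \cdot \text{grid}/2$, shell 2 voxels thick), and every
draw is a pure function of the spec's seed.

What the phantoms do *not* emulate: anatomical detail, beam hardening,
partial-volume effects at the skull base, or registration error. Passing
the phantom benchmarks therefore demonstrates that the pipeline's machinery
(compression, likelihood, thresholding, mapping) behaves correctly and that
the detection pattern — gross intensity/geometry corruptions trivially
detectable, mild noise and mirror-symmetry flips not — reproduces at desk
scale; it does not certify performance on clinical data.

## The corruption suite

`default_corruption_suite()` enumerates fourteen near-OOD classes: Gaussian
noise at sd 0.01/0.1/0.2 (unclamped — clipping would censor the noise
signature), background substitution at 0.3/0.6/1.0 (applied to voxels
exactly equal to 0, valid because preprocessing maps background there),
flips through the three central planes (masks co-transformed so they stay
aligned), deletion of a block of axial slices covering 20% of the extent
(central or abutting the top; the source protocol does not state a size, and
example figures show blocks of roughly this scale), mask-based skull
stripping, and global intensity scaling by 0.1 and 0.01. The noise parameter
is the Gaussian *standard deviation*: the printed noise levels are σ values,
and reading them as variances would imply noise with sd up to 0.45 on a
[0, 1] image, inconsistent with the two lower levels being near-undetectable
in the source benchmark. Noise seeds derive from the source volume id and
the parameters, so a corrupted cohort is reproducible end to end.

## Segmentation-uncertainty baselines

The comparison targets are three per-lesion uncertainty methods on a small
3D encoder-decoder (full-resolution convolution, stride-2 down, mid-level
convolution, nearest-neighbour up with 1×1 skip fusion, dropout, conv head):

* **softmax** — the foreground probability itself, from a cross-entropy-
  trained network (Dice-trained probabilities are poorly calibrated);
* **deep ensemble** — N = 5 networks trained on disjoint folds;
* **MC dropout** — one network, dropout p = 0.5 active at inference,
  N = 5 stochastic passes.

Per voxel, the N foreground probabilities are averaged and the binary
entropy of the mean distribution is subtracted from 1, so larger values mean
more certainty (maximum 1; $1 - \ln 2 \approx 0.307$ at $\bar p = 0.5$).
Computing entropy on the mean distribution (rather than the mean of member
entropies) is the conventional predictive-entropy choice; the source text
does not distinguish them. Lesions are 26-connected components (configurable
to 6) of the majority vote over the N thresholded predictions; each lesion's
confidence is the mean voxel certainty over its component. A predicted
component is a true positive when at least half of *its own* voxels overlap
ground truth — the denominator is the predicted component because the score
grades predictions; exactly 50% counts as TP.

## Numerical and tuning choices

* **Desk-scale defaults.** Volumes $32^3$; VQ with 2 levels, $K = 32$,
  $n = 8$, channel widths (8, 16); transformer presets of 4 layers / 4
  heads / width 128 by default and 2 layers / 2 heads / width 64 in the
  scaled experiment. The full-scale configuration (4 levels, $K = n = 256$,
  $176 \times 208 \times 176$ volumes, 1573 tokens) is expressible through
  the same configs; `latent_shape()` reproduces its arithmetic exactly.
* **Problem sizes.** The scaled experiment trains on 200 clean phantoms and
  scores 20 held-out clean volumes against 20 per corruption class; the
  Markov-chain recovery check uses 2000 sequences of 32 tokens. These sizes
  give stable AUC estimates in minutes of single-CPU compute, which is the
  scale this package targets.
* **Optimisation.** Everything trains with Adam. The VQ uses lr $3 \times
  10^{-3}$ with batches of 2 volumes (many small steps converge markedly
  faster here than few large-batch steps at equal cost); the transformer
  uses lr $10^{-3}$, batch 8. All initialisation and shuffling is seeded;
  two runs with the same seed are bitwise-identical.
* **Padding.** Inputs not divisible by $2^{\text{levels}}$ are
  symmetrically zero-padded to the next multiple before encoding and cropped
  after decoding; the padded extent travels with the model.
* **Ties and degenerate inputs.** Quantisation ties break to the lowest
  index. The normalised reconstruction MSE is undefined for an all-zero
  volume and is flagged (`NA` with a warning) rather than silently dropped.
  AUC uses the Mann-Whitney construction with half-credit for ties, computed
  from average ranks. The rank correlation in the likelihood-vs-FP analysis
  is Spearman's, since the relation is monotone rather than linear and no
  particular statistic is canonical for it.
* **Probability floors.** Per-token log-probabilities are floored at
  $10^{-300}$ before the log to keep corrupted-input likelihoods finite.

## Known limitations

* Pure-R training: fine at desk scale, not intended for full-resolution
  clinical volumes; the module boundaries (encode / flatten / score) are the
  stable interface a compiled or GPU backend could slot into.
* The phantom family is geometrically crude (see above), so absolute
  log-likelihood values and AUCs are not comparable to clinical numbers;
  only the qualitative detection pattern is.
* No likelihood-ratio or complexity corrections: the score is the raw exact
  log-likelihood, by design.
* Sampling/generation from the sequence model is out of scope; the model is
  used only as a density estimator.

## Reproducing the experiment

```{r, eval = FALSE}
ex <- ood_experiment(n_train = 200, n_test = 20, seed = 1, verbose = TRUE)
ex$summary          # per-class mean (sd) log-likelihood and AUC
experiment_aucs(ex) # named AUC vector
autoplot(ex)        # score distributions by class
```

`scripts/acceptance.R` runs exactly this plus the latent-shape arithmetic
and the spatial-map chunk contrast, and writes the numbers as JSON.
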