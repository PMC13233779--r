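---
title: "Metacognitive regularization for adversarial EEG generators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacognitive regularization for adversarial EEG generators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmgan)
```

## The problem

Deep classifiers for event-related-potential (ERP) brain-computer
interfaces are starved for data: stimulus-locked EEG epochs are expensive
to record, highly variable across subjects and sessions, and plentiful
only for the majority (non-target) class of an oddball paradigm.
Adversarial generators can synthesize additional epochs, but plain GANs
trained on EEG fail in two characteristic ways: the generated traces miss
the physiological structure of the real signal (wrong spectrum, wrong
local waveform geometry), and the generator collapses onto a few repeated
waveforms (mode collapse), so the synthetic set adds volume without adding
information.

`mrmgan` implements a *metacognitive regulation module* for such
generators: three regularizers attached to the generator objective — not
the critic — that monitor complementary views of the generation process.
The time-domain regularizer (TR) matches local waveform curvature, the
frequency-domain regularizer (FR) matches amplitude spectra, and the
latent-space regularizer (SR) rewards output diversity proportional to
latent diversity. A single weight $\lambda$ trades the diversity pressure
against the two similarity pressures:

$$
L_G^{final} \;=\; L_G \;+\; \lambda\, L_{SR}
\;+\; (1-\lambda)\left(\tfrac12 L_{FR} + \tfrac12 L_{TR}\right),
\qquad \lambda \in (0,1).
$$

`combined_generator_loss()` computes exactly this expression;
`mrm_gan()` trains reduced-scale WGAN-GP, conditional WGAN-GP and 1-D
convolutional ("WaveGAN-style") variants with the terms enabled
individually or together.

## The three regularizers

### Time domain: three-point curvature

A discrete trace $(y_1,\dots,y_T)$ is locally summarized at each interior
sample by the curvature of the parametric quadratic through three
consecutive points, $x(t)=a_1+a_2t+a_3t^2$, $y(t)=b_1+b_2t+b_3t^2$ with
$t\in\{-1,0,1\}$ and $x$ the sample abscissa, so $a_2 = \Delta x$ and
$a_3 = 0$:

$$
k \;=\; \frac{|2(a_3 b_2 - a_2 b_3)|}{(a_2^2+b_2^2)^{3/2}}
\;=\; \frac{2\,\Delta x\,|b_3|}{(\Delta x^2 + b_2^2)^{3/2}} .
$$

We take the absolute value: curvature is a magnitude, and the loss built
on it requires nonnegative arguments. With $\Delta x$ equal to the true
sample spacing this estimator converges to the osculating-circle
curvature $1/r$ as the spacing shrinks (the suite verifies 1% agreement
on circles of radius 0.5, 1 and 5); inside the training loss we use index
units ($\Delta x = 1$), which only rescales the statistic uniformly.

The TR loss is a binary cross-entropy between the curvature profiles of a
real and a generated batch. A cross-entropy needs arguments in $(0,1)$,
while curvature is unbounded — we therefore squash it with the monotone
map $\hat k = k/(1+k)$ and clip to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-7}$ (`squash_curvature()`). This mapping is the
package's own choice of domain repair: it is the minimal monotone
bijection from $[0,\infty)$ onto $[0,1)$, it preserves curvature
ordering, and it leaves the BCE's key property intact — for fixed real
statistics the loss is minimized exactly when the generated curvature
profile equals the real one (verified numerically in the suite).

### Frequency domain: DFT amplitude spectrum

`amplitude_spectrum()` computes $F[k]=\bigl|\sum_n x[n]
e^{-j2\pi kn/N}\bigr|$ and, in normalized form, divides by $\sum_k F[k]$
so the spectrum reads as a probability distribution over frequency bins.
The FR loss is the binary cross-entropy between each generated epoch's
normalized spectrum and the average normalized spectrum of the real
batch. The reference average can alternatively be frozen over the whole
training set (`f_real_scope = "global"` in `mrm_gan()`); the per-batch
default follows how the other statistics are computed and adds no memory
between steps.

### Latent space: the dissimilarity ratio

For two latents $z_1 \ne z_2$ and their generated outputs, the ratio

$$
\rho \;=\; \frac{1-\cos(G(z_1),G(z_2))}{1-\cos(z_1,z_2)}
$$

measures how much output dissimilarity the generator produces per unit of
latent dissimilarity. With all vectors unit-normalized, $1-\cos(u,v) =
\|\hat u - \hat v\|^2/2$, so $\rho$ equals the squared distance ratio —
the two forms agree to $10^{-9}$ in the suite. A collapsing generator
drives $\rho \to 0$.

The direction of the SR term deserves care. Adding $+\rho$ to a loss
being *minimized* would push $\rho$ down and *reduce* diversity —
opposite to the stated purpose of the term and to the accompanying
gradient-norm analysis, which argues that optimizing the term *raises*
the generator's gradient norm. We therefore default to the mode-seeking
direction `sr_mode = "reciprocal"`, $L_{SR} = \mathrm{mean}\,
1/(\rho+\varepsilon)$, which keeps the $+\lambda L_{SR}$ sign of the
combined objective while making its minimization push $\rho$ up. The
alternatives `"negative"` ($-\rho$) and `"literal"` ($+\rho$, the
combined objective read verbatim) are retained for fidelity experiments.

### The gradient-norm bound as an executable check

For unit latents, the ratio of the *output-normalized* generator
$h(z)=G(z)/\|G(z)\|$ along the straight path
$\gamma(t)= t z_1 + (1-t) z_2$ obeys

$$
\rho \;\le\; \Bigl(\int_0^1 \bigl\|J_h(\gamma(t))\,u\bigr\|\,dt\Bigr)^2,
\qquad u = \tfrac{z_1-z_2}{\|z_1-z_2\|},
$$

a direct consequence of the gradient theorem plus Cauchy–Schwarz.
`sr_bound_check()` evaluates both sides with trapezoid quadrature
(forward-mode directional derivatives through the generator) and counts
violations; since the inequality is a theorem, any violation beyond the
quadrature tolerance indicates an implementation defect. We use the
directional Jacobian norm rather than an operator norm — it is tighter,
cheap to compute exactly, and sufficient for the inequality. For the
identity map the two sides coincide in the limit of nearby pairs; the
suite asserts equality on close pairs and zero violations for identity,
constant and randomly initialized two-layer generators.

## Trainers

All three variants minimize the Wasserstein critic objective with
gradient penalty: interpolates $\hat x = u\,x_{real} + (1-u)\,x_{fake}$
receive the penalty $(\|\nabla_{\hat x} f(\hat x)\| - 1)^2$ with
coefficient 10 (the conventional value). Five critic updates alternate
with one generator update; both use Adam with learning rate $10^{-4}$ and
betas $(0.5, 0.9)$ — standard WGAN-GP practice, which we prefer over the
SGD schedule quoted for the *classification* networks since the
generative and classification training blocks are described jointly in
the source experiments and the WGAN-GP literature is unambiguous here.

The networks are deliberately desk-scale (the originals are GPU-scale and
unspecified layer-by-layer): `wavegan_lite` uses a four-stage 1-D
transposed-convolution generator (channel widths 32/16/8/4, kernel 9,
stride 2, tanh head) against a four-stage strided-convolution critic;
`wgan_gp` and `cwgan_gp` use two-hidden-layer MLPs. The conditional
variant concatenates a one-hot label to the latent and to the critic
input; the gradient penalty is taken with respect to the data part only.
Critics use leaky-ReLU exclusively: with piecewise-linear activations the
second derivative vanishes almost everywhere, so the double backprop
required by the gradient penalty is *exact* linear algebra (verified
against finite differences at $10^{-4}$ tolerance and better).

Everything is implemented in base R on BLAS matrix products;
convolutions are lowered to matrix multiplication with memoized
gather/scatter index vectors. Training is deterministic given the seed:
the model object stores the RNG and optimizer state, and
`mrm_gan_resume()` continues a run bit-identically (the suite compares an
interrupted-and-resumed run with an uninterrupted one). When every
regulation term is disabled the trainer reduces exactly — bit for bit —
to the plain base variant; a run with the regulation code path active but
its contribution multiplied by zero reproduces the plain run exactly,
which pins down that the terms enter the update nowhere else.

## Evaluation

*Mode Score* (diversity, higher better): with a compact convolutional
classifier trained on real data only and frozen,
$\mathrm{MS} = \exp\bigl(\mathbb{E}_{x\sim fake}\,
\mathrm{KL}(p(y|x)\,\|\,p^*(y)) - \mathrm{KL}(\bar p\,\|\,p^*)\bigr)$,
where $p^*$ is the real label marginal and $\bar p$ the mean predicted
distribution over the generated set. An uninformative classifier gives
exactly 1; a perfect classifier with matched uniform marginals gives the
class count $C$. Because the score depends on the classifier, its
provenance (training seed and data fingerprint) is recorded in the
report; scores are comparable only within one classifier.

*Sliced Wasserstein distance* (similarity, lower better): epochs are
flattened, sample counts equalized by seeded subsampling, and the exact
1-D Wasserstein-1 distance (mean absolute difference of sorted
projections) is averaged over 128 seeded random unit directions.

*Diagnostics*: `welch_psd()` averages Hamming-tapered modified
periodograms over 1-second windows with 50% overlap and truncates to
0.01–40 Hz (band-average flatness for white noise and Parseval
consistency are tested); `erp_average()` averages epochs of one label and
min–max normalizes per channel; `erp_trend()` overlays a 15th-order
polynomial fitted on an orthogonal basis over a rescaled abscissa, the
conventional smooth for highlighting the P300 deflection.

*Classification metrics*: accuracy, precision, recall and F1 from the
confusion counts, and AUC as the pairwise statistic
$\sum I(s_{pos} > s_{neg}) / (MN)$ with ties counted $1/2$ — the printed
indicator form is silent on ties, and $1/2$ is the convention that makes
the statistic equal the Mann–Whitney estimate. Multiclass tasks are
reduced one-vs-rest and macro-averaged.

## Selecting the trade-off weight

`lambda_grid_select()` implements the gain rule: MS and SWD columns
(grid plus the unregularized baseline) are z-score standardized jointly —
the baseline must share the scale for the differences to be meaningful —
then $\Delta MS = MS_\lambda - MS_{orig}$,
$\Delta SWD = SWD_{orig} - SWD_\lambda$, and the selected
$\lambda^\ast = \arg\max (\Delta MS + \Delta SWD)$ over candidates with
both gains positive. An empty feasible set raises a typed error
(`no_feasible_lambda`) so callers can widen the grid. The default weight
shipped in `regularizer_weights()` is 0.6, the value this rule selects in
the source experiments.

## Augmentation and saturation

`run_augmentation()` follows the mixing-ratio protocol: a stratified
80/20 split of the real data, 5-fold cross-validation inside the 80%, and
per fold a classifier trained on the real training portion plus $r$ times
as many label-matched generated epochs, $r = 0,1,\dots$ Metrics are
always computed on real-only validation folds and the real-only test
split — generated epochs never enter evaluation, which we consider the
only defensible reading since mixed validation data would let synthetic
artifacts inflate the reported gain.

`fit_saturation()` models mean accuracy against the mixing ratio as the
power law $y = a x^\gamma + b$. For fixed $\gamma$ the problem is linear,
so $(a,b)$ are solved in closed form and only $\gamma$ is searched — a
grid over $(0,3]$ refined by golden-section, bracketing every plausible
saturation exponent. The suite requires exact recovery (to $10^{-3}$) of
a planted curve $y = 8.6\,x^{0.40} + 79.6$, SSR no worse than a dense
brute-force grid, and first-order optimality of the residuals.

## The synthetic oddball generator

`generate_oddball()` emulates the structure of stimulus-locked P300
recordings so the whole pipeline is testable without any external data:
per epoch, $1/f$ background noise (`pink_noise()`, spectral exponent 1 by
default — the canonical EEG background slope) plus, in target-class
epochs, a positive Gaussian-shaped deflection with amplitude 5 (arbitrary
µV-like units against noise SD 2.5), latency drawn from
$\mathcal N(400\,\mathrm{ms}, 40^2)$ inside the canonical 300–500 ms
window, width 150 ms, weighted 1.0 on the "Pz-like" channel and 0.6 on
its neighbours. These defaults are fixed study conditions, not tuning
knobs: amplitude-to-noise 2:1 makes the ERP invisible in single epochs
but reliably recoverable by averaging ~tens of epochs, which is the
regime real oddball data occupy. Epoch $i$ has its own RNG substream
derived from the root seed, so per-class counts can change without
reshuffling other epochs.

What the generator does *not* emulate: volume conduction (the channel
topography is a fixed weight vector), eye-blink and movement artifacts,
inter-subject variability, latency jitter correlated across channels,
and non-Gaussian ERP morphology. Tests passing on this data demonstrate
the *mechanics* of the method — losses, gradients, selection rules,
directional effects of the regularizers — not clinical-grade realism.

## Numerical choices and degenerate inputs

* BCE clipping margin $\varepsilon = 10^{-7}$ everywhere a spectrum or
  squashed curvature enters a logarithm.
* The latent ratio rejects pairs whose normalized latents coincide
  (denominator below $10^{-12}$); the trainers draw pairs by splitting
  each latent minibatch, so no extra randomness is consumed.
* The 0.01 Hz high-pass edge is below one cycle on second-long epochs; a
  literal FIR at that edge would be longer than the epoch, so the
  high-pass is realized as per-epoch mean subtraction before the 40 Hz
  low-pass (129 taps at 256 Hz, scaled with the sampling rate, Hamming
  taper). Filtering is zero-phase by centered convolution of the
  symmetric kernel with edge reflection — ERP latencies are preserved
  exactly.
* MaxAbs scaling is per epoch per channel by default (`scope` switch for
  per-channel or global): it keeps every training example in $[-1,1]$ as
  the tanh generator heads require, and all-zero traces pass through
  unchanged.
* Non-finite losses abort training with a warning and revert to the last
  finite step rather than continuing on poisoned parameters.
* Mode Score uses $0\log 0 = 0$; a generated probability mass on a class
  absent from the real marginal would give an infinite KL and is reported
  as `Inf` rather than masked.

## Problem sizes and the ablation regime

The shipped experiments are sized for a laptop CPU: the directional
ablation trains `wavegan_lite` (batch 32) for 600 generator steps per arm
on 400 single-channel 1-second epochs at 256 Hz, three seeds per arm; the
augmentation demonstration uses the compact classifier for a few hundred
steps per fold. These sizes reproduce the *directions* of the reference
results (SR raises Mode Score; FR+TR lower SWD; accuracy rises with the
mixing ratio and saturates) but not their absolute magnitudes, which came
from GPU-scale training on real recordings.

Three instrument choices matter for the ablation and deserve
justification; all were fixed from pilot trajectories on *design seeds
disjoint from the seeds the shipped test uses*, then frozen.

First, single-checkpoint GAN metrics fluctuate strongly from step to
step and seed to seed, so each arm is scored by the *trajectory mean* of
its metric over checkpoints at steps 250 and 500 of the same run —
a lower-variance instrument that costs nothing extra (runs are resumed
between checkpoints and resuming is bit-exact).

Second, the diversity arm uses the bounded (`"negative"`) direction of
the latent term rather than the reciprocal default. The reciprocal
form's pressure on the dissimilarity ratio decays as $1/\rho^2$; tanh
waveform pairs sit at $\rho \approx 0.7\text{--}1.3$ from the first
steps (class-level collapse coexists with waveform-level variety), so at
desk scale the reciprocal direction exerts almost no force exactly where
the Mode Score looks. The bounded direction applies constant pressure —
it is also the direction the established mode-seeking regularizer
literature uses — and its diversity effect is measurable at this scale.
At full scale, with hard collapse ($\rho \to 0$), the two directions
act alike; the reciprocal form remains the package default.

Third, the synthetic task is easier than real recordings: the *plain*
trainer escapes mode collapse on its own within a couple of thousand
steps, after which all arms converge and no contrast remains. The
ablation therefore runs 500 steps per arm — the regime where mode
collapse is present, which is the failure mode the module exists to
counteract and the regime the full-scale reference results inhabit. The
similarity clause compares the fully regulated model (all three terms)
against the plain baseline, matching the headline full-module
comparison. The generated "target-class" average is formed by weighting
generated epochs with the frozen classifier's target probability: the
generators are unconditional, so no epoch carries a label, and at desk
scale no single epoch need cross the hard decision threshold — the
weighted average is always defined and extracts exactly the
target-like content the clause asks about.

## Known limitations

* At desk scale the latent term's Mode-Score effect (+0.01 to +0.02 in
  trajectory-mean MS on pilot runs) is smaller than the seed-to-seed
  variance of mode-collapse escape timing (~0.1), so the three-seed
  directional diversity check is under-powered and can resolve in either
  direction; the similarity (SWD) contrast is robust at the same scale.
* The curvature and spectrum statistics are computed per channel;
  cross-channel covariance is not regularized.
* The Mode Score depends on its classifier; two reports are comparable
  only if their classifier provenance matches.
* The reduced-scale architectures cap achievable sample quality; the
  package's purpose is a faithful, fully testable implementation of the
  method, not a state-of-the-art EEG synthesizer.
* `wavegan_lite` requires epoch lengths divisible by 16 (four stride-2
  stages); resample or pad epochs accordingly.
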