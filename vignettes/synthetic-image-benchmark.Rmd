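---
title: "Benchmarking synthetic medical image sharing: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking synthetic medical image sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthrad)
```

## The problem

Privacy rules make patient-level medical images hard to share. One proposed
workaround is to train a conditional generative adversarial network (GAN) on
the real cohort and share only synthetic images that, in aggregate, carry the
cohort-level statistics. Whether that actually works is an empirical question,
and `synthrad` implements the benchmark that answers it: train one multi-label
classifier on real images and one on label-equivalent synthetic images,
evaluate both on the *real* test fold, and report the utility gap

$$\Delta \mathrm{AUC} \;=\; \overline{\mathrm{AUC}}_{real} - \overline{\mathrm{AUC}}_{syn},$$

where $\overline{\mathrm{AUC}}$ is the mean per-label AUROC. A second
diagnostic,

$$\Delta_{syn} \;=\; \overline{\mathrm{AUC}}_{syn}(X_{syn}) -
  \overline{\mathrm{AUC}}_{syn}(X_{real}),$$

detects *label overfitting*: a conditional generator that encodes class
identity through unrealistic image features scores far better on its own
synthetics than on reals, so $\Delta_{syn} \gg 0$ even when the images look
plausible.

Datasets here are multi-label: each image carries a binary vector over finding
labels, and a *class* is one unique label combination (multi-hot vector). The
benchmark sweeps the number of classes, the number of training samples per
class, and the resolution, holding everything else fixed
(`benchmark_table()` records the published sweep compositions).

## The two generative models

Both models are Wasserstein GANs with gradient penalty (weight 10, the cited
default; the source does not restate it), Adam ($\beta_1 = 0$,
$\beta_2 = 0.99$), one critic update per generator update, and equalised
learning rate (weights kept at unit variance and rescaled by the He constant
$\sqrt{2/\mathrm{fan_{in}}}$ at every use).

**Progressive-growing reference (`kind = "prog"`).** Resolution blocks of two
3×3 convolutions with Leaky-ReLU and pixel-wise feature vector normalisation;
nearest-neighbour upsampling between generator blocks, average-pooling
downsampling in the discriminator; a minibatch standard-deviation channel in
the final discriminator block; 1×1 to/from-image heads per resolution allowing
smooth interpolation (blend weight linear in real images seen within a
transition phase). Conditioning is auxiliary-classifier style: the
discriminator also predicts the label, and a softmax cross-entropy term enters
both losses (real and fake for D, fake only for G). Training grows from 8 px:
one stabilisation phase, then a (transition, stabilisation) pair per doubling,
each lasting `images_per_phase` real images — so 8→32 px at 1.4M/phase costs
7M images and 8→128 px at 1M/phase costs 9M.

**Conditional pixel-norm / projection model (`kind = "cpd"`).** No growth.
The generator keeps to-image heads at *every* resolution and sums them in
image space (output skips), with a bounded tanh output. After each generator
convolution, pixel normalisation is conditioned on the noise and labels:

$$b^i_{x,y} = \frac{a^i_{x,y}}
  {\sqrt{\tfrac1N \sum_{j=0}^{N-1} (a^j_{x,y})^2 + \epsilon}}
  \cdot \gamma^i + \beta^i,
  \qquad \gamma = W_1 [z;y] + b_1,\; \beta = W_2 [z;y] + b_2,$$

with $\epsilon = 10^{-8}$ (`conditional_pixel_norm()`). The discriminator uses
residual blocks and a projection head: global sum pooling to features $f$,
then $\mathrm{score} = w^\top f + b + \langle V^\top y, f\rangle$
(`projection_score()`), which is exactly linear in $y$.

A third BigGAN/self-attention variant existed upstream but was excluded from
the benchmark results for instability; it is out of scope here.

## FID-based training control

Image sets are compared by the squared Fréchet distance between Gaussian
summaries $(m, C)$ of feature embeddings:

$$d^2 = \lVert m - m_w\rVert_2^2 +
  \mathrm{Tr}\!\left(C + C_w - 2 (C C_w)^{1/2}\right).$$

The evaluation always uses $N$ real and $N$ fresh synthetic images
($N = 10{,}000$ by default): when the fold is smaller than $N$ the real side
cycles through the fold so usage counts differ by at most one, and the
synthetic side redraws noise for the (repeated) labels. Training runs for a
minimum budget equal to the progressive schedule total, then evaluates FID
every 400,000 real images ("400T" is read as 400 thousand, consistent with
the section's use of M for millions) and stops after two consecutive
evaluations that fail to improve on the running best.

Numerical choices:

* Matrix square root by eigendecomposition of $C^{1/2} C_w C^{1/2}$ with
  eigenvalues clipped at zero, and the result floored at zero — robust to the
  slight indefiniteness of sample covariances and checkable against an
  independent eigen-oracle (the tests do both, at 1e-8).
* Covariance divisor $n - 1$ (unbiased); the source states neither the
  divisor nor the Inception layer.
* At desk scale the embedder is a small *fixed-seed random* convolutional
  encoder (`fid_embedder()`), not Inception-v3: no external weights, fully
  deterministic, identical across the real/synthetic sides. FID values are
  therefore comparable only within one embedder, which is all the stopping
  controller needs; reproducing published absolute FID magnitudes is a
  non-goal.

## Gradient penalty without double backprop

The WGAN-GP penalty $w_{gp}\,(\lVert \nabla_x D(\hat x)\rVert - 1)^2$ needs
the gradient of an input-gradient norm with respect to the parameters. The
input gradient itself is computed exactly by backpropagation. For the
parameter gradient the package uses a central-difference Hessian-vector
product: with $v = 2c\,g$ (where $g$ is the input gradient and $c$ the
per-sample penalty coefficient, both held constant),

$$\nabla_\theta \langle g, v\rangle \approx
  \frac{\nabla_\theta D(\hat x + \varepsilon v) -
        \nabla_\theta D(\hat x - \varepsilon v)}{2\varepsilon},$$

two extra forward/backward passes with $\varepsilon$ scaled to the
perturbation magnitude. The unit tests verify this against brute-force
finite differences of the penalty itself on small critics; agreement is to
~1e-6 relative. Note that because the minibatch standard-deviation channel
couples samples, "per-sample" input gradients are gradients of the summed
scores, as in the reference implementations.

## The classifier and its protocol

The downstream model is a multi-label CNN with sigmoid outputs and per-label
binary cross-entropy. The protocol constants are the published ones and are
package defaults: at most 5,000 images per epoch, batch size 48, initial
learning rate 1e-4, LR divided by 10 after 2 consecutive epochs without
improvement of the mean validation AUROC, stop after 3, best-validation
weights retained. "Improvement" means strictly greater than the running best.
Degenerate labels (all-0/all-1 in a fold) are excluded from the mean AUROC
and reported — the source is silent on this case.

Two architectures are provided. The default `small_cnn` is a seeded
three-block CNN suited to 8–32 px phantoms. `densenet121_style` reproduces
the dense-connectivity pattern (blocks 6/12/24/16, growth 32, compression-½
transitions, global average pooling) ending in the 1024-dimensional
penultimate representation used by the privacy audit — but without batch
normalisation (the desk-scale engine has no BN layer) and with a 3×3 stem in
place of the 7×7/stride-2 + max-pool stem. No pretrained weights are used or
downloadable; "pretrained densenet-121" is explicitly replaced at desk scale.
Images are resized to the model input by power-of-two average pooling /
nearest-neighbour upsampling rather than bilinear interpolation — at phantom
scales the resize is always a clean power of two.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` + `generate_dataset()` produce the stated world every test
runs in: a centred ellipse background (the "anatomy") plus one localized
geometric primitive per finding label (blob/ring/line/texture) at a fixed,
label-specific position, additive Gaussian pixel noise, patient ids assigned
in consecutive blocks, folds split patient-wise within class strata. Defaults,
chosen once:

* lesion contrast 0.35 and noise SD 0.05 — a high-signal regime in which a
  small classifier reaches AUC ≈ 1, appropriate because the benchmark's
  *machinery* (not clinical difficulty) is under test;
* one image per patient — patient grouping is structural, and multi-image
  patients are exercised explicitly in tests via `images_per_patient > 1`;
* pixels stored in [0,1], mapped affinely to [−1,1] at every model input.

Because label information is spatially localized by construction, occlusion
attribution has a known ground truth, and separability is monotone in the
contrast parameter. What the phantom does **not** emulate: anatomical
variability between patients, correlated acquisition noise, class imbalance
beyond the class list, or any visual realism. A green test therefore
establishes that the pipeline's statistics behave correctly on data with
known structure — it does not certify performance on radiographs or CT
scans, and the published real-data gaps (e.g. ΔAUC ≈ 0.02–0.07) are
deliberately not reproduction targets.

## Statistics

* `mann_whitney_extrema()`: one-sided Mann-Whitney U between ΔAUC samples at
  sweep extrema. Exact p by the count-distribution recursion for
  $n + m \le 12$ without ties, normal approximation with tie and continuity
  correction otherwise. The alternative direction is explicit because the
  source reports only "one-sided": larger label spaces are tested for larger
  ΔAUC, smaller per-class counts for smaller ΔAUC, matching the reported
  trends.
* `wilcoxon_signed_rank()` / `reader_study_stats()`: reader accuracies
  $acc = (TR + TS)/(TR + TS + FR + FS)$ against the random-labelling null of
  0.5; exact p by dynamic programming over doubled midranks for $n \le 15$
  (zeros dropped); panels under 5 readers report mean ± SD without a test,
  mirroring the published practice for small panels.
* `auroc()`: midrank statistic, ties counting ½ per pair — exactly the
  pair-counting definition, verified against brute force.

## Scale-down and determinism

Everything in the test suite and acceptance script runs at desk scale:
8–16 px, ≤ 16 channels, hundreds of images and thousands of training images
instead of millions. Protocol constants that *are* the published numbers
(N = 10,000; 400k cadence; patience 2; 1.4M/1M per phase; 5,000 images/epoch;
batch 48; lr 1e-4; patience 2/3; 12,544 occlusion tiles; class/sample table
rows) remain the package defaults and are asserted at those values. One
master seed fans out to per-stage seeds (`fanout_seed()`) so data generation,
GAN training, synthesis noise and classifier training are independently
reproducible.

## Known limitations

* Pure-R training loops: minutes, not hours, are the intended scale; the
  architecture is faithful but the channel counts are not GPU-scale.
* The desk FID embedder makes absolute FID values incomparable to
  Inception-based numbers.
* `prog` generator output is linear upstream; `gan_generate()` clips to
  [−1,1] to honour the output-range contract (the cpd model is tanh-bounded
  by design).
* 2D grayscale only; no DICOM, no differential-privacy accounting — both
  explicitly out of scope.
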