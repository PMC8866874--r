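---
title: "Shift-contrastive anomaly detection for otoscopy video screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-contrastive anomaly detection for otoscopy video screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoscad)
```

## The screening problem

Otoscopy footage from pediatric encounters is heavily skewed toward normal
ears, and abnormality is diverse: supervised classification of diagnoses is
data-starved from the outset. `otoscad` therefore frames screening as
*unsupervised anomaly detection*: all training videos are normal, and a video
is flagged when it diverges from the learned normal appearance. Because
diagnostic information is carried by individual views of the tympanic
membrane rather than by motion, the video problem is decomposed into a frame
problem plus an aggregation step:

1. **Eardrum detection** — a supervised single-instance detector finds the
   membrane region in each frame (at most one instance per frame, so no
   anchors or non-maximum suppression are needed).
2. **Representation learning** — a self-supervised embedder maps membrane
   patches onto the unit sphere so that normal patches concentrate and
   off-distribution patches disperse.
3. **Anomaly scoring** — each detected patch is scored by its cosine
   distance to the k nearest training embeddings; the video score is the
   mean over its detected frames, thresholded at an operating point chosen
   on a validation split.

## The training objective

Let $\phi(x)$ denote the l2-normalized embedding of a patch $x$ and $c$ the
normalized center of all training embeddings. Contrastive learning alone is a
poor fit for anomaly detection: it spreads normal samples over the whole
sphere, leaving no "normal region" for a score to refer to. The objective
used here combines two terms.

**Mean-shifted contrastive loss.** Each patch contributes two benignly
augmented views (random resized crop, horizontal flip — never color, since
color is the diagnostic cue). With $\theta(x) = (\phi(x) - c)/\lVert \phi(x)
- c\rVert$, the standard InfoNCE loss with temperature $\tau$ is applied to
the $\theta$'s, each view as anchor against its partner, the denominator
running over every other view in the batch. Re-centering means the
contrastive geometry lives around $c$ rather than spanning the sphere.

**Distributional-shift angular loss.** Color-jittered copies $z$ of the
patches act as stand-ins for pathology (an infected membrane differs from
normal mainly in color). The angular term attracts normal views to the
center and repels shifted views from it:
$$\mathcal{L}_{sa} = -\phi(x)\cdot c \;+\; \max(0,\; m + \phi(z)\cdot c),
\qquad m = 1.$$
The hinge saturates only at the antipode, so shifted samples feel a constant
outward pull. We note the repulsive sign deliberately: an attractive hinge of
the form $\max(0, 1 - \phi(z)\cdot c)$ would drive shifted samples *toward*
the center, indistinguishable in effect from applying the plain angular loss
to both $x$ and $z$, and could not produce the large margin that the
shift-angular objective alone delivers in the ablation. The margin is
exposed in `embedder_config(margin = )`.

The full objective is the sum of both terms. Shifted samples additionally
participate in the contrastive term as instances of their own (their own
positive pairs, negatives to everything else), so a batch of $N$ videos
contributes $4N$ views. Ablation modes (`objective = "msc"`, `"angular"`,
`"shift_angular"`) select subsets: the `"msc"` baseline is the mean-shifted
contrastive loss plus the plain angular loss, with no shifted samples in the
batch.

**Batch construction.** One patch is drawn per video per batch
(`batch_size` videos), so near-identical frames of one video never meet as
negative pairs. The temperature default is $\tau = 0.25$ and scoring uses
$k = 2$ nearest neighbours.

**Center.** $c$ is computed once from the initial encoder over all training
patches and held fixed; recomputation per epoch is available behind
`center_recompute_per_epoch` but is off by default, following the convention
of mean-shifted contrastive training.

## The shift transformations

Three color-jitter variants manufacture off-distribution negatives:

- **cj-wf** jitters the whole patch;
- **cj-rc** jitters inside one random rectangle (area fraction uniform in
  [0.1, 0.5], log-uniform aspect in [1/3, 3]);
- **cj-rr** interpolates jittered and original images with a smooth weight
  map: a few random pixels set to one, Gaussian-smoothed (sigma = 10% of the
  patch side), rescaled to peak at one.

Jitter half-ranges default to 0.1 for brightness and contrast, 0.4 for
saturation and 0.15 for hue. The weighting toward chroma is deliberate: the
shift transformation's job is to emulate *pathology-like* deviation, and
middle-ear pathology expresses itself chromatically (erythema), whereas
brightness and contrast vary benignly with illumination and probe position —
deviations a screening model must tolerate, not flag. With
illumination-heavy jitter the embedder can satisfy the repulsion term
through a luminance shortcut and become blind (or adversarial) to
near-luminance-neutral color shifts; we observed exactly this failure mode
during development, including ranking inversions. None of the jitter values
are prescribed by the underlying method description; they are exposed in
`shift_spec()` and serialized in the YAML config.

## The synthetic study conditions

Clinical otoscopy video is IRB-restricted, so the package ships a generator
(`scene_spec()`, `generate_dataset()`) that emulates the structure the method
assumes rather than photorealism. A frame is a darker textured canal
background; with probability 0.85 a shaded ellipse (the membrane) is drawn,
its diameter drawn per axis from 35–65% of the frame, its center drifting by
up to 2 px per frame. A frame is annotated — flag plus tight box — only when
the ellipse spans at least 20% of the frame in both width and height,
mirroring the clinical annotation rule; smaller or absent views are negative
frames. Abnormal videos recolor the membrane toward red (erythema) with
magnitude 0.35, over the whole membrane or a random sector covering 20–60%
of its area, fixed within a video. The per-video base color varies with
standard deviation 0.05 per channel, which makes the abnormal shift overlap
the normal color variation: partial lesions at the default magnitude move
the mean membrane color by less than the across-video color spread, so the
task is not linearly trivial. Pixel noise (sd 0.02) and 8-bit quantization
(which also makes the PNG dataset layout round-trip exactly) complete the
frame.

Default counts reproduce the skewed clinical balance: 60 normal training
videos, 10 + 10 normal validation/test, 10 + 10 abnormal validation/test,
with 5–15 frames per video at 64×64 px — deliberately small so the whole
pipeline runs in CPU minutes. Every video is guaranteed at least one
annotated frame, as a video with no usable membrane view would not have
entered a clinical dataset.

What passing tests on this generator do **not** show: robustness to
specular highlights, wax, hair and partial occlusion, to camera exposure
changes, to non-color pathology (perforation, retraction), or to detector
drift on real anatomy. The generator's role is to verify the method's
mechanics — detection, embedding geometry, scoring, thresholding — under the
stated statistical structure, not to certify clinical performance.

## Backbones and numerical choices

No deep-learning framework is assumed: both backbones are compact
fully-connected encoders over 4×4-mean-pooled pixel features, with analytic
backprop in plain matrix algebra (verified against central finite differences
in the test suite, tolerance 1e-4). At the bundled data scale these encoders
saturate the detection task and leave the embedding task non-trivial, which
is what the tests need; the backbone is a configuration surface
(`detector_config()`, `embedder_config()`), and a clinical-scale
configuration (224 px inputs, wider layers, 5,000-step schedules, embedder
learning rate 1e-5 with weight decay 5e-5 and no momentum) ships in
`inst/config/clinical-scale.yaml` but is not exercised by the tests.

A from-scratch encoder differs from a fine-tuned pretrained backbone in one
way that matters for this objective: near a random initialisation the whole
batch can sit close to one point on the sphere, which is the fixed point of
the angular attraction, and training can stall there or collapse into it.
The package exposes three guards — learning-rate warmup, gradient-norm
clipping, and feature standardization — all off by default after
measurement at the bundled scale: clipping and low learning rates trap
training at the no-progress plateau rather than escaping it, and
standardization equalises per-feature noise with the low-dimensional color
signal, degrading even an untrained encoder's scores. A linear projection
head (`hidden = 0`) is available as the closest stand-in for
already-informative pretrained features. The shipped defaults (one
96/64-unit hidden layer for detector/embedder, momentum SGD) were chosen by
pilot convergence at the bundled scale.

Other numerical decisions, fixed once:

- degenerate-norm guard $\varepsilon = 10^{-8}$ for all normalizations;
  embeddings coinciding with the center raise a distinct degenerate error;
- kNN ties broken by bank row order (deterministic);
- the localization L1 term is masked on negative frames — a distance to an
  undefined box is meaningless;
- detector augmentation: random resized crop (with box re-annotation under
  the same 20% rule), mild color jitter, cutout. Rotation and shearing are
  omitted: axis-aligned re-annotation under rotation systematically inflates
  boxes at 64×64 scale;
- the operating threshold is the largest candidate (midpoints of adjacent
  distinct validation scores) whose validation TPR under the strict
  `score > psi` rule still reaches the target; videos with no detections are
  excluded from metrics and reported separately as unscorable;
- training lengths (250 detector steps, 250 embedder steps) were chosen by
  pilot convergence of the loss curves at the bundled scale; both are config
  fields.

All randomness flows from explicit seeds: dataset generation derives an
independent substream per video, and `run_experiment()` derives stage seeds
from one global seed, so a config reproduces every metric bit for bit.

## Known limitations

- The generator's lesion model (sector recoloring) is a coarse proxy for
  real middle-ear findings; bulging, effusion and texture changes are not
  modelled, and pneumatic assessment is out of scope.
- Mean aggregation dilutes anomalies confined to a few frames of a long
  video; the frame-score pooling function is intentionally simple.
- The dense encoders do not transfer to full-resolution clinical frames;
  they are the bundled-scale instantiation of a configurable backbone.
- Scores are relative to the training feature bank: a shift in acquisition
  hardware or lighting between training and deployment shifts scores and
  invalidates a previously chosen threshold.
- At the bundled scale the end-to-end AUROC varies by several points across
  seeds (the small test split — 20 videos — quantises AUROC in steps of 1%,
  and the from-scratch embedder is sensitive to its initialisation). Multi-
  seed reporting, as in the test suite, is the intended usage.
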