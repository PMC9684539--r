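---
title: "Identifying tsetse flies from wing interference patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tsetse flies from wing interference patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wipid)
```

## The problem

Tsetse flies (*Glossina* spp.) vector the trypanosomes responsible for human
and animal African trypanosomiasis, and surveying them requires identifying
specimens to species or subspecies — ordinarily a job for a small number of
expert taxonomists.  Transparent insect wings photographed against a dark,
light-absorbing background display *wing interference patterns* (WIPs):
stable, species-characteristic colour patterns produced by thin-film
interference in the wing membrane, exactly as on a soap bubble.  The colour
at any point is set by the local membrane thickness.  WIPs vary strongly
between species, moderately within species, and show a faint, recurrent
sexual dimorphism.

`wipid` implements the computational side of WIP-based identification as a
tested, reusable pipeline: a physics-based synthetic image generator
emulating a 23-taxon reference database, preprocessing and stratified
cross-validation, four compact convolutional classifiers with an in-package
training engine, a bag-of-features SVM baseline, hierarchical evaluation
(genus, species complex, species/subspecies) and a 15-condition image
perturbation suite with traffic-light robustness scoring.

Because the reference photographic database is distributed only on request,
the package's quantitative guarantees are expressed on synthetic data whose
statistical structure (class imbalance from 1 to 620 images per taxon,
multicolour patterns, faint dimorphism, within-species variation) emulates
the real database.  What passing tests demonstrate is that the *pipeline*
recovers known generating structure under realistic imbalance and noise —
not that any particular accuracy will be attained on real photographs.

## The optical model

The wing membrane in air is a single dielectric film with two interfaces.
For film index $n$ (default 1.5, chitin-like), ambient index 1, incidence
angle $\theta_i$ (default 10°, the acquisition geometry) and thickness $d$,
light refracts to $\theta_t$ by Snell's law and accumulates the phase

$$\delta = \frac{4\pi n d \cos\theta_t}{\lambda},$$

with a half-wave shift at the external reflection.  The implementation uses
the two leading beams: amplitude $r$ (Fresnel, per polarisation) reflected
at the top interface and $-(1-r^2)\,r\,e^{i\delta}$ returned from the bottom
one, giving

$$R = \tfrac{1}{2}\sum_{s,p} r^2\left|1 - (1-r^2)e^{i\delta}\right|^2 .$$

Higher-order internal bounces carry amplitude $r^3 \approx 0.008$ and below
and are neglected.  The test suite bounds this approximation against the
exact multi-beam (Airy) solution: the absolute deviation stays below 0.02
for $n \le 1.6$ over thicknesses 100–900 nm.  Two consequences the test
suite asserts directly: reflectance is periodic in $d$ with period
$\lambda/(2n\cos\theta_t)$, and a quarter-wave film ($d = \lambda/4n$)
reflects maximally.  At $d = 0$ the two reflections cancel (the residual
$r^6 \sim 10^{-4}$ of the transmission correction is far below visual
relevance).

Real wings are not ideal flat films: membrane corrugation makes WIPs
essentially non-iridescent in practice, and the renderer correspondingly
evaluates a single effective incidence angle rather than modelling
angle-dependent iridescence.

## Colorimetry

Reflectance spectra are integrated against CIE illuminant D65 (standard
10 nm table) and the CIE 1931 2° observer, evaluated with the multi-lobe
Gaussian analytic fits of Wyman, Sloan & Shirley (2013) — accurate to about
1% and far more compact than the tabulated observer.  White-point handling
is von Kries scaling against the integrated illuminant white followed by
re-application of the sRGB D65 white, so a unit-reflectance spectrum maps
*exactly* to neutral (1, 1, 1); encoding is standard sRGB gamma.  The
default wavelength grid is 380–780 nm in 10 nm steps (41 points):
interference spectra are smooth at visible film thicknesses, and halving the
step changes rendered 8-bit colours by less than one count.

Rendered thickness ramps reproduce the Newton series: with increasing
thickness across the first order, hue moves monotonically from yellow
through orange and red into violet, and over 100–900 nm the four colour
families reported on Glossina wings — green, yellow, blue and red — all
appear.

## The synthetic generator

Each taxon is a `SpeciesTemplate`: a base membrane thickness, Gaussian
patches (centre, radius, thickness offset) defining the coloured regions, a
constant +12 nm male offset (the faint dimorphism), and a smooth
per-specimen random field (white noise low-pass filtered at 5% of the image
width, clamped at ±3σ, default amplitude 10 nm) modelling within-species
variation — discrete local variations on an otherwise stable pattern.

The wing outline is a half-ellipse: straight leading edge, elliptical
trailing margin.  Two chordwise veins ("V" at 70% span, "VI" at 35%) and
the trailing-edge arc are carried as named polylines, because the
robustness module needs nameable crop boundaries; thin +120 nm ridges along
the veins make them visible as colour lines.  Real Glossina venation and
landmark geometry are deliberately out of scope — the generator's purpose is
statistical structure, not anatomy.

The shipped fixture (`glossinaTemplates()`) has one template per named
taxon in the reference database with that database's per-class image counts
(1 to 620, total 1762), the three studied species complexes (*fuscipes*,
*palpalis*, *morsitans*) labelled as such.  Base thicknesses step by 14 nm
in alphabetical taxon order, so congeners (adjacent rows) get similar but
distinct colours, which is the qualitatively realistic regime.

Seeds are counter-based: record $i$ of a run with master seed $s$ uses seed
$s + 131071\,i$, so each specimen's image depends only on (template, sex,
counter, master seed), never on generation order, and datasets reproduce
byte-for-byte.  A mild contrast/saturation boost (`acquisitionAdjust()`)
models the photographic post-processing of the real database; the
robustness conditions "raw picture" and "resized raw picture" bypass it.

What the generator does *not* emulate: real venation, specimen damage,
mounting artefacts, focus gradients, and microscope HDR/white-balance
behaviour.  Conclusions about those factors come only from the perturbation
suite, which applies them synthetically.

## Preprocessing and cross-validation

Stored images are resized to 256 × 116 (width × height) and normalised into
(0, 1) by a global division by the nominal bit depth (255 for 8-bit); each
architecture then declares its own input size with an on-the-fly resize at
training time.  This honours both geometries used in the original protocol
(256 × 116 at preparation, 256 × 256 at training) with no information loss
beyond the first resize.  Resampling is pinned to bilinear; an image already
at target size is rescaled in value only, never resampled.  Whether the
normalisation interval is open or closed is immaterial under /255.

Classes with fewer than 10 images are discarded before training to prevent
overfitting on a handful of specimens.  Folds (k = 5) are stratified: each
class is shuffled with its own substream of the master seed and dealt
round-robin starting at an offset derived from the class index, giving an
exact partition with per-class fold sizes differing by at most one,
deterministically.

Training-time augmentation is horizontal/vertical flips, rotation uniform
in ±15° and zoom in [0.9, 1.1] — mild bounds chosen to keep the wing in
frame, since the protocol names the operations but not their magnitudes.
Sex is carried in the manifest but never used as a label.

## Classifier architectures

Four classifiers share one declarative layer-descriptor format and one
training contract (cross-entropy, trained from random initialisation — no
pretrained weights for any architecture):

* **DarkNet-9** — the DarkNet-19 stage pattern truncated after the
  256-filter scale: convolutions 32, 64, 128, 64(1×1), 128, 256, 128(1×1),
  256 — 8 convolution layers — then a 1×1 classification convolution,
  global average pooling and softmax.  This is the only truncation of the
  published stage pattern consistent with both "one or two scales fewer"
  and the stated 8-layer count.
* **DarkNet-14** — additionally keeps the 512 scale (512, 256(1×1), 512,
  256(1×1), 512): 13 convolutions plus the classification layer.
* **Reduced MobileNet** — stem convolution (32 filters, stride 2) then one
  depthwise + pointwise pair per scale through 64, 128, 256, 512; the
  1024-filter scale is omitted and each scale has exactly one depthwise
  convolution; batch normalisation after every weighted layer; a two-layer
  fully connected head (512 units, then the classes), VGG-style.
* **ResNet-18** — the published residual layout: 7×7/2 stem, eight
  two-convolution residual blocks (64, 64, 128, 128, 256, 256, 512, 512
  filters, stride-2 projection shortcuts at scale changes), global average
  pooling and a fully connected classifier.  17 convolutions plus the head.

Parameter counts order DarkNet-9 (0.8 M) < DarkNet-14 (4.6 M) <
ResNet-18 (11.2 M), asserted numerically on built models.

No deep-learning framework is assumed: the training engine stores
activations as channels × pixels matrices, lowers convolutions to im2col
(compiled) plus a BLAS matrix product, and backpropagates through batch
normalisation (ε = 10⁻⁵, running-statistic momentum 0.9), leaky-ReLU (slope
0.1 for the DarkNet family, 0 otherwise), max pooling (argmax bookkeeping),
depthwise convolutions and residual blocks.  Optimisation defaults — Adam,
learning rate 10⁻³, batch 32, 50 epochs — are pragmatic choices exposed in
`trainConfig()`, since the original protocol leaves them unspecified.  All
randomness flows through R's RNG from the configured seed, so loss traces
are bit-reproducible on a given BLAS.

## The bag-of-features baseline

The classical baseline is local descriptors → 4000-word dictionary →
L1-normalised histogram → polynomial-kernel SVM.  The descriptor stage is
pluggable by design; the default is Harris keypoints with
orientation-normalised 4×4×8 gradient histograms (128-d, SIFT-like), which
satisfies the behavioural contract (locality, rotation robustness,
emptiness on structureless images) without a patent-encumbered or
build-fragile dependency.  The dictionary is Lloyd k-means under a fixed
seed (tests use k ≪ 4000 through the exposed argument; the default honours
the 4000-codeword dictionary).  Nearest-codeword ties break to the lower
index.  The SVM is one-vs-rest over binary polynomial-kernel machines
(degree 3, C = 1, both exposed), predicting by maximum decision value.
No published accuracy exists for this baseline, so only behavioural and
smoke properties are asserted.

## Hierarchical evaluation

Training happens once at the finest level (subspecies where defined, else
species); genus- and complex-level metrics are obtained by *coarsening
predictions*, since the original study evaluates at several levels without
describing separate trainings.  The coarsening map sends members of the
three studied complexes to their complex and everything else to an explicit
`"unassigned"` class — never a silent drop.  A consequence asserted as a
property: accuracy is monotone under coarsening.  Records whose class is
absent from a fold's training data are scored (and necessarily wrong), not
excluded, mirroring how 2-image taxa fail in practice.  Non-Glossina
negative samples are supported as templates of another genus flowing
through the same pipeline.

## The robustness suite

Fifteen conditions, in the fixed legend order: no transformation, Gaussian
blur, lens blur, video distortion, spread, hurl, RGB noise, CIE noise,
three partial-wing occlusions (trailing edge deleted, outer part cropped at
vein V, inner part cropped at vein VI), the raw unprocessed picture,
horizontal and vertical flips, and the resized raw picture.  The
scatter/throws/scrambling-RVB/scrambling-CIE vocabulary is accepted as
aliases for spread/hurl/RGB-noise/CIE-noise — two names for the same four
operations.

The original descriptions name effects, not parameters, so defaults are
pinned and echoed in every run log: Gaussian blur σ = 2 px; lens blur as a
disk (bokeh) kernel of radius 4 px with a (1, 1) px centre offset — the
closest standard reading of "decentring of the lens"; video distortion
darkens every 3rd pixel row by 50%; spread swaps each pixel with a random
neighbour within 3 px (a pure permutation, so per-channel value multisets
are preserved exactly); hurl replaces each pixel with probability 0.1 by a
uniform random colour; RGB noise adds Gaussian noise of σ = 0.08; CIE noise
perturbs L, C and h (σ = 6, 6, 0.15 rad) in CIE LCh(ab) under D65 and
converts back with gamut clipping.  Every stochastic condition is a pure
function of (image, parameters, seed).

Occlusions crop at the named geometric boundaries of the synthetic wing
(which are a fixed function of the frame, so no per-image metadata is
needed), fill with the dark background, and are idempotent.  The raw
conditions are modelled as bypassing `acquisitionAdjust()`: when the
generating templates are available the specimens are re-rendered without
post-processing (and, for condition 15, resized); this is the synthetic
analogue of "the original picture without colour/contrast/resizing".

Scoring follows the traffic-light rule: green exactly at 100% per-species
identification, red exactly at 0%, yellow in between, blank where a species
has no samples.  The "none" column reproduces the model's base accuracy
exactly, and a species absent from training is red across all 15 columns.

## Problem sizes and numerical choices

The parameter-recovery evaluation uses 8 well-separated templates × 40
images at the generator's native 116 × 256 geometry, DarkNet-9 at 32 × 32
input, Adam with learning rate 10⁻³, batch 32, 12 epochs, 5-fold CV — sizes
chosen so the whole evaluation is a routine desk computation on one core
while leaving the generator's study conditions untouched.  The 32 × 32
training input is legitimate for these architectures because global average
pooling makes them size-agnostic; colour patterns, not fine texture, carry
the class signal in the synthetic regime.  The label-shuffled control uses
a single 80/20 split at the same settings.  The robustness acceptance check
scores 5 specimens per class over the full grid.

Numerical conventions worth knowing: softmax rows are guaranteed to sum to
1 within 10⁻⁶; argmax ties (prediction, codeword assignment) break to the
first/lowest index; batch-norm inference uses running statistics;
`augmentImage` with all parts disabled is an exact identity; Gaussian blur
uses a 3σ-trimmed normalised kernel with reflective boundaries, so it
preserves the image mean to 10⁻⁶.

## Limitations

* Absolute template thicknesses are illustrative, not biological estimates:
  no published calibration links Glossina membrane thickness to WIP colour.
* Synthetic-data accuracies do not transfer to real photographs; the
  package's claims about real data are structural (architecture layouts,
  protocol parameters) and behavioural (invariances, degradation modes).
* The training engine favours transparency and reproducibility over speed;
  it is adequate for the package's evaluation sizes, not for training on
  large photographic databases.
* The SIFT+VLAT comparison method and GAN-based augmentation are not
  implemented; negative (non-Glossina) handling is a labelled pass-through,
  not a dedicated open-set mechanism.
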