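---
title: "Classifying confocal endomicroscopy frames: models, training strategies and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying confocal endomicroscopy frames: models, training strategies and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Confocal laser endomicroscopy (CEM) images the colonic mucosa in vivo at
video rate through a fiber probe. A single inspection of one subject yields
thousands of frames, each a small grayscale matrix (nominally 290 rows by
292 columns here) showing the micro-texture of the mucosa: in healthy
tissue, a quasi-regular lattice of round crypt lumens with bright rims; in
inflamed tissue, enlarged and irregular lumens on a brighter background; in
dysplastic ("cancer") tissue, disordered, elongated and fused structures.
`cemclass` implements a complete pipeline for classifying such frames into
the three tissue states, together with the evaluation harnesses that
distinguish the two clinical uses of such a classifier:

* **cross-subject** evaluation — the model is trained on one cohort and
  applied to subjects it has never seen; whole subjects are assigned to
  train/validation/test, so this measures generalization across
  individuals;
* **cross-sample** evaluation — frames are split at random, so frames from
  one subject (but never the same frame) may appear on both sides; this
  measures how well annotation of a large stream can be automated from a
  partial annotation of the same cohort.

Cross-subject prediction is the harder problem: each subject has its own
appearance (illumination, crypt spacing, orientation), so the shift between
training and test distributions is larger.

## Informative-frame quality control

Raw streams contain non-informative frames: sensor saturation from excess
fluorescence, underexposure from probe misposition, occlusions. The QC test
implemented in `histogram_skewness()` / `filter_frames()` computes the
Fisher–Pearson standardized third moment of the pixel-intensity
distribution,

$$ g_1 = \frac{m_3}{m_2^{3/2}}, \qquad
   m_k = \tfrac{1}{n}\sum_i (x_i - \bar x)^k, $$

and keeps a frame iff \(g_1 > -5\) (strictly). Design choices worth noting:

* **Population moments.** With ~84,680 pixels per frame the small-sample
  bias correction is negligible; the uncorrected \(g_1\) is the simplest
  defensible estimator. Computing over raw pixel values is mathematically
  identical to count-weighted histogram moments and avoids binning choices.
* **Zero-variance frames** have undefined skewness and are discarded with
  reason `zero_variance`; they carry no diagnostic texture.
* **Asymmetry of the rule.** Saturated frames concentrate mass at the top
  of the range and have strongly negative skewness (a frame with 99% of
  pixels at 255 and 1% at 0 has \(g_1 \approx -9.85\)), so they are
  discarded. Underexposed frames are the mirror image with strongly
  *positive* skewness and therefore **pass** the literal rule. The rule is
  implemented exactly as stated; the package's benchmark pipeline removes
  remaining ground-truth artifacts via the simulator manifest so the
  classification task stays well-posed, and real-data users should treat
  the filter as a saturation detector only.

## Handcrafted texture features: LBP + linear SVM

The local binary pattern of a pixel compares it with its 8 neighbors:
\(LBP(x,y) = \sum_{n=0}^{7} 2^n\, s(i_n - i_{x,y})\) with \(s(x) = 1\) for
\(x \ge 0\) and 0 otherwise — ties set the bit. All bits carry equal
significance, so any fixed neighbor ordering is valid; `cemclass` freezes
**clockwise from the top-left neighbor**, with neighbor \(n\) weighted
\(2^n\), so codes are reproducible. Border pixels lack a full neighborhood
and are skipped (no padding — padding would fabricate comparisons), so the
code map of an \(H \times W\) frame is \((H-2) \times (W-2)\). The map is
computed globally first and then tiled, so codes near patch borders use
true neighbors from adjacent patches.

The code map is tiled into non-overlapping \(8 \times 8\) patches — the
scale of a healthy vesicular crypt — over the largest fitting grid
(remainders dropped), and each patch contributes a raw-count 256-bin
histogram; concatenation in row-major patch order gives the feature vector
(a nominal frame: \(36 \times 36\) patches, length 331,776). Histograms are
left unnormalized: patch pixel counts are constant (64), so normalization
is a scalar absorbed by the SVM.

Classification uses a linear SVM, one-vs-rest over the three classes with
\(C = 1\) on the raw count features. Two numerical choices matter:

* **Exact kernel reduction.** The features are sparse and very
  high-dimensional, so the fit goes through the linear Gram matrix: the
  centered training Gram is eigendecomposed into an exact, equivalent
  representation in at most \(n\) dimensions (for an SVM with a bias
  term, centering only shifts the bias — the decision boundary is
  unchanged), and the reduced dense problem is solved by libsvm at the
  raw-count kernel scale. This sidesteps both the cost of 331k-dimension
  kernel evaluations and the ill-conditioning that pure-R SMO solvers
  exhibit on Gram matrices dominated by the histograms' shared mass.
* **Decision orientation.** Each binary machine's decision value is
  oriented on the training data so that larger always means "this class";
  prediction takes the class with the largest oriented value, breaking
  ties toward the more severe class.

LBP is invariant to monotonic gray-level transforms, so per-subject
brightness/contrast differences do not disturb it; geometric subject
effects (crypt spacing, orientation) do, which is one reason cross-subject
accuracy trails cross-sample accuracy.

## The compact CNN and transfer scaffold

The representation-learning branch is a deliberately small convolutional
network: five 3×3 convolution layers with 64, 128, 256, 512, 512 filters,
each followed by ReLU and 2×2 max pooling, then a 1024-unit fully
connected layer with ReLU and dropout (p = 0.5) and a 3-class softmax
output. Training minimizes mean cross-entropy with ADAM at learning rate
0.001, batch size 32 (both exposed in `train_config()`), retaining the
best-validation-loss weights with early stopping (patience 10 by default).
No data augmentation is applied, and class re-weighting is off by default.

The engine behind it (conv via im2col + GEMM, pooling, dropout, ADAM,
full backward pass) is implemented in compiled code inside the package and
is validated in the test suite against finite-difference gradients. All
stochasticity — initialization, shuffling, dropout — flows from R's RNG, so
a fixed seed reproduces a training run bit-for-bit.

Input geometry: the native 290×292 frame is not divisible by \(2^5\), so
frames are either bilinearly resized (default 288×288, the nearest multiple
of 32, distorting aspect by <1.5%) or center-cropped. The synthetic
benchmark uses 32×32 center crops: the class-discriminative texture is
local (a crop covers several crypts at native scale), and the small input
keeps a five-stage network trainable on a single CPU in minutes.

The transfer scaffold mirrors the standard freeze-and-fine-tune recipe: a
VGG16-shaped backbone (13 conv layers; grayscale input adapted by channel
replication), the 1000-class head replaced by a 3-class layer, and the
first \(k\) convolutional layers (default 3) excluded from gradient
updates — "layers" counts conv layers, matching a 1..13 freezing sweep.
Optionally a linear SVM is fitted on the penultimate feature layer and
replaces the softmax head (`svm_on_features()`). Pretrained weights are a
user-supplied input; nothing is downloaded, and with random initialization
the scaffold is validated structurally (freezing contract, head shape),
not for accuracy. ResNet50/DenseNet identifiers are reserved but not
implemented: their batch-norm and skip topologies are out of proportion to
their role here, and the constructor says so rather than approximating.

## Redundancy-aware sample selection

Video-rate acquisition makes consecutive frames near-duplicates, so a
random training subsample wastes annotation effort on redundancy. The
selection procedure clusters, per class, the four first-order statistics
of each frame — standard deviation, mean, variance, skewness of raw pixel
values — with k-means (features z-scored per dimension first; otherwise
variance, on a scale of ~10³, dominates skewness, ~10⁰) and picks one
uniformly random member of each non-empty cluster. The variance/std pair
is deliberately redundant, kept as specified; its only effect is a benign
doubling of that direction's weight. Constant frames (undefined skewness)
are excluded and flagged. k-means uses 10 seeded restarts (cheap at four
dimensions) with a bounded retry loop against empty-cluster failures,
after which fewer selections are accepted. Test data are never clustered
or selected. Budgets `k` count clusters per class.

## The synthetic benchmark

No public archive of the original frames exists, so the package ships a
procedural simulator (`synth_config()`, `generate_frame_set()`) that
reproduces the *statistical* structure the pipeline depends on, not the
optics:

* **Three texture classes** built from a hexagonal lattice of crypt lumens
  (dark discs with bright rims on a mid-gray background): healthy — small
  regular round lumens, spacing ≈ 12 px so an 8×8 patch covers one crypt;
  inflammation — enlarged irregular lumens, raised background intensity;
  cancer — elongated, disordered, partially fused structures with a
  broken lattice (large positional jitter, 25% dropout).
* **Subject effects**: each subject draws a brightness offset (±25),
  lattice-spacing multiplier (0.85–1.2) and lattice rotation once; this
  makes cross-subject generalization strictly harder than cross-sample,
  mirroring the real protocol gap qualitatively.
* **Temporal redundancy**: frames come in redundancy groups (default 5)
  rendered from one base scene, shifted by at most `jitter_px` (default 3)
  with fresh additive Gaussian noise (sd 8).
* **Acquisition drift**: each scene additionally draws a brightness shift
  (sd 8, truncated at ±16) and contrast factor (0.88–1.12), emulating slow fluorescein
  concentration and probe-coupling drift. This is what makes first-order
  statistics informative about scene identity — without it, clustering on
  those statistics could not tell scenes apart and the selection strategy
  would be untestable. The drift is truncated, and the intensity palette
  leaves headroom, so informative frames stay inside the 8-bit gamut:
  clipping would flatten texture non-uniformly across subjects and
  contaminate the class signal. In-gamut affine drift leaves LBP features
  untouched (monotonic).
* **Artifacts**: saturated frames (≥95% of pixels ≥250 with a small dark
  remainder, skewness ≪ −5) and underexposed frames (the mirror regime),
  interleaved at `artifact_fraction` with ground truth recorded in the
  manifest so QC sensitivity/specificity is computable without labels.
* **Determinism**: identical configuration + seed gives bit-identical
  frames and files.

Frame geometry defaults to 290 rows × 292 columns; the row/column
assignment of the nominal "292 × 290" matrix is a convention of this
package. What the simulator does **not** model: respiratory motion,
fluorescein pharmacokinetics, probe optics, occlusions by residues or
mucus. Passing benchmarks on synthetic data therefore demonstrates the
correctness and sanity of the pipeline, not clinical performance.

## Benchmark problem sizes and expectations

The study-scale benchmark (used by the acceptance tests and
`scripts/acceptance.R`) generates 9 subjects per class with 75 informative
frames each (~2,000 frames). The LBP+SVM is trained on a
20-frame-per-subject subsample of the 75% training split (≈540 frames,
bounding the memory of the 331,776-dimension featurization); the CNN,
whose 32×32 crops are cheap, uses a 30-frame-per-subject subsample with
one sixth carved off for validation and trains at most 15 epochs with
patience 4. Both are evaluated on the full 25% test split. The cross-subject benchmark assigns 6/1/2 subjects per
class to train/validation/test. The selection benchmark uses a smaller,
strongly redundant stream (3 subjects/class, 35 frames, redundancy groups
of 5) and compares cluster-based against random selection at budgets of
8, 16 and 24 frames per class over three seeded trials; budgets near the
number of distinct scenes per class are where coverage — and hence the
gain — differs most.

On these conditions the expected ordering is: scratch CNN ≥ 95% and
LBP+SVM ≥ 90% cross-sample accuracy; cross-subject accuracy below
cross-sample for the same model family; cluster selection at least
matching random selection at every budget. Accuracies reported on real
animal cohorts are not reproducible from synthetic data and are not
targets of this benchmark.

## Degenerate inputs and tie-breaks

* Constant frames: undefined skewness → discarded by QC; excluded from
  selection clustering; LBP code 255 everywhere.
* Majority voting over a subject's predicted frame labels breaks exact
  ties by clinical severity (cancer > inflammation > healthy);
  configurable.
* Stratified splits put `floor(n · test_fraction)` frames per class in
  test, remainder in train; k-fold assigns `rep_len(1:k)` over shuffled
  frames so fold sizes differ by ≤1 within a class. Both guard against
  leakage (an error, itself under test, if a subject or frame appears in
  two splits).
* Single-class training sets are refused by the SVM; labels outside the
  three classes are refused by the CNN.

## Known limitations

* The simulator's classes are easier to separate than real tissue; real
  accuracies will be lower and the synthetic benchmark says nothing about
  them.
* The transfer scaffold without pretrained weights tests structure, not
  transfer value; supplying converted ImageNet weights is the user's
  responsibility.
* The QC rule intentionally passes underexposed frames (see above).
* The SVM model retains its training feature matrix (prediction evaluates
  the kernel against it); for very large training sets this is the
  dominant memory cost.
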