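---
title: "Pattern mining and few-shot particle localization in cryo-ET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern mining and few-shot particle localization in cryo-ET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cryo-electron tomography images the native interior of cells as 3D volumes
(tomograms) reconstructed from tilt series of projection images. Downstream
subtomogram averaging needs thousands of particle center coordinates per
species, but tomograms are crowded, low-contrast, and distorted by the
missing wedge — the unsampled region of Fourier space left by the limited
tilt range, which blurs every object along the beam (z) axis. `tomomine`
implements a two-stage strategy for this setting:

1. **Exploration** — propose candidate positions everywhere, learn a
   self-supervised embedding of the candidates, and let the user pick the
   cluster(s) corresponding to the molecule of interest. This replaces
   per-dataset manual annotation with a visual, label-free triage.
2. **Localization** — from the handful of coordinates the first stage
   yields, train a voxel-level center detector with a positive-unlabeled
   (PU) objective and contrastive regularization, and read out coordinates
   by non-maximum suppression (globular species) or filament tracing
   (tubular species).

Everything is exercisable end-to-end on synthetic tomograms with known
ground truth, so the whole pipeline is testable without any external data.

# Synthetic scenes: what they emulate, and what they do not

`scene_spec()` / `render_scene()` draw cosine-tapered dark spheres
(globular particles), curved tubes whose centerlines follow the quadratic
family `x = a0 + b0*y + c0*y^2`, `z = a1 + b1*y + c1*y^2` (the same family
the filament-tracing stage fits), an optional membrane-like sheet and
small high-density fiducial dots into a constant background; a missing
wedge is imposed in Fourier space (coefficients whose (k_x, k_z) direction
lies outside the half-angle from the k_z = 0 plane are zeroed), and i.i.d.
Gaussian noise is added with standard deviation `noise_sigma` times the
clean signal's peak-to-peak amplitude.

The default scene is the scaled study condition used by the test suite:
a 64 x 64 x 32 volume with 30 spheres of radius 4, a 60-degree wedge and
`noise_sigma = 0.7`. These sizes keep every training run on a single CPU
within minutes while still being genuinely hard (the noise amplitude is
comparable to the particle contrast, and the wedge smears every particle
along z).

What the generator deliberately does **not** model: the contrast transfer
function, realistic reconstruction artifacts (ring/streak artifacts of
weighted back-projection — the wedge filter stands in for the angular
sampling limit), structured biological background, and molecular density
from atomic models (particles are smooth radial profiles). Passing tests
therefore demonstrate the correctness and the qualitative behavior of the
algorithms, not real-data detection rates.

Tube placement happens before sphere placement, since centerlines are
extended obstacles that are hard to fit into an already crowded volume;
all placements respect a minimum separation of 1.5x the maximum particle
radius and raise a placement error after bounded retries.

# Candidate proposal

Preprocessing is Gaussian denoising (separable, reflect-padded; default
sigma 2 voxels) followed by 256-bin histogram equalization onto [0, 1] — a
monotone, rank-preserving contrast normalization. A constant volume maps to
0.5 by convention. Because particles are dark (cryo-ET convention), the
equalized volume is inverted before blob detection; `invert_contrast`
exposes the convention.

Candidates come from a difference-of-Gaussians (DoG) pyramid: the volume is
smoothed at a geometric sigma ladder starting at `expected_radius/sqrt(2)`
with ratio 1.6 and 3 levels (the ladder is our choice — the blob-detection
standard — as no schedule is prescribed by the underlying method), adjacent
levels are subtracted, and the response is the voxelwise maximum across
levels. The automatic threshold is the response mean plus 0.5 *population*
standard deviations. Greedy 3D NMS then selects coordinates by decreasing
response with a minimum Euclidean separation; ties are broken toward the
lexicographically smallest (x, y, z). On noise-free scenes this proposal
stage has perfect recall by construction (a property test asserts it).

For each candidate at (x, y, z), the network input is a patch pair: `P_s`,
a square patch from the central tomographic slice, and `P_t`, the average
of patches sampled from every tilt image within ±15° of untilted, each
centered at the tilt-projected position
`x_theta = (x - floor(W/2)) cos(theta) + (z - floor(D/2)) sin(theta) + floor(W/2)`,
`y_theta = y` (tilt axis y). Patches are sampled bilinearly, reflect-padded
at borders (and flagged); when no tilt series is available, or no tilt
falls inside the angular window, `P_t` falls back to `P_s` (P_s-only mode).
The two patches enter the network stacked as two channels — the minimal
fusion, since the pairing itself is what carries the complementary
contrast.

# The exploration network

The encoder is a Siamese 2D CNN: a residual backbone (depth configurable;
the scaled profile uses two residual stages of two 3x3 convolutions each,
with 1x1 channel projections and 2x2 max pooling), global average pooling,
and a three-layer fully connected projection head with batch normalization
and ReLU; a two-layer prediction head follows. Both heads output
128-vectors. Training minimizes the symmetrized negative cosine similarity
between the prediction of one augmented view and the *stop-gradient*
projector output of the other:

L = D(y1, stopgrad z2)/2 + D(y2, stopgrad z1)/2,  D(y, z) = -(y/||y||)·(z/||z||)

with minimum -1. The stop-gradient is implemented literally: the analytic
gradients returned for the z arguments are identically zero (a test
asserts this against finite differences). Optimization is SGD with
momentum 0.9, weight decay 1e-4, and a cosine-decayed learning rate.

Augmentations (always the same spatial transform for both patches of a
view): horizontal/vertical flips, brightness jitter in [0, 0.5], contrast
jitter in [0, 0.2], random resize-crop with scale in [0.7, 1], corner
dropout (a square of 10–25% of the patch side at a random corner, our
default for an unspecified range), and rotations restricted to multiples
of 90° to avoid interpolation artifacts.

Two choices deserve explanation:

* **Output normalization of the projector.** The projector ends in a
  batch-normalization layer without affine parameters. At desk scale
  (tens of candidates, dozens of optimization steps) this is what prevents
  the classic failure mode of negative-cosine Siamese training — a
  near-constant embedding — from erasing the input-dependent structure.
  `embed_dataset()` applies this normalization using the statistics of the
  evaluated dataset itself (a single full-dataset pass), which keeps the
  embedding centered; consequently an embedding depends (weakly, through
  two moments) on the dataset it is evaluated with, which is the right
  trade-off for a method whose output is consumed by clustering over that
  same dataset.
* **Random initialization.** ImageNet-pretrained initialization is the
  full-scale default in the field; here the backbone is initialized
  randomly (He initialization) so that no download is ever needed. The
  scaled training profile (patch 32², batch 16, 30 steps, learning rate
  0.02) preserves and sharpens the class structure of the patches; the
  separability test (spheres vs tubes) passes across seeds with
  within-class minus between-class cosine margins of 0.02–0.27.

# Embedding space: layout, over-clustering, selection

The 2D layout is a neighbor-graph embedding: a symmetrized k-nearest-
neighbor graph (default k = 40) with Euclidean edge weights, geodesic
distances by shortest paths, classical MDS per connected component, and
side-by-side placement of components with a gap scaled by `min_dist`
(default 0.1), min-max normalized to the unit square. This is a
deterministic nonlinear method in the same family as the manifold
embeddings commonly used for this visualization; determinism across runs
was prioritized over stochastic-layout aesthetics. Colors follow
RGB = (u, v, 1 - (u+v)/2) from the normalized planar coordinates.

Grouping is over-clustering: vanilla k-means with k = 50 (k much larger
than the expected number of classes), then spectral clustering of the k
centers into h = 10 final labels — Gaussian affinity with bandwidth equal
to the median inter-center distance (our choice; the similarity kernel is
otherwise unspecified), normalized-Laplacian eigenvectors, k-means on the
leading h of them. Each candidate inherits its center's final label.
`select_coords_by_label()` is the non-interactive stand-in for lasso
selection in a browser session: it returns the candidate coordinates of
chosen labels, which become the few-shot annotations for the detector.

# The localization network and its losses

The detector is intentionally 2D-heavy: a per-slice 2D UNet (two encode
blocks of two 3x3 convolutions + ReLU + 2x2 max-pool in the scaled
profile; decode blocks with 2x2 transpose convolutions and skip
concatenation) produces per-slice features, a single 3D convolution
(3x3x3, ReLU) fuses them across z, and two 1x1x1 heads emit (a) the
sigmoid center heat map and (b) the linear contrastive feature map. This
mirrors how human pickers work: xy slices carry most of the information,
while xz/yz views are degraded by the missing wedge. Output stride is 1.
(`slice_context` optionally widens each per-slice input to a small slab of
neighboring slices; the default keeps the single-slice design.)

**Targets.** Globular annotations are splatted as Gaussian kernels
exp(-||v - p||² / (2 sigma_k²)) (elementwise maximum on overlap, value 1
at each center voxel), truncated at 3 sigma_k, beyond which voxels are
unlabeled and carry -1. Tubular annotations fill radius-3 balls with 1.

**PU focal risk.** Voxels are grouped into true positives (Y = 1), soft
positives (0 < Y < 1) and unlabeled (Y = -1). Each group contributes the
mean of a focal negative log-likelihood (exponent alpha = 2 on the
prediction, beta = 4 on the soft label; values from the center-point
detection literature, since none are prescribed); the non-negative PU
combination is

R = pi_p (pi_tp R+tp + pi_sp R+sp) + max{0, R-u - pi_p (pi_tp R-tp + pi_sp R-sp)}

The printed focal expressions are log-likelihood style; the risks are
their negatives, which makes minimization well-posed — a perfect
classifier drives R to 0 monotonically (asserted by test). The max{0, ·}
clamp guards against overfitting the unlabeled set; its subgradient is
taken as 0 when the inner term is negative (the simple non-negative-risk
variant). With no soft-positive voxels (tubular targets) the sp terms
vanish and the plain non-negative PU form remains.

Two priors need estimators the method leaves open:

* `pi_p`, the marginal probability that a voxel is particle: default
  `expected_particles x particle volume / volume size` with the particle
  volume taken as the `expected_radius` ball (~0.06 for the study scene),
  exposed in the configuration. The looser kernel-support-based estimate
  (~0.2 for the same scene) over-weights the non-negative clamp's
  correction term and measurably hurts background suppression.
* `pi_tp`, the mixture weight of centers within the positive class:
  defaulting this to the voxel-count ratio n_tp/(n_tp + n_sp) (~1e-3 for
  Gaussian targets) multiplies the only center-raising term by ~1e-3 and
  demonstrably prevents center peaks from ever forming. The package
  therefore treats centers and shoulders as equal mixture halves by
  default (`pi_tp = 0.5`), which restores the balance the center-point
  detection losses achieve by per-object normalization; `pi_tp = NA`
  selects the voxel-count estimator for users who want it.

**Debiased contrastive regularization.** Feature vectors are L2-normalized
and compared through exp(f_i·f_j / t) with temperature t = 0.07 (exposed;
no value is prescribed). For each positive anchor, the other 2n_p - 1
positive vectors (across both views) are positives and the unlabeled
vectors negatives; the denominator's negative mass is debiased,
g_sup = max{(mean_u - pi_p mean_p)/pi_n, e^(-1/t)}. For each unlabeled
anchor (both views are anchored; the twin is the same position in the
other view) the only positive is its augmented twin and the remaining
2N - 2 vectors are negatives, with the prior chosen by pseudo-group:
predicted probability > 0.9 uses pi_n, < 0.3 uses pi_p, and neutral
voxels take the prediction-weighted average of the two losses (the
weights are treated as constants in the gradient). Unlabeled vectors are
subsampled (cap 512 by default, 128 in the scaled profile) to bound the
quadratic pair cost. All three losses and their analytic gradients are
verified against brute-force double-loop oracles and finite differences.

**Consistency.** The augmented view is produced by flips and 90°
rotations only — transforms with exact inverses — so the augmented heat
map can be re-aligned voxelwise and compared by mean squared error.

**Total objective.** R + lambda1 (L_sup + lambda2 L_unsup) + lambda3 L_cons
with lambda1 = 0.1, lambda2 = 0.5, lambda3 = 0.1. Ablation flags drop the
contrastive module (lambda1 = lambda3 = 0) or replace the PU risk with a
plain focal loss that treats unlabeled voxels as negatives.

**Wedge-subspace projection.** Before anything else the detector projects
the volume onto the measurable Fourier subspace: coefficients inside the
missing wedge (default half-angle 60 degrees, i.e. the common +/-60-degree
tilt range; the tilt range is acquisition metadata, configurable via
`detect_wedge_filter`, `NA` to disable) are zeroed. The reconstruction
carries no signal there, so this removes roughly a third of the white
noise power at zero signal cost — on the study scene it lifts even a
plain smoothed-darkness baseline by ten F1 points.

**Input rescaling.** The detector denoises (Gaussian, sigma 2) and then
*standardizes* the volume (z-score, sign-flipped so particles are
positive) rather than histogram-equalizing it. Under near-Gaussian noise,
rank equalization compresses the deep dark tail — exactly the voxels that
carry the particle signal — into a negligible value range, which degrades
both classical template scores and the trained detector on the synthetic
scenes. Equalization remains available
(`detect_rescale = "equalize"`) and is the sensible choice for real
tomograms whose intensity artifacts are heavy-tailed. Candidate proposal
keeps the classic denoise + equalize front end, where only ranks matter.

**z context.** Missing-wedge-elongated particles span many z slices while
the fusion kernel alone sees one neighbor on each side, so by default each
per-slice UNet input is a 5-slice slab (`slice_context = 2`, replicated at
volume edges); the per-slice design is otherwise unchanged. This widens
the effective z receptive field to roughly the particle extent, which is
the main axis separating particles from uncorrelated noise blobs.

**Training.** Random 64 x 64 x 5 crops (each guaranteed to contain at
least one annotated center) in batches of 2, Adam, learning rate 3e-3
decayed by 10 every 8 epochs, 15 epochs of 16 steps in the scaled profile.
The published recipe (learning rate 1e-3, decay every 5 epochs, 10
epochs) is reachable through the same keys; the scaled profile's slightly
larger rate and longer schedule compensate for random initialization and
the small training volume. Inference runs the full tomogram in one pass. Peaks are extracted by 3D
max-pooling NMS: a voxel is kept iff it equals the window maximum of its
cubic kernel (default 9 = 2 x expected radius + 1, forced to 3 in tubular
mode) and exceeds the probability threshold (default 0.85, the middle of
the high-precision plateau of the standardized-input calibration); ties
keep the lexicographically smallest coordinate.

# Filament tracing

Dense tubular detections are grouped by connected components of the graph
with edges at Euclidean distance <= cutoff (default 6 = twice the tubular
NMS kernel). Each group with at least 6 points and nonzero y spread is
fitted by two independent least-squares quadratics, x on y and z on y;
the parameterization axis is fixed to y, and groups that cannot be
parameterized in y are rejected rather than re-parameterized — a
documented limitation for filaments nearly perpendicular to y. Fit
quality is the RMS of the pooled x and z residuals. Curvature is the
standard plane-curve curvature of each parabola,
kappa(y) = |2c| / (1 + (b + 2cy)²)^(3/2), maximized on a dense y grid
(step 0.1; the printed closed form in the source method is typeset-garbled
and dimensionally inconsistent, so the package implements the standard
formula for the stated parabola family). Tubes pass iff residual and
maximum curvature are both strictly below their cutoffs; survivors are
resampled at uniform y steps of 2 and out-of-volume points dropped.

# Evaluation

Predictions are matched to ground truth greedily in score order: each
prediction claims the nearest unclaimed ground-truth point within the
match radius (default = expected particle radius). TP(k), precision
TP(k)/k, recall TP(k)/n_gt, and the F1 harmonic mean follow; F1 is
reported for the full thresholded prediction list. Greedy-by-score was
chosen over optimal assignment because the evaluation is defined over
"top k predictions" — a ranking-based notion.

# Numerical and reproducibility choices

* All convolutions are zero-padded stride-1 with explicit forward and
  backward passes; gradients of every layer and every loss are verified
  against central finite differences at tolerance 1e-4 or better.
* All randomness flows from a single configuration seed through R's RNG;
  training, augmentation, rendering and clustering are bit-reproducible
  given the seed. Derived seeds stay below 2^31.
* Predicted probabilities are clamped to [1e-6, 1 - 1e-6] inside the
  losses; the clamp region carries zero gradient.
* Heat-map NMS and greedy NMS break value ties lexicographically so the
  outputs are permutation-independent.
* The problem sizes used by the test-suite study conditions — 64 x 64 x 32
  scenes, 30 particles, 10 annotations, two-stage networks with 4–16
  channels — were chosen so that each training-based check completes in
  minutes on one CPU while still exercising the full objective.

# Known limitations

* The synthetic generator omits CTF and reconstruction artifacts; real
  tomograms will need retuned thresholds (`prob_threshold`, NMS kernel,
  DoG sigmas) and benefit from the full-scale training profiles.
* The exploration stage at desk scale relies on short training plus
  dataset-statistics normalization; it separates visually distinct shape
  classes but should not be expected to resolve subtle conformational
  differences the way the full-scale recipe (batch 256, 300 epochs,
  pretrained backbone) can.
* Filaments nearly perpendicular to the y axis are rejected by design
  (y-parameterized fitting).
* The detector's z context is one fused slice neighborhood (3x3x3 kernel
  over per-slice features); very elongated particles along z would need
  more fusion layers (`unet_blocks`, architecture extension).
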