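---
title: "Methods: architecture accounting, mask evaluation and the synthetic test bench"
author: "podkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture accounting, mask evaluation and the synthetic test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podkit)
```

# The problem

Pods on a mature soybean plant are small, densely packed, mutually occluding
objects photographed against a solid backdrop from the side of the row.
Detecting them with boxes alone fails — neighbouring pods share almost every
box — so the task is instance segmentation: per-pod pixel masks.  The model
family podkit works with is the one-stage prototype-coefficient design: a
prototype branch ("Protonet") emits $k$ full-image basis planes
$P_1,\dots,P_k$, each detection head emits, besides a box and a confidence, a
coefficient vector $c \in \mathbb{R}^k$, and the instance mask is

$$ M = \mathbf{1}\!\left[\sigma\!\Big(\sum_{j=1}^{k} c_j P_j\Big) > \tfrac12\right] \cdot \mathbf{1}[\text{inside box}], $$

binarised strictly above $0.5$ and zeroed outside the instance box.  podkit
implements this assembly, the evaluation stack around it, the symbolic
architecture accounting for the network variants, the no-reference
image-quality (NR-IQA) frame-harvesting stage, dataset I/O, and a synthetic
scene generator so that every stage is testable without field data.

# Symbolic graphs and the parameter convention

`buildBaseline()` assembles the nano-scale one-stage segmentation baseline as
a symbolic DAG of primitive layers (no weights): a CSP backbone, a feature
pyramid with taps P3/P4/P5 at strides 8/16/32, decoupled box and class heads,
per-scale coefficient heads and the prototype branch consuming P3 only.

Parameter counting follows the **fused (deployment) convention**: a
convolution followed by batch normalisation is counted as one biased
convolution, because that is what the folded inference-time network carries.
Published summary tables for this architecture family report the fused model,
and the convention is pinned by tests at full precision (the single-class
baseline has exactly 3,258,259 parameters).  The frozen 16-weight projection
of the distribution-focal box head is included.  Width rules follow the
family's scaling: the prototype stem width is $\min(2k, 64)$, the coefficient
head width $\max(16, k)$, and the class-head width $\max(64, \min(n_c, 100))$.

FLOPs are fixed at **2 × multiply–accumulates of convolution, transposed
convolution and linear layers** at the stated input size; nearest-neighbour
upsampling, pooling and concatenation are index/copy operations and count
zero.  Profiler conventions differ, so this one is stated explicitly and
used everywhere.  One subtlety is documented in `profileModel()`: the
GFLOPs figure under which this architecture family is usually quoted
corresponds to the stock 80-class prediction-head widths (12.0 GFLOPs at 640
px), while a single-class head is narrower (11.3 GFLOPs).  `profileModel()`
reports both.

An independent oracle guards the whole accounting: tests materialise every
layer's weight arrays at their stated dimensions and count elements, which
must equal the closed-form sums for every variant.

# Hierarchical prototype aggregation (HPA)

A P3-only prototype branch sees high resolution but shallow semantics.  HPA
feeds the branch a fusion of all three pyramid levels: P4 and P5 are
upsampled ×2 and ×4 to P3 resolution and the three scales contribute
$c_3 + c_4 + c_5 = k$ channels (default split 24/6/2 for $k = 32$).  The
constraint is enforced by construction: an `hpaConfig()` whose split does not
sum to $k$ is rejected.

The geometry of the upsampling pathway is a genuinely open design point, and
several choices reproduce the same headline behaviour.  podkit fixes it as
follows (the `parallel_convT` variant):

* P3 → 1×1 convolution to $c_3$ channels;
* P4 → transposed convolution (kernel 2, stride 2) at working width 64,
  then a 3×3 projection to $c_4$;
* P5 → transposed convolution (kernel 4, stride 4) at width 64, then a 3×3
  projection to $c_5$;
* channel concatenation to $k$, then a C2f block fusing back to the
  prototype stem width of 64 — the prototype stem itself is untouched.

Projecting *after* a full-width learnable upsampling (rather than before,
which would be cheaper) is deliberate: the upsampling stage then works on the
full feature space and the per-split projections stay small, which matches
the observed near-independence of the variant's parameter total from the
split and lands the composed total exactly on the published accounting
(3.586 M parameters for 24/6/2).  The cascaded variant chains two ×2 stages
through a P5+P4 concatenation; the interpolation variant replaces the
learnable upsamplings with nearest neighbour and is correspondingly lighter.

# The U-shaped prototype decoder with EMA attention

The second modification rebuilds the prototype branch as a U-shaped decoder
whose output sits at **one quarter** of the input resolution (160×160 at 640
px), to help small objects.  Two forms exist:

* **P3-only graph**: a local U — 3×3 convolution at P3 resolution, a 2×2
  max-pooled trough, two ×2 upsampling stages, a 3×3 refinement at quarter
  resolution, and the 1×1 projection to $k$ planes.  With
  `upsample_mode = "nearest"` the upsampling is parameter-free (3.242 M on
  the baseline); with transposed convolutions it costs two ConvT(64,64,2,2)
  stages (3.275 M).
* **Graph with HPA**: the decoder spans the pyramid itself — it starts at
  P5, upsamples, fuses P4, upsamples, fuses P3, and upsamples once more to
  quarter resolution, with 3×3 convolutions at every stage.  This *subsumes*
  the HPA upsampling pathway, with an observable consequence the accounting
  reproduces: the composed model's parameter total (3.537 M) no longer
  depends on which HPA upsampling variant was configured.

EMA (efficient multiscale attention) blocks follow each convolution of the
prototype branch when `use_ema = TRUE`.  The block reshapes channels into
groups (channel-to-batch), runs a 1×1 branch over pooled height/width
profiles and a 3×3 spatial branch, and fuses them by cross-spatial weighting
— no channel dimensionality reduction anywhere.  The group count defaults to
32, the published module's default, making each block a few dozen
parameters; `emaLayer()` exposes the numeric forward pass, which tests pin
against a straight-loop re-implementation.  Two numerical choices are ours:
the 3×3 branch uses replicate padding (so a constant input produces a
spatially uniform response — a contract the tests assert) and
cross-correlation orientation, the convention of every deep-learning
framework.

## What the accounting does and does not reproduce

The printed totals this implementation reproduces to the third decimal:
baseline 3.258, prototype counts 16/128 → 3.110/4.113, P3–P4-only 2.161,
HPA-parallel 3.586, U-decoder nearest/convT 3.242/3.274, and the composed
model 3.537 (identical across HPA variants).  Two published figures are not
reproducible under any uniform rule we found and are left as documented
discrepancies rather than fitted: the prototype-count-64 row (3.487; this
accounting gives 3.482) and the standalone cascaded/interpolation variants'
totals.  GFLOPs for the modified variants land within a few tenths of the
published figures but are not exact under the fixed convention; parameters,
not FLOPs, pin the geometry.

# Mask evaluation

* `maskIoU()` — $|A \cap B| / |A \cup B|$; two empty masks score 1.0 (a
  degenerate case real data never meets, but the definition must total).
* `postprocess()` — confidence threshold (default 0.3) then greedy NMS on
  **box** IoU (default 0.5), descending confidence, ties by input index.
* `matchInstances()` — greedy one-to-one matching on **mask** IoU (this is a
  segmentation benchmark; boxes are only an NMS device), confidence order,
  IoU ties by truth index.  Count conservation (`tp + fn =` #truths,
  `tp + fp = ` #predictions) is asserted property-style.
* `averagePrecision()` — the area under the confidence-ranked
  precision–recall curve with 101-point interpolation (the COCO convention),
  switchable to the exact all-point envelope.  mAP@50 and mAP@50–95 (IoU
  0.50:0.05:0.95) derive from it; mAP@50–95 ≤ mAP@50 always.

Pixel geometry is one convention everywhere: 0-based, half-open boxes
$[x_1,x_2) \times [y_1,y_2)$, x rightwards, y downwards, and a pixel belongs
to a polygon iff its centre lies inside under the even-odd rule.  Mask →
polygon conversion traces component boundaries along the pixel lattice, so
the round trip is exact for 4-connected components (holes are filled; parts
separated by cropping become multiple polygons of one instance).

# Frame harvesting (NR-IQA)

Videos are decomposed at one frame per second (`extractFrames()`: frame at
$t = 0$, then every interval, capped by availability — the boundary rule is
tested against a manual index oracle).  Four indicators score each frame:

| indicator | definition | range | degenerate value |
|---|---|---|---|
| clarity | variance of the 4-neighbour Laplacian response (valid interior) | $[0,\infty)$ | 0 on constants |
| edge sharpness | mean squared Sobel gradient magnitude (Tenengrad) | $[0,\infty)$ | 0 on constants |
| entropy | Shannon entropy of the 256-bin 8-bit histogram | $[0,8]$ bits | 0 on constants |
| co-occurrence energy | angular second moment of the symmetric GLCM, 32 grey levels, offsets (0,1) and (1,0) averaged | $(0,1]$ | 1 on constants |

These are standard formulations chosen for the stated screening roles;
grayscale conversion uses the standard luma weights.  All four are invariant
to flips, and the two detail indicators decrease monotonically under
increasing Gaussian blur of a fixed scene — both tested.

`twoStageFilter()` applies loose stage-1 bounds to every frame, then
per-subset stage-2 bounds (each subset of a field campaign has its own
lighting and variety, so thresholds are tuned per subset); stage 2 may never
be looser than stage 1 on a shared indicator, and every dropped frame is
audited with its stage and failing indicator(s).  Because absolute thresholds
are campaign-specific, the shipped default (`looseProfile()`) is
dataset-relative: keep above the 5th percentile of each detail indicator and
below the 95th percentile of co-occurrence energy (near-blank frames score
maximal energy).

# The synthetic test bench

`generateScene()` renders what the imaging protocol produces, as a cartoon:
a bright solid backdrop, `n_pods` filled rotated ellipses with mild boundary
wobble (pods), optional elongated quadrilateral "stems" and broad "leaves"
drawn over them, then blur and noise.  Ground truth stores the *visible*
(post-occlusion) masks, matching how field annotations are drawn; an
occluder is redrawn rather than allowed to hide a pod completely, and
unsatisfiable placements raise an error after bounded retries.  Everything is
bitwise deterministic per seed.  `generateClip()` pans a window across a
wider scene with per-frame jitter and a blur schedule, emulating handheld
scanning for the harvesting pipeline; clips are PNG-sequence objects, the
representation the toolkit uses throughout (video container decoding is out
of scope here).

What the cartoon deliberately lacks — real pod texture, specular lighting,
plant architecture, motion blur anisotropy — bounds what passing tests mean:
they certify the *machinery* (geometry, accounting, evaluation, filtering)
on controlled inputs, not field performance of any trained model.

# The toy trainer

`trainToy()` exists to exercise the prototype-coefficient pathway end to end,
not to replicate any full-scale recipe.  It is a deliberately small model in
plain R: a fixed per-pixel feature stack (colour channels, grayscale, blurred
grayscale, gradient magnitude, bias) feeds trainable linear heads — cell
objectness, box geometry, $k$ prototype planes and per-cell coefficients.
Training is plain SGD on a composite loss: class-balanced binary
cross-entropy on objectness, squared error on box geometry at positive cells
(centre-based assignment: the cell containing the instance's box centre),
and per-instance binary cross-entropy between the assembled logistic mask
and the ground truth, **cropped to the dilated instance box** so that other
instances outside it do not supply conflicting supervision — the standard
device in this model family.  Gradient norms are clipped; each step draws one
scene and a random flip/rotation/crop combination; everything is
deterministic per seed.

At prediction time masks are assembled inside dilated decoded boxes, each box
is tightened to its mask's extent (duplicate candidates then collapse onto
the same box), and greedy NMS plus the 0.3/0.5 inference thresholds produce
the final set — all through the same exported operations the evaluator uses.
The end-to-end check trains on 32 easy scenes (96×96 px, three large disjoint
unoccluded pods each, 300 steps — sizes chosen to keep the whole suite quick
on one core) and requires a falling loss and mAP@50 ≥ 0.5 on held-out scenes;
typical runs reach ≈ 0.8 with full recall.  An untrained model scores ≈ 0.

# Known limitations

* The accounting reproduces fused parameter totals; activation memory,
  latency and training-time statistics are out of scope.
* The two published figures noted above (prototype-count-64 row; standalone
  cascaded/interpolation totals) are documented, not fitted.
* `extractFrames()` consumes frame sequences or in-memory clips; compressed
  video containers are not decoded.
* Mask vectorisation represents outer boundaries only — masks with interior
  holes rasterise back filled.
* The toy trainer's linear heads cannot learn texture; it is a test vehicle.
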