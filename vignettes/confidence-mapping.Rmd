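---
title: "Diffuse characterization of retinal fluid with voting confidence maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffuse characterization of retinal fluid with voting confidence maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diabetic macular edema (DME) destroys the layered structure of the retina by
fluid leakage from damaged vessels. In optical coherence tomography (OCT)
B-scans the clinical literature distinguishes three accumulation patterns:
cystoid macular edema (CME, hyporeflective pockets with cellular walls),
diffuse retinal thickening (DRT, spongiform accumulation without defined
limits), and serous retinal detachment (SRD, dome-shaped fluid under the
outer retina). DRT in particular cannot be delimited by a crisp segmentation
boundary: its texture and gray levels shade into normal tissue, and expert
annotations of such regions carry intrinsic *uncertainty* — areas known to be
pathological whose subtype cannot be assigned with confidence.

`octfluid` implements the *diffuse paradigm* for this problem. Instead of
segmenting fluid boundaries, a convolutional classifier is trained on small
labeled windows, and a per-pixel **confidence map** is produced by sliding
overlapping windows over the retina and letting every window vote for the
class of each pixel it covers. The confidence of class $c$ at pixel $p$ is

$$\mathrm{conf}_c(p) = \frac{\#\{\text{windows covering } p \text{ classified } c\}}
                            {\#\{\text{windows covering } p\}},$$

so a confidence of 0.8 for CME means 80% of the windows covering that pixel
were classified as CME. Proportions over the four classes sum to 1 wherever
at least one window casts a vote.

## Window sampling and cross-validation

Training samples are 64 px × 64 px windows centered on labeled pixels, up to
25 per label present in an image, drawn uniformly **without replacement**
(drawing with replacement would duplicate patches; the protocol wording does
not force either choice, and labels with fewer than 25 candidate centers
contribute all of them rather than discarding the image). Windows reaching
past the image border are completed by mirroring, using the reflection that
does not repeat the border pixel — stated explicitly so tests can be
bit-exact. In our 1-based convention a window of even side $w$ centered at
row $r$ spans rows $r-w/2, \dots, r+w/2-1$.

Images are assigned to 6 folds at image level (never at window level), so no
window of one image can appear in two roles. All assignments of the folds
into 3 training / 2 validation / 1 test are enumerated — 60 experiments —
and metrics are reported as mean ± sd over the grid. Fold assignment is
uniformly random without stratification: the full combination grid absorbs
residual imbalance.

## The classifier and the three regimes

The backbone is a densely connected convolutional network. The
`densenet161` variant follows the standard DenseNet-161 configuration
(7×7 stride-2 stem, 3×3 stride-2 max pooling, dense blocks of 6/12/36/24
bottlenecked BN–ReLU–1×1–BN–ReLU–3×3 layers, growth rate 48, compression
0.5 — growth and compression are the standard values, which the protocol
does not restate; on a 64×64 patch the stages measure 32, 16, 8, 4, 2 px).
Convolutions receive Kaiming initialization, linear layers uniform, and a
terminal softmax yields the class distribution. Because no deep-learning
framework is available (or needed) at this scale, the layers, their
backward passes, and the AdamW+AMSGrad optimizer are implemented directly
in R on top of BLAS matrix multiplication (convolution via im2col); an
analytic-vs-numerical gradient test guards the implementation. A `reduced`
variant (default blocks 2/2/2, growth 10, 3×3 stem) keeps the identical
topology at desk scale; all regime logic is variant-agnostic.

Training is shared by all regimes: class-weighted cross-entropy (each
sample's loss multiplied by its class weight — the weighting mechanism is
not dictated by the protocol; loss weighting is deterministic and
test-friendly, and validation loss uses the same weights so regimes are
comparable), AdamW with AMSGrad, learning rate and decoupled weight decay
0.01, betas (0.9, 0.999), epsilon 1e-8, batch size 250 for the full variant
(scaled down to 64 for the reduced one so desk-scale runs still take several
optimizer steps per epoch), random horizontal flips with probability 0.5,
learning rate × 0.66 after 10 epochs without validation improvement, early
stop after 25, and the returned model is the best-validation-loss snapshot.
"Improvement" means a decrease of at least 1e-6 (the protocol states no
tolerance). The class weight of, e.g., the healthy class is
$(\mathrm{CME}+\mathrm{DRT}+\mathrm{SRD})/\mathrm{healthy}$, and analogously
for each class.

The three regimes differ in what the network knows before fine-tuning:

1. **Baseline** — trained from scratch on the four defined classes;
   uncertainty-centered samples are discarded.
2. **Generalist transfer** — a backbone pretrained on a wide-spectrum
   generalist corpus has its head replaced by the four target classes
   (keeping every other weight bit-for-bit) and is fine-tuned like the
   baseline. At desk scale, where no external weights are available, a
   synthetic *pretext task* of four generic texture families (gradients,
   speckle, gratings, blobs) stands in for the generalist corpus; the model
   provenance records this.
3. **Uncertainty-aware two-stage transfer** — stage 1 trains a *binary*
   classifier, healthy versus pathological, where the pathological side
   pools CME, DRT, SRD **and the uncertainty samples** (healthy weight
   $(\mathrm{U}+\mathrm{CME}+\mathrm{DRT}+\mathrm{SRD})/\mathrm{healthy}$,
   pathological weight its reciprocal). Stage 2 replaces the head with the
   four subtypes and fine-tunes on defined labels only. The filters learned
   from uncertain tissue in stage 1 survive into stage 2 even though no
   uncertainty sample is ever shown there. Both stages use the same
   training protocol, including the early-stopping budget (the protocol
   does not say otherwise).

## Metrics

Per class, one-vs-rest: accuracy, precision, recall, F1 (harmonic mean of
precision and recall), Matthews correlation coefficient, and the
Mann–Whitney AUC with the tie convention
$\mathrm{AUC} = \sum_{i,j} I(x_i, y_j)/nm$, $I = 1$ if $x>y$, $\tfrac12$ if
equal, $0$ otherwise (computed through midranks, algebraically identical to
the double loop and verified against it exhaustively in the tests). Hard
labels are the argmax with ties broken by the lowest class index. The
overall row is the class-support-weighted mean of the per-class values; an
unweighted mean is also available because the exact aggregation used for
published tables of this kind is usually not printed. Zero-denominator
ratios are reported as undefined (`NA`) rather than silently zero, with an
explicit flag to map them to 0 in aggregate rows.

## Confidence maps and their analysis

Maps use windows of 64 px with 60 px overlap (stride 4). The lattice is
anchored at the ROI bounding box by default (anchoring to the image is a
config option; the choice is not dictated by the protocol), windows are kept
if they intersect the ROI at all, trailing origins are appended so the far
edges are covered — full coverage is required for the voting denominator —
and votes are hard argmax labels, since the confidence is *defined* as a
proportion of labeled windows, not an average of probabilities. Only images
from folds never seen in training should be mapped. Rendering uses a
piecewise-linear cold-to-warm palette whose change is concentrated between
confidence 0.35 and 0.65 (steep mid-range), alpha-blended over the
grayscale B-scan inside the ROI.

For analysis, the 4-connected components (4-connectivity chosen as the
conservative reading and stated for test exactness) of each class in the
reference mask are scored by the maximum map confidence inside them, giving
a (size, max confidence) point cloud per class. A trend is computed by
sliding a window covering 1000 px of component size in steps of 10,
taking the median confidence per window (closed-open size intervals for
determinism; the window slides over size values, the literal reading of a
"range of sizes", not over sorted ranks), and smoothing the support points
with an interpolating cubic b-spline evaluated at 10 points. An inherent
property of voting maps reproduces here: a component much smaller than the
window can never be covered predominantly by windows centered inside it, so
its maximum confidence is bounded below 1 and grows with component size.

## What the phantoms emulate — and what they do not

Since the clinical dataset behind this methodology is private, the package
ships a synthetic phantom generator so every stage is testable end to end.
A phantom is a retina band between two smooth random cubic curves (an
ILM-like top and an RPE-like bottom — reproducing the curved ROI geometry
without any layer segmentation), with sinusoidal intra-retinal banding,
per-label Gaussian texture, and multiplicative log-normal speckle (OCT noise
is speckle-dominated). CME appears as hyporeflective ellipses, DRT as a
larger high-variance ellipse, SRD as a dome resting on the retinal floor.
Every planted region is wrapped in an *uncertainty halo* (Chebyshev width 3
by default), emulating the labeling protocol in which border pixels are
never assigned a definite class; standalone diffuse uncertainty patches can
also be planted. Default means on the unit intensity scale (healthy 0.58,
CME 0.10, DRT 0.38, SRD 0.16, speckle sd 0.12) give a healthy–pathology
contrast of at least 0.2 — the prevalence of each fluid type per image is
not quantified anywhere, so prevalences are free parameters with defaults
(CME 0.8, DRT 0.6, SRD 0.5) chosen once to make most phantoms multi-class.
Output is 8-bit by default, 16-bit behind a flag.

Phantoms are deliberately *easier* than clinical OCT: classes are separable
mostly by first-order intensity statistics, there is no vendor-specific
processing, no shadowing vessels, no lipid deposits, no motion artifacts.
Passing the learning tests therefore shows that the training regimes,
weighting, scheduling and voting machinery are implemented correctly — not
that the reduced network would reach clinical accuracy on real scans.
Published results at clinical scale are out of this package's reach by
construction and are not reproduced.

## Numerical and scale choices

Desk-scale test conditions: 8 phantoms of 160×256 px, 12 samples per label
at 32 px windows, 4 folds split 2/1/1, the reduced backbone
(blocks 2/2, growth 8, 12 stem channels), and a 25-epoch cap — sizes at
which one regime trains in tens of seconds while all contracts (weighting,
scheduling, head replacement, best-snapshot selection) are exercised
verbatim. The learning-sanity check runs all three regimes over five seeds
and requires >90% four-class test accuracy in at least four of them. The
full-scale profile (356 images, 6 folds, 60 splits, DenseNet-161, batch
250) is wired through the same code path via the CLI's `--profile full`.

Degenerate inputs are handled explicitly: empty ROIs, absent classes
(flagged unsupported in reports), all-positive or all-negative score lists
(AUC undefined), too few trend support points (raw medians with a warning),
and windows larger than twice the image extent (mirroring is no longer
defined) are errors or flagged results, never silent zeros.

## Known limitations

* The uncertainty-sampling rule admits all mask pixels labeled uncertain;
  by phantom construction these are inner-retina pixels, so the "borderline
  regions" clause for vitreous/choroid samples never triggers on synthetic
  data.
* Pixel coverage near the deepest/shallowest ROI rows comes from windows
  whose centers lie further inside the band; classes hugging the ROI floor
  (SRD) receive fewer center-based votes, which depresses their maximum map
  confidence relative to interior classes. This is a property of the
  paradigm, visible already on phantoms.
* Batch-norm running statistics make the validation loss of the first few
  epochs noisy; best-snapshot selection is unaffected.
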