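---
title: "The Explainability Consistency Score: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Explainability Consistency Score: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecscore)
```

## The problem

Deep-learning graders of diabetic retinopathy (DR) reach specialist-level
accuracy, but clinical adoption hinges on whether their attention is in the
right place. Saliency ("heatmapping") techniques attach a per-pixel
importance value to a model's score; retinal specialists independently
produce pixel-level segmentations of the four canonical DR lesion types —
hemorrhages (HE), microaneurysms (MA), soft exudates (SE) and hard exudates
(EX). The question this package quantifies: *do the image regions a heatmap
ranks as most important coincide with the regions experts marked as
lesions?*

Pixel-level overlap metrics (Dice, IoU) answer this badly, for three
reasons. Heatmap styles differ wildly — region-based methods mark broad
blobs while gradient methods mark scattered individual pixels, so any
pixel-exact criterion ranks the two families incomparably. Exact pixel
agreement is also an unreasonably strict demand on an attribution method
whose job is to indicate *where* the evidence is, not to segment it. And an
unweighted pixel count lets the rarest, most diagnostically decisive lesions
vanish: microaneurysms are the hallmark of early DR yet contribute about 1%
of annotated lesion pixels.

## The score

Both maps are reduced to an $S \times S$ grid overlaid on the $N \times N$
image. With cell width $d = N/S$, the discretized expert segmentation
weights each lesion type's pixel count:

$$
DE_{i,j} \;=\; w_{HE}\!\!\sum_{(p,q)\in c_{ij}}\!\! HE_{p,q}
\;+\; w_{MA}\!\!\sum_{(p,q)\in c_{ij}}\!\! MA_{p,q}
\;+\; w_{SE}\!\!\sum_{(p,q)\in c_{ij}}\!\! SE_{p,q}
\;+\; w_{EX}\!\!\sum_{(p,q)\in c_{ij}}\!\! EX_{p,q},
$$

where $c_{ij}$ is the pixel block of cell $(i,j)$. The heatmap is
discretized the same way without weighting, $DH_{i,j} = \sum_{(p,q) \in
c_{ij}} H_{p,q}$, because heatmaps carry no lesion identity. The
Explainability Consistency Score is then

$$
\mathrm{ECS}(DE, DH) \;=\;
\frac{\left|\,\mathrm{top}_K(DE) \cap \mathrm{top}_K(DH)\,\right|}
     {\min\!\big(K,\; \mathrm{nnz}(DE)\big)},
$$

the fraction of the expert's $K$ most lesion-dense cells that the heatmap
also places in its own top $K$. Dividing by $\min(K, \mathrm{nnz}(DE))$
rather than $K$ keeps the score in $[0,1]$ on images with fewer than $K$
annotated cells, so it reads as a percentage of the achievable agreement.
The discretization makes the score insensitive to heatmap style (blobs vs
scattered pixels within a cell are equivalent), and the weighting makes a
microaneurysm cell able to compete with a hemorrhage cell for top-$K$
membership.

## Lesion weights

Weights follow the inverse-frequency rule $w_t = \max_u n_u / n_t$ over
corpus lesion-pixel counts $n_t$, so the most frequent type anchors at 1.
Two sources are kept strictly separate:

* `derive_weights(count_lesion_pixels(corpus))` applies the rule to your
  own corpus;
* `lesion_weights_preset("idrid-paper")` returns the published constants
  for the IDRiD expert segmentations verbatim:
  $w_{HE}=1,\; w_{EX}=1.05,\; w_{SE}=5.77,\; w_{MA}=46.97$.

The published constants are close to, but not exactly, the ratios of the
rounded corpus percentages (47/44/8/1 gives 1, 47/44 ≈ 1.068, 47/8 = 5.875,
47), presumably because they were computed from unrounded counts on a
particular training split. The preset therefore stores the printed values
untouched, and the two routes are never mixed silently. A lesion type with
zero corpus pixels has no defined weight; `derive_weights()` stops with
guidance instead of emitting `Inf`.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `S` (grid size) | 10 | 10×10 cells give region-level granularity an ophthalmologist can act on, and are coarse enough that blob-style and pixel-style heatmaps become comparable. |
| `K` (top cells) | 15 | The number of highest-mass cells compared; 15 of 100 cells covers the lesion extent of typical DR-positive fundus images. Sweeps over {10, 15, 20} are built in (`sensitivity_sweep()`), and method rankings should be — and in our synthetic checks are — stable across them. |
| `weights` | `"idrid-paper"` preset | See above. |
| channel reduction | `"abs-max"` | Three-channel gradient maps are collapsed by the per-pixel maximum over channels. The default takes absolute values first, because signed gradient maps carry evidence in both directions and a literal signed max would discard strong negative attributions; the literal `"max"` mode (negatives clipped afterwards) is available for fidelity to the simpler convention. |
| bootstrap | percentile, 10 000 resamples | See below. |

## Numerical and procedural choices

**Cell indexing.** Cells are 0-based conceptually, 1-based in R, row-major,
with half-open pixel blocks $[i\,d, (i{+}1)\,d)$. When $N$ is not divisible
by $S$, the trailing $N \bmod S$ rows/columns join the last cell row/column
— boundary cells are slightly larger, and no annotated pixel is ever
dropped. Rectangular images use independent cell widths per axis.

**Top-K eligibility and ties.** Only strictly positive cells can enter a
top-$K$ set: on sparse maps with fewer than $K$ positive cells the set is
simply smaller, which keeps a score of 0 attainable and meaningful (a
heatmap that marks nothing relevant should not collect overlap credit from
zero-valued cells). Ties are broken deterministically — value descending,
then row-major index ascending — so scores are bit-reproducible; a seeded
random tie mode exists for sensitivity checks. The heatmap side having
fewer than $K$ positive cells is handled by the same eligibility rule.

**Empty expert annotations.** An image with no annotated lesion has an
undefined score (`nnz(DE) = 0` would divide by zero). Such images raise a
typed condition and are excluded from averages with a logged skip — the
evaluation targets DR-positive, lesion-annotated images.

**Random-importance baseline.** The chance floor is the expected ECS of a
heatmap whose cell ranking is uniformly random. We randomize *cell* values
(iid uniform), not pixel values: cell sums of iid pixel noise concentrate
sharply around their common mean, which would produce a near-deterministic
ranking rather than a uniformly random one. For a fully positive expert
grid the expected score has the closed hypergeometric form
$K \cdot \min(K,S^2) / S^2 / \min(K, \mathrm{nnz})$ — at $S=10$, $K=15$
this is 0.15, and the simulated baseline reproduces it within Monte-Carlo
error.

**Bootstrap confidence intervals.** Dataset means are accompanied by
nonparametric percentile-bootstrap CIs over images (default 10 000
resamples, seeded). Strata with a single image (severity grading of small
datasets routinely produces such strata) report a mean without a CI rather
than a meaningless degenerate interval.

**Integrated Gradients quadrature.** `integrated_gradients()` approximates
the path integral with a *midpoint* Riemann sum (default 64 steps). The
midpoint rule's $O(1/\text{steps}^2)$ error keeps the completeness identity
$\sum_i a_i = f(x) - f(x_0)$ tight at moderate step counts (relative error
around $10^{-5}$ at 256 steps on smooth scorers), where an endpoint rule's
$O(1/\text{steps})$ error would still sit near $4 \times 10^{-3}$; both are
exact for linear scorers.

**SmoothGrad family.** `smoothgrad()`, `smoothgrad_squared()` and
`vargrad()` share one noise pipeline, so with equal seeds they see the same
perturbed inputs and the variance identity
$\mathrm{VarGrad} = \mathrm{SG}^2 - \mathrm{SG} \odot \mathrm{SG}$ holds on
the sample level. VarGrad uses the population ($1/n$) variance. Defaults
$\sigma = 0.15\,(\max x - \min x)$ and 25 samples are the conventional
choices for these ensembles. $\sigma = 0$ short-circuits to the exact
degenerate results (the plain gradient, its square, and the zero map).

**Gradient provider, not a network.** All attribution methods consume a
`score_function()` — a scalar scorer plus its per-pixel gradient. The
methods are architecture-independent given gradients, so any model can
stand behind this contract; a central finite-difference provider is
constructed automatically when no analytic gradient is supplied, and the
two agree to $10^{-4}$ relative on smooth test functions.
Architecture-bound techniques (Grad-CAM and its layer selection, Guided
Backpropagation, DeconvNet, LRP variants) are deliberately out of scope:
they require access to a network's internal activations and modified
backward passes, which is the province of deep-learning frameworks.

## The synthetic generator

`generate_mask_set()` emulates the *structure* of expert lesion
annotations: four aligned binary masks per image, with HE/EX/SE as filled
axis-aligned ellipses and MA as 1–4 pixel dots. The default geometry — per
100×100 image, 3 HE ellipses with semi-axes 3.5–6.5 px, 6 EX at 2.5–4.5 px,
1 SE at 3–4.5 px, 2 MA dots — was chosen from expected ellipse areas
($\pi a b$) so a corpus realizes the severely imbalanced pixel profile of
real expert segmentations, about 47% HE / 44% EX / 8% SE / 1% MA of lesion
pixels; a 50-image corpus lands within ±20% relative of that profile.
Severity grades are sampled from the empirical grade distribution of a
54-image DR-positive tuning set (1/18/16/19 images of grades 1–4).

`generate_heatmap_with_overlap()` constructs heatmaps whose ECS is known
*exactly*: it works in discretized cell space — choose
$\mathrm{round}(qK)$ of the expert's top-$K$ cells and $K -
\mathrm{round}(qK)$ cells outside that set, assign descending distinct
masses, paint each chosen cell's mass as a per-pixel constant — so
discretization recovers the construction and the score equals
$\mathrm{round}(qK)/K$ by arithmetic, not approximately. This turns the
whole scoring pipeline into a parameter-recovery experiment.

What the generator does *not* emulate: fundus photograph appearance
(vessels, optic disc, illumination), lesion texture and irregular
morphology, annotation noise, or any dependency between a trained model's
attention and lesion positions. Morphological realism is unnecessary for
the score itself — ECS depends only on pixel membership in cells — but it
means passing tests certify the *metric machinery*, not any claim about how
real models attend to real retinas. Scores on real datasets require the
real images, masks and models.

One test fixture deserves a note: the end-to-end chain check scores the
gradient map of a disk-sum scorer against the HE-only expert map. A
disk-sum scorer has a single disk, so the aligned fixture uses one HE
lesion per image and centres the disk on that lesion's bounding circle;
with several scattered lesions a single disk cannot represent an "aligned"
model and the check would measure geometry, not the pipeline.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic data
at these sizes, chosen to exercise every code path at desk scale: 100×100
images on a 10×10 grid ($K = 15$); 1 000 random cell maps (grids up to
10×10, $K \le 20$) against a brute-force enumeration oracle; 200 fixtures
per overlap level $q \in \{0, 0.2, ..., 1\}$; 10 000 draws for the random
baseline; 54-image tuning and 27-image test corpora for the reporting
pipeline, mirroring the split sizes of the motivating study design.

## Known limitations

* The score compares *sets* of top cells; it is blind to ranking quality
  inside the top-$K$ and to near-miss mass just outside it.
* Published weights and any derived weights depend on the annotation corpus;
  transferring a preset to a corpus with different lesion statistics changes
  the meaning of $DE$.
* The bootstrap CI procedure is the package's choice of interval; with very
  small image counts (n < ~20) percentile intervals are themselves noisy.
* `fixture_params()` draws lesion positions uniformly; real lesions cluster
  anatomically (e.g., around the macula), which can only matter for methods
  whose attributions have matching spatial priors.
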