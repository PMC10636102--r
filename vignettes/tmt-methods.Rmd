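---
title: "Temporalis muscle morphometry and growth charts: models and methods"
author: "TMTmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporalis muscle morphometry and growth charts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

TMTmorph measures temporalis muscle thickness (TMT) and cross-sectional
area (CSA) from T1-weighted brain MRI and turns cohort measurements into
sex-specific growth centile charts. The temporalis muscle is a practical
imaging surrogate for lean muscle mass: brain MRI is acquired routinely in
paediatric care, so an automated, reproducible TMT readout enables
opportunistic screening for sarcopenia without extra scans. This vignette
explains the models the package implements, the choices that were open and
how they were settled, and what the synthetic validation does and does not
establish.

## Pipeline overview

For one subject the pipeline is:

1. **Preprocessing** — resample to 1 mm isotropic (trilinear), median
   filter (radius 1 voxel), Otsu background removal, z-score over the
   Otsu foreground, robust rescale to [0, 1].
2. **Slice selection** — locate the axial slice at the superior orbital
   roof by regressing, from 5 mm maximum-intensity-projection (MIP) slabs
   resized to 256 x 256, the signed mm offset from each slab to the
   landmark; a sweep of candidate slabs is aggregated by the median.
3. **Segmentation** — segment both temporalis muscles on the selected
   slice at a 512 x 512 working resolution, predicting four overlapping
   tiles, binarising at 0.5 and majority-voting per pixel; the largest
   connected component per side is kept.
4. **Morphometry** — TMT per side is the minimum Feret diameter of the
   mask (rotating calipers on the pixel-corner hull); CSA is pixel count
   times pixel area; the bilateral mean is reported.
5. **Centiles** — a fitted LMS model converts (age, sex, TMT) to a centile.

All geometry is computed in millimetres using the NIfTI voxel spacing;
volumes are reoriented to RAS on load so "left"/"right" are fixed by the
data layout (the radiological display convention is a config flag).

## Preprocessing choices

The chain runs in the order listed above. Two points were genuinely open:

* **Z-score region.** Statistics are computed over the Otsu foreground
  only; including the large zero background would bias the mean far below
  tissue intensity and make the scale depend on the field of view.
* **Intensity standardisation.** The final standardisation maps the 0.5th
  and 99.5th percentiles to 0 and 1 with clipping. The anchors are
  *whole-volume* percentiles: the low anchor then sits inside the
  background cluster, so the background/tissue intensity gap survives the
  map. Anchoring on foreground percentiles instead stretches the darkest
  tissue onto the background; a second pass of the chain then draws a
  different Otsu foreground, and preprocessing stops being stable under
  repetition. With whole-volume anchors, re-preprocessing an already
  preprocessed volume changes voxels by well under 5% RMS, which is the
  stability property the test suite asserts.

The median-filter radius (1 voxel) and histogram size (256 bins) are
defaults exposed in the `[preprocess]` config block.

## Slice selection

Training examples are MIP slabs with labels `offset = target z − slab z`
in mm (labels in mm rather than slices keep the model meaningful across
slice spacings). At inference the package sweeps a candidate band (by
default the central third of the volume), converts each predicted offset
into an implied target index, and takes the median. The median tolerates
up to half the candidates being wrong, which the suite checks by
corrupting 40% of predictions. The MAD of the implied targets is reported
as a dispersion; above 4 mm a warning is logged but measurement proceeds,
since craniocaudal shifts of this size change the thickness measurement
only marginally (the phantom muscles, like the real muscle near the
orbital roof, have nearly constant cross-section over several mm).

The deployable model behind this interface is a contract
(`SliceRegressor`): anything deterministic that maps a MIP slab to an
offset. The reference implementation is deliberately small — a
one-hidden-layer perceptron (32 tanh units) on the 16 x 16 downsampled
slab, trained with Adam on mean squared error for 30 epochs, batch 64. A
pure linear readout was tried first and left a systematic multi-slice
bias on held-out phantoms: slab appearance varies nonlinearly with
position through the head taper, and the hidden layer removes that bias.
Large-scale backbones and their published weights are out of scope; the
contract is the integration point.

## Segmentation, voting and the loss

The `Segmenter` contract maps an image tile to per-pixel probabilities.
The reference model is a two-level U-Net (3x3 convolutions, one 2x2
max-pool, nearest-neighbour upsampling with a skip concatenation, 1x1
output head) with forward and backward passes written directly in R as
BLAS matrix products; it trains on CPU in minutes and overfits 32 phantom
slices to a training Dice above 0.8 within 30 epochs, which is the
training-sanity bar the acceptance suite holds it to.

Training minimises the focal Tversky loss,
`(1 − TI)^(1/gamma)` with `TI = (TP + s)/(TP + alpha FN + beta FP + s)`
on soft counts; defaults `alpha = 0.7, beta = 0.3, gamma = 4/3` weight
false negatives harder, appropriate for a thin structure. With
`alpha = beta = 0.5, gamma = 1` the loss reduces exactly to one minus
soft Dice, and the suite verifies that identity to 1e-9.

Tile voting: four tiles shifted by (±d, ±d) around the region of
interest, binarised predictions accumulated into a vote grid, and a
strict majority (ties negative — conservative for thin muscles) decides
each pixel. The geometry guarantees at least three votes per ROI pixel
only when `tile ≥ roi + 2d`; with symmetric shifts and in-bounds windows
the per-pixel count is otherwise 1, 2 or 4, never exactly 3, so the
package constructs layouts with `tile = roi + 2d` and *counts* coverage
exhaustively rather than assuming it. Voting over independently corrupted
oracle predictions (10% salt-and-pepper) restores Dice ≥ 0.95, which is
what the redundancy is for.

## Morphometry

TMT is the minimum Feret diameter: the smallest distance between two
parallel supporting lines of the mask. Each foreground pixel contributes
its four corners (pixel-as-area model), so a bar w pixels wide measures
exactly w mm at 1 mm spacing; the convex hull of the corner cloud is
taken and the minimum width is found flush with a hull edge (rotating
calipers). This realises "thickness perpendicular to the long axis"
without estimating the axis, and it is orientation-invariant. Two
consequences are documented rather than hidden: rasterised *rotated*
shapes measure up to one pixel diagonal above their continuous width
(corner model inflation), and implementations using pixel centres would
read systematically ~1 px lower. The brute-force reference used in the
tests enumerates every pairwise point direction — the complete set of
directions at which a flush minimum can occur — and agrees with the
calipers to 1e-9; a uniform dense angular grid can only overshoot, by
about `size x step / 2` at its resolution, so it serves as an upper-bound
check rather than the equality oracle.

Multi-component masks are rejected in morphometry; component cleanup is
segmentation's responsibility. The bilateral mean halves the sum of both
sides; with one side missing the present side is reported with a flag.

## LMS growth charts

Cohort TMT is modelled with the classical LMS (Box-Cox Cole-Green)
family: at age t the measurement is Box-Cox normal with median M(t),
coefficient of variation S(t) and skewness power L(t); the z-score is
`z = ((y/M)^L − 1)/(L S)` (log branch as L → 0, switched at |L| < 1e-8),
a centile is `100 Φ(z)`, and the density is truncated to y > 0
(normalising constant `Φ(1/(S|L|))`). Conversions are exact inverses of
each other; the round trip is verified to 1e-8.

The fit maximises the exact BCCG log-likelihood with `optim` (BFGS) over
natural-cubic-spline coefficients for log M(t) and log S(t) (log links
keep both positive on the whole domain) and a constant-or-linear L(t).
Degrees of freedom per curve are selected jointly by BIC
(`−2 loglik + k log n`, k the total coefficient count) over a candidate
grid, df 2–5 for M and S and df 1–2 for L. Fixed-df regression splines
were chosen over penalised smoothers because the parameter count in BIC
is then exact and the fit is deterministic; the df grid plays the role
the smoothing parameter would. L defaults to constant because the
skewness power is weakly identified at moderate n. Ages above 30 are
collapsed to 30 before fitting (a single 30+ category stabilises the
sparse top of the chart), and the model refuses to extrapolate outside
its fitted age domain.

Model adequacy is checked by probability-integral-transform uniformity
(fitted centiles/100 should be uniform; Kolmogorov-Smirnov at alpha
0.01) and by parameter recovery on synthetic cohorts: at n = 2000 drawn
from L = 1, M(t) = 6 + 0.3 t, S = 0.12, the fitted median curve is
recovered within 3% and S within 15% on the integer-age grid, with error
shrinking as n grows. One subtlety: because M is modelled through a log
link, a median that is *linear* on the raw scale needs one interior knot
(df 3) to be represented without a small bias floor; BIC finds this on
its own.

Two chart summaries have no canonical definition in the growth-chart
literature, so the package fixes explicit ones and does not claim
numeric equality with any published figure:

* `mmPerCentile`: the mean, over an age grid and over adjacent centile
  pairs (1,2)…(98,99), of the measurement difference per centile step.
* `centilePrecision`: the median over ages of
  `|centile(M(age) + error) − 50|`, i.e. how far a typical measurement
  error moves a median subject, with a bootstrap 95% interval over ages.

Leave-one-study-out refits (at the full fit's df) report the maximum
absolute deviation of M(t) per held-out study, flagging cohorts dominated
by a discordant study.

## Agreement statistics

Dice is `2|A∩B|/(|A|+|B|)`, with two empty masks scoring 1 (agreement on
absence; a message notes when this convention fires). The "MAE" used
throughout is a *median* absolute error — robust, with the even-length
median as the mean of the middle two. Gwet's AC1 uses mean pairwise
per-item agreement and prevalence-based chance agreement
`pe = (1/(K−1)) Σ π_k (1−π_k)`; it is stable where kappa collapses under
prevalence imbalance (acceptability ratings are heavily skewed toward
"acceptable"). The worked example (80 both-accept, 10 both-reject, 5+5
split) gives pa = 0.90, pe = 0.255, AC1 = 0.8658, and is asserted to
four decimals.

## The phantom: what it emulates and what it does not

`generatePhantom()` builds a deterministic head-like volume: an
ellipsoidal "head" with a gentle axial intensity ramp, a bright planar
ridge at the landmark slice (so slab position and the landmark are both
learnable by a regression model), and two lateral crescent "muscles"
built as annular sectors between co-centred circles. The arc radius is
large (180 mm) so the crescent's sagitta stays below half a voxel —
necessary because the minimum Feret diameter of an arc-shaped strip is
its thickness *plus* the sagitta. The arc centre is snapped to the pixel
lattice so the radial band rasterises to the intended pixel count, and
every build verifies its own truth masks against the angle-sweep Feret
reference, erroring if the built thickness is off by more than half a
voxel. Noise and blur are applied only after truth extraction. The
default grid is 128 x 128 x 96 at 1 mm with thicknesses 8 and 12 mm,
which keeps end-to-end runs to a few seconds per volume and the full
validation suite within minutes.

Synthetic cohorts draw ages uniformly and TMT from the generating BCCG
curves, optionally with per-study multiplicative offsets for LOSO tests.

What passing on phantoms shows: the plumbing is correct — geometry,
units, orientation handling, vote coverage, loss identities, aggregation
arithmetic, chart mathematics, and that the reference models can learn
the mapping when one exists. What it does not show: performance on real
MRI. The phantom has no bias field, no motion or ghosting, no anatomy
besides the two crescents, sharp tissue boundaries, and a landmark far
more salient than a real orbital roof. Accuracy figures on real cohorts
require real scans and expert annotations and are out of scope here.

## Numerical choices and degenerate inputs

* Otsu ties break toward the lower threshold; constant images are errors.
* The Box-Cox log branch switches at |L| < 1e-8; centile conversions are
  continuous across it (verified to 1e-3 centile at L = ±1e-6).
* Focal Tversky smoothing term is 1e-7, small enough to keep the
  soft-Dice identity to 1e-9 on realistic mask sizes.
* Empty segmentation sides are flagged results, not exceptions; empty
  inputs to morphometry and both-sides-empty measurements are errors.
* The LMS optimiser retries once from a seeded jittered start if the
  first BFGS run fails; non-convergence is an error, never silent.
* Problem sizes in the test and acceptance runs (96–128 voxel grids,
  n = 2000 cohorts, 6 training phantoms, 30-epoch toy training) were
  chosen so each module exercises its full code path in seconds to a few
  minutes; they are stated in the tests and the acceptance script.

## Known limitations

* Rigid registration to age templates is accepted as given; volumes must
  already be roughly aligned (axial = third axis).
* The reference models are didactic: they learn phantoms, not anatomy.
  The contracts are the integration points for real backbones.
* The corner-model Feret measurement reads up to ~1 px above pixel-centre
  implementations on rotated shapes (flagged above).
* BCCG only; heavier-tailed chart families (BCT, BCPE) are out of scope.
* Published chart coefficients cannot be reproduced without the original
  cohort; chart behaviour is validated by parameter recovery instead.
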