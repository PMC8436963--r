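---
title: "Quantifying melanistic spot patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying melanistic spot patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pattquant)
```

This vignette explains the models and procedures behind `pattquant`,
the choices that were genuinely open when the package was designed, and
what its synthetic validation does and does not establish about real
photographic data.

## The measurement model

A *region image* is an RGB photograph restricted to a hand-drawn mask
of one body region — front/back left/right leg (FL, FR, BL, BR), head
(HD), dorsal trunk (TR) or tail (TA) — with a physical scale in cm per
pixel. Melanistic skin is consistently darker than background skin, but
both the absolute darkness and the contrast vary between animals and
regions, so a fixed threshold cannot work. The package instead uses
robust-background (Niblack) thresholding with the whole region as the
window: a pixel is dark when its green value is strictly below

$$T = \mu - k\,\sigma,$$

where $\mu$ and $\sigma$ are the mean and (population) standard
deviation of the green channel over the usable region pixels. The green
channel separates pigmentation from shadows better than luminance in
this kind of photograph; $k$ is tuned per morphological region type —
0.85 for limbs, trunk and tail, and 0.50 for the head, whose larger
melanistic fraction drags $\mu$ down. Two guards keep the threshold in
a physically meaningful band: a global floor of 60 (out of 255), below
which pixels are invariably melanistic, and a trunk-specific cap of 108
that prevents sparse trunk patterns from inflating the threshold.

### Lighting artifacts

Limb photographs may contain cast shadows and specular glare; the trunk
may contain shadows visible in the blue channel (where melanistic spots
barely register against the yellowish skin). The detection rules are:

| region | shadows | glare |
|--------|---------|-------|
| limbs  | $G < \mu_G - 0.3\sigma_G$ | $G > \mu_G + 0.3\sigma_G$ |
| trunk  | $B < \mu_B - 0.85\sigma_B$ | — |
| head, tail | — | — |

Flagged pixels are excluded from the threshold statistics, and glare
pixels can never be classified dark. What to do with *shadow* pixels in
the dark classification was a genuinely open design point. Excluding
them entirely sounds conservative, but on a spotted limb the rule
$G < \mu_G - 0.3\sigma_G$ necessarily flags the melanistic spots
themselves — they are the darkest pixels — so excluding shadow pixels
from the dark set would erase every limb pattern. The default
(`artifact_action = "exclude_stats"`) therefore leaves shadow pixels
eligible for dark classification; the stricter behaviour is available
as `"exclude_dark"`. The cost of the default is that a shadow deep
enough to cross the final threshold can alias as a spot — the reason
regions should be photographed under diffuse lighting, and a known
limitation of automatic artifact handling. On strongly bimodal regions
the two artifact bands can cover every pixel; the threshold statistics
then fall back to the full region, which is plain Niblack thresholding.

### Spot extraction

Dark pixels are grouped into 8-connected components; components smaller
than 350 px (inclusive: 350 px is kept) are discarded as stray pixels
or dirt. Enclosed holes are filled by a 4-connected background flood —
the complementary connectivity avoids topological paradoxes — and the
contours are smoothed by a morphological closing followed by an opening
(two iterations, 3×3 square element), which removes granular boundary
effects without moving clean contours. After re-filtering, a spot is
*interior* when none of its pixels is 8-adjacent to the mask boundary
or image border, otherwise *boundary*. A region qualifies as patterned
with at least 4 interior spots (limbs), 6 (trunk, tail) or always
(head, which is always densely patterned in this species).

## The 14 pattern indices

Per region, from the cleaned spots (sample standard deviations, n−1,
throughout; an index whose spot class is empty is `NA`):

| index | definition | spots used | units |
|-------|-----------|------------|-------|
| FM | dark area / mask area | all | — |
| SS, SSD | mean/sd equivalent-ellipse major axis | interior | cm |
| EE, EED | mean/sd major:minor axis ratio (≥ 1) | interior | — |
| PL | spectral peak wavelength | all | cm |
| MD, MDD | mean/sd of mean distance to 3 closest centroids | all | cm |
| SA, SAD | mean/sd spot area | interior | cm² |
| SI, SID | mean/sd of pooled spot green values | all | 0–255 |
| EL, ELD | mean/sd spot elongation area/(2d²) | interior | — |

Notes on the less standard choices:

* **Equivalent ellipse.** Axes come from the pixel set's second central
  moments with the standard +1/12 per-pixel correction (full axis =
  $4\sqrt{\lambda}$), matching the usual region-properties convention.
  EE is reported as the major:minor *ratio* because that is the
  quantity verbally defined for it; the eccentricity convention
  $\sqrt{1 - (b/a)^2}$ is available via `ee_convention`.
* **Thickness d for EL.** d counts successive erosions until the spot
  vanishes. The erosion uses a 3×3 *cross* (4-connected) element,
  which peels one unit of inradius per step, so d is the spot's
  half-width: a 20×20 square and a disk of radius 10 both have d = 10,
  and a disk attains EL = area/(2d²) ≈ π/2, the round-shape baseline.
  A square element would measure the Chebyshev inradius instead
  (d ≈ 0.7 r for a disk) and lose that interpretation.
* **Peak length.** The binary spot field, cropped to the mask bounding
  box with out-of-mask pixels set to the in-mask mean, is mean-removed,
  zero-padded to a power-of-two square N, and Fourier transformed. PL
  = N/r\*, where r\* maximizes the radially averaged power over
  integer-radius annuli. The search excludes wavelengths with fewer
  than `min_periods = 2` full periods across the smaller window
  dimension: window-envelope leakage otherwise dominates the lowest
  annuli on sparsely spotted regions and masquerades as a wavelength.
  All concretization choices (padding, mean fill, annulus width, search
  domain) are exposed as arguments.
* **SI/SID** pool pixels across all spots rather than averaging
  per-spot means, reading "mean green value of spots" at pixel level.

Replicate photographs of one region are averaged per index; an index
missing in some replicate is averaged over the non-missing ones (with a
warning), and an averaged region qualifies only when every replicate
qualifies.

## Distances on pattern space

Each qualifying region is a point in 14-dimensional pattern space. Two
squared distances are fitted:

* **Mahalanobis**: $d_N^2(x,y) = (x-y)^\top S^{-1} (x-y)$ with $S$ the
  sample covariance of *all* qualifying complete patterns pooled across
  body parts. A ridge of $10^{-8}\,\mathrm{tr}(S)/14$ is added only
  when the condition number exceeds $10^{12}$ (degenerate data). This
  metric is affine-invariant and equals Euclidean distance after
  whitening — both properties are enforced by tests.
* **Developmental Noise**: $d_D^2(x,y) = \sum_i w_i (x_i-y_i)^2$ with
  $w_i = 1/\mathrm{mean}_n(S_i^n)$, where $S_i^n = (FL_i - FR_i)^2/2$
  is the left–right variance of index i over the two front legs of
  animal n, averaged over animals with qualifying patterns on all four
  legs (back legs enter only the eligibility requirement). Because the
  two front legs share genotype and environment, their differences
  estimate developmental noise; indices dominated by it get small
  weights. The metric is invariant to per-index rescaling, i.e.
  independent of units.

Reported distances are always the *squares*, multiplied by a
calibration constant chosen so that the mean squared distance over all
pairs of qualifying leg patterns from *different* animals is exactly 1,
regardless of leg identity. Between-individual means average unordered
animal pairs symmetrically:
$\tfrac12\,[d^2(A_g, B_h) + d^2(A_h, B_g)]$.

With $n$ patterns close to the 14 dimensions, the fitted covariance is
near-singular and Mahalanobis distances become nearly equidistant — the
within/between ratio is pushed toward 1. This is a small-cohort
artifact (the real study had 132 patterns); analyses on small synthetic
cohorts therefore either use more animals or average over repetitions.

## Statistical analyses

* **Permutation test** for "within-individual distance < between", per
  body-part pair: the gecko labels of the second part are permuted
  uniformly; $p = (1 + \#\{\text{null ratio} \le \text{observed}\}) /
  (1 + n_\text{perm})$, one-sided, never exactly 0. Default
  $n_\text{perm} = 10\,000$.
* **Correlations**: Pearson r between indices (pooled patterns) and
  between body parts per index (animals with both parts); p-values by
  permutation (two-sided, same +1 rule), with a parametric t option.
  Stars at 0.05/0.01/0.001/0.00001.
* **PCA** on standardized indices (the indices carry mixed units, so
  the correlation matrix is the only defensible choice); component
  signs fixed so the largest-magnitude loading is positive.
* **Coefficient of variation** sd/mean per index, per part and pooled.
* **Replicate error**: mean squared distance of a region's replicate
  index vectors from their centroid, compared with between-individual
  distances of the same part and, for legs, the within-individual
  left–right distance.
* **Sides × individuals ANOVA** per index on the balanced
  gecko × side × replicate design (sides fixed, individuals random):
  $F_\text{interaction} = MS_{SI}/MS_E$ tests fluctuating asymmetry
  against measurement error, $F_\text{sides} = MS_S/MS_{SI}$ tests
  directional asymmetry. Sums of squares come from `aov`; the mixed
  F ratios are assembled from its table, and a denominator mean square
  of zero (to float precision) is signalled as `NA` rather than an
  infinite F.
* **Hierarchy check**: per animal, "any patterned leg implies a
  patterned trunk" and "a patterned trunk implies patterned head and
  tail".

## The synthetic generator: what it emulates

`generate_pattern` places elliptical spots (lognormal semi-major axes,
lognormal axis ratios truncated at 1, uniform orientations) at
uniformly jittered hexagonal lattice points inside a rectangle, ellipse
or capsule mask. A crowding rule caps each semi-major axis at half the
gap to the nearest neighbour minus the separation a two-iteration
closing needs, so spots can neither overlap nor be merged by
smoothing — which keeps the ground truth (spot count, areas, axes)
unambiguous. `render_image` draws Gaussian pixel noise around distinct
spot/background levels in green, offsets red, gives blue a nearly
spot-blind profile (so trunk shadow detection behaves as on real skin),
and optionally adds a linear shadow ramp, a glare blob and sub-size
speckles.

Default geometry (canvas sizes 150–230 px per side at 0.01 cm/px,
lattice spacings 38–50 px, spot semi-axes 13.5–16.5 px) gives regions
whose spot counts, qualifying rates and melanistic fractions (~0.25)
resemble the photographic regions the method was designed for, at
roughly one tenth of their pixel count — small enough that the full
25-animal, 7-part, 4-replicate cohort (700 images) is generated and
measured in about two minutes on one CPU, the problem size used by the
end-to-end tests.

Cohorts add three variance layers:

1. a per-animal "genetic" latent (log spot size, log spacing, spot
   intensity; sds 0.10/0.06/6 with a 0.3 size–spacing correlation),
2. developmental noise: the two members of a leg pair share one base
   parameter draw, and each side is an independently perturbed copy,
   with perturbation `0.3 * dev_scale` of the base draw's own spread
   plus a per-side latent shift. At `dev_scale = 0` the sides carry
   identical patterns; head, trunk and tail are independent
   realizations,
3. replicate measurement error: each photograph re-rasterizes the
   pattern and its mask at a random sub-pixel offset (≤ 2 px) with
   fresh pixel noise and a small global lighting drift — replicates
   differ in boundary-pixel sampling exactly the way re-posed
   photographs do.

The factor 0.3 in layer 2 places the default condition in the
intermediate within/between regime observed in real animals; the
measured ratio rises monotonically in `dev_scale` (≈ 0.3 / 0.8 / 0.9 at
scales 0/1/3 under the Mahalanobis metric on 12-animal cohorts).

**Ground-truth wavelength.** The generator records `pl_cm` as the
nearest-neighbour spacing λ — the natural "typical distance between
spots". For an infinite hexagonal point lattice the radial spectral
peak would sit at the plane spacing $\sqrt{3}/2\,\lambda$; in the small
windows generated here the measured peak empirically tracks λ with a
mild downward bias (ratios ≈ 0.85–0.96 by region shape; tests compare
cohort means at 10%). Large windows recover the plane spacing, which a
dedicated test asserts.

**What passing tests do not show.** The generator draws clean ellipses
on statistically stationary backgrounds. Real photographs contain
non-elliptical and merged spots, stripes, gradual pigment boundaries,
colour calibration drift, perspective distortion of curved body parts
and genuinely irregular lighting. Recovery of generator ground truth
therefore validates the algorithmic chain (thresholding → cleaning →
indices → metrics → statistics), not the adequacy of these rules for
any particular photographic setup; the per-part rules encode judgments
that were made against real gecko photographs and may need re-tuning
for other species or imaging conditions.

## Numerical and degenerate-input conventions

* Strict inequality `G < T`: a uniform region at the threshold yields
  an empty dark set.
* Masks and channels are plain R matrices; coordinates are reported
  0-based row/column.
* Components are labelled in scanline order of their top-most,
  left-most pixel, so outputs are reproducible byte-for-byte.
* Morphology treats out-of-image pixels as background; smoothing pads
  before closing so border spots are not clipped.
* Degenerate spots (single row/column) get an equivalent-ellipse minor
  axis floored at 1 px.
* `NA` (never silent zero) signals undefined quantities: PL of a
  uniform field, MD with fewer than 2 spots, sd of a single value,
  CoV with zero mean, F with a zero denominator, correlations of
  constant columns.
* All stochastic procedures take explicit seeds and are
  bit-reproducible given them.
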