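---
title: "Measuring eye features in color images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring eye features in color images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyefeatures)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. The measurement problem

Given a frontal color face image and a face bounding box (from any
external detector — face detection is deliberately not part of this
package), we measure per eye: the pupil/iris center, the iris radius, and
the external eye shape as two parabolas (upper and lower eyelid) with the
eye corners at their intersections. The approach assumes a roughly frontal
pose, a visible iris (semi-closed eyes break the circularity cue), and
medium-to-good image quality.

## 2. Iris center: dark radial symmetry

The fast radial symmetry transform is a gradient-voting operator. Every
pixel with a nonzero Sobel gradient votes at the pixel its gradient points
*away from* at distance $r$ (the negatively-affected pixel): dark circular
blobs — iris plus pupil on skin/sclera background — collect many aligned
votes at their centers. Per radius, with $\tilde O_r$ and $\tilde M_r$ the
orientation and magnitude projections normalized by their maximum absolute
value,

$$F_r = |\tilde O_r|^{\alpha}\,|\tilde M_r|\,\mathrm{sign}(\tilde O_r),
\qquad S_r = F_r * A_r, \qquad S = \sum_r S_r .$$

Two points here were open and are worth recording:

* **Sign.** In dark mode both projections are accumulated with negative
  increments, so they share a sign everywhere; a formula that multiplies
  the *signed* $\tilde M_r$ by $\mathrm{sign}(\tilde O_r)$ would be
  nonnegative everywhere and could not be searched for minima. We
  therefore carry a single sign, from the orientation projection, and
  take the magnitude of $\tilde M_r$. In single-sign modes this reduces
  to the classic $\tilde M_r\,|\tilde O_r|^\alpha$ form.
* **Normalization.** The normalization of $\tilde O_r,\tilde M_r$ is not
  uniquely determined; we use per-radius max-absolute normalization by
  default and expose the classic clamp-at-$\kappa$ rule as
  `frst_params(normalization = "kappa")`.

Parameters: `alpha = 2` (radial strictness; higher suppresses straight
edges), `gaussian_sigma_factor = 0.25` (the spreading kernel $A_r$ has
$\sigma = 0.25\,r$, truncated at $3\sigma$, unit sum, zero boundary).
Affected-pixel offsets round half away from zero, and votes falling
outside the image are discarded rather than clamped, so borders are never
over-weighted. These choices are frozen by an exact-equality test against
a literal per-pixel oracle.

Candidate minima are collected with a tiled $2r_{\min}$ window scan;
flat tiles yield no candidate, and minima closer than $r_{\min}$ are
merged keeping the lower value. Candidate score is
$(-S)\cdot(255-\mathrm{blur}(I))/255$, halved above the eyebrow row (the
penalty magnitude is not dictated by the method; 0.5 is a configuration
default). Pair selection maximizes the score product weighted by a
Gaussian prior on the inter-pupillary distance over face width, mean 0.4
and sigma 0.1 — the five-eye facial canon; both are exposed in
`pipeline_config()`. The final center is constrained to the dark pupil:
the minimum of the blurred intensity in an $(r_{\min}/2)$-sized window,
ties broken toward the unrefined estimate.

The radius search range comes from anthropometry (eye width
$\approx$ face width / 5; iris/eye width $\approx 0.42$):
$R_0 = 0.5\cdot 0.42\cdot W/5$, range $[\lceil 0.7R_0\rceil,
\lfloor 1.3R_0\rfloor]$. Faces whose nominal radius falls below 2 px are
rejected as too small to measure.

## 3. Iris radius: radial gradient projection

On a blurred ROI around the center, the absolute vertical-edge Sobel
response is sampled along circles:
$\mathrm{proj}(r)=\sum_\theta |\mathrm{sobel}|(c_x\pm r\cos\theta,\,
c_y\pm r\sin\theta)$, $\theta$ stepped at 1° over $[-45°,45°]$ — the
iris–sclera transition is strongest laterally, while the vertical
transitions are routinely occluded by the eyelids. The lowest $k=20\,\%$
of the nonzero gradient magnitudes are zeroed first (noise floor; the
tie-inclusive percentile rule means $k=100$ blanks everything). The
radius is the projection argmax, ties toward the smaller radius. The
gradient sign is discarded because the left and right transitions have
opposite polarity and both sides are summed.

## 4. Sclera probability and the 24-bit lookup table

Pixel classification uses only chromatic information: HSV hue (wrapped
to $[0,1)$, achromatic pixels assigned hue 0) and the two chromatic
opponent channels $(O_1,O_2)=((R-G)/\sqrt2,\,(R+G-2B)/\sqrt6)$. The
intensity channel $O_3$ is excluded by default (illumination robustness)
and can be enabled with `include_o3 = TRUE`; hue circularity is not
modeled by a linear separator, so an optional $(\sin,\cos)$ encoding
exists but is off by default to stay close to the plain feature set.
Features are standardized by training mean/sd.

The classifier is a linear soft-margin SVM (via e1071) trained on pooled
pixels of small labeled patches — the pixel-based strategy; 25 sclera and
30 non-sclera patches of about 10×10 px are ample. Decision values from a
5-fold split are calibrated with Platt scaling,
$P(\text{sclera}\mid d) = 1/(1+e^{Ad+B})$, fitted by Newton iterations on
the prior-corrected targets; out-of-fold decisions avoid the optimistic
bias of calibrating on training decisions. Because a 24-bit image has
finitely many colors, the calibrated model is compiled once into a
$2^{24}$-entry table quantized to 8 bits; lookup then equals direct
evaluation within $1/255$, which the tests assert on random colors. The
file format is a 16 MiB raw array with a 32-byte header (magic, version,
feature flags), little-endian.

## 5. Eyelid shape: two parabolas fitted by Monte Carlo

The eye outline is a 12-value control-point vector
$X = [c_x\,c_y\,t_x\,t_y\,b_x\,b_y\,tl_x\,tl_y\,tr_x\,tr_y\,bl_y\,br_y]^T$:
center; top and bottom mid-points; two top outer control points; and two
y-offsets that place the bottom parabola's outer points below the top
ones at the same x. Control points are stored relative to the center
(translation invariance). The offsets are interpreted as *added to the
top outer points' y* — the reference point was ambiguous and this reading
keeps the bottom outer points on the bottom curve by construction.

A hypothesis is scored on the sclera probability map as
$$\omega = \frac{\alpha\,\overline{p_+} - \beta\,\overline{p_-}}
{\alpha+\beta},$$
where $\overline{p_+}$ averages the map over the bands $1\ldots\Delta$
just inside both eyelid curves and $\overline{p_-}$ just outside
($\alpha=\beta=0.5$, $\Delta = 5$ px). Sums vs means was ambiguous in the
formulation ("average difference" vs a plain $\Sigma$); means are used so
$\omega \in [-1, 1]$ regardless of band size. Band offsets are applied
vertically rather than along the curve normal — consistent with the
$y=f(x)$ parametrization and indistinguishable for shallow eyelid
curvature. Both eyelids are pooled into one score (joint scoring;
separate scoring is a configuration alternative). The scoring interval is
a fixed $[c_x-3R,\,c_x+3R]$ window for every hypothesis — corners are
only known after voting — which keeps scores comparable across
hypotheses; an explicit interval can be passed for controlled
experiments.

$N = 200$ shapes are sampled uniformly; fewer than 100 degrades accuracy
and more brings no relevant gain. The sampling bounds are proportional to
the iris radius $R$ and come from eye anthropometry (e.g.
$t_y \in [-2.2R, -0.8R]$, outer points at $1.2$–$3R$ laterally); they are
not dictated by the method and are fully config-exposed
(`default_shape_bounds()`). The center coordinates are fixed at the
detected iris center by default (degenerate bounds) — jitter can be
enabled through the bounds. The fittest 30 % vote; since $\omega$ may be
negative while the voting formula assumes positive weights, weights are
shifted by the minimum selected fitness and floored at
$\varepsilon=10^{-6}$, making the solution a convex combination of the
selected shapes.

**Identifiability.** The probability map constrains the two *curves*, not
the decomposition of a curve into control points: a control point can
slide along its parabola without changing any band. Coordinates such as
$bl_y, br_y$ are therefore informed mainly by the sampling prior, and
recovery of the full 12-vector is only well-posed when the ground truth
sits at the center of the hypothesis domain. The parameter-recovery tests
use exactly that truth; on arbitrary shapes the package recovers the
curves, corners and mid-points, and the voted control points inherit a
prior pull along the curves. This is a property of the model, not a
defect of the sampler.

## 6. The synthetic generator

`render_eye()`/`render_face()` draw piecewise-constant regions: skin
background, sclera between the two parabolas, iris disk clipped to the
eye region, concentric pupil, dark eyebrow bands, optional specular
highlight, and additive Gaussian noise rounded back to 8-bit. Masks and
annotations are exact by construction (anti-aliasing is off by default),
so recovery tests are well-posed. Default palette: skin (205,170,140),
sclera (235,230,225), iris (60,80,40), pupil (15,15,15). Anthropometric
placement matches the detection priors: IPD ratio 0.4, eye row at 0.42 of
the face height, nominal iris radius $0.042\,W$; the canonical open-eye
shape puts the corners at $\pm 2.38R$ so the iris/eye width ratio is
0.42. The dataset presets are `clean` (noise sd 2), `noisy` (sd 12 plus a
specular highlight) and `occluded` (top eyelid lowered over the iris,
emulating semi-closed eyes).

What the generator does **not** emulate: texture (skin pores, eyelashes,
iris striation), shading and illumination gradients, glasses and their
specular reflections, head pose, compression artifacts, and the
age-related effects (eyelid ptosis, sclera color degradation) known to
degrade the method. Passing tests on this corpus therefore demonstrates
the correctness and internal consistency of the algorithms — not
performance on photographs; on real data the published experience is that
accuracy drops with occlusion, low resolution and age.

## 7. Numerical choices and degenerate inputs

* Rectangles are 0-based, half-open; coordinates are 0-based with y down.
* Eye band fractions default to rows $[0.20h, 0.55h)$ of the cropped
  face; the vertical projection is smoothed with a 5-row moving average
  before the first-valley scan (raw sums are noise-dominated), plateaus
  break to the topmost row, and a projection with no interior valley
  falls back to the global minimum.
* Rounding: affected-pixel offsets round half away from zero (bit-stable
  tests); face-crop offsets floor, widths round.
* Blur for darkness weighting, refinement and the radial projection uses
  $\sigma = 2$ px with replicated edges; nominal radii are rounded to 9
  decimals before integer floor/ceiling so IEEE dust cannot flip a bound.
* Degenerate inputs raise errors with stage names: no candidate in a face
  half (detection failure for that eye), all-zero radial projection (no
  edge evidence), parabolas with fewer than two intersections (corner
  fallback to the scoring-interval endpoints), zero-denominator
  classification measures (flagged, never silently 0).
* Problem sizes in the shipped tests and the acceptance script — 32×32
  oracle images, 30 disks, 50 eyes, 30–50 faces, 20 Monte Carlo seeds —
  were chosen as the smallest corpora at which the binomial pass
  fractions are stable.

## 8. Known limitations

Closed or semi-closed eyes defeat the circularity cue; strong specular
reflections can out-vote the iris; the parabola pair cannot represent
ptotic eyelids; the linear color model assumes sclera chromaticity
separates from skin, which degrades with sclera yellowing; and corner
estimates inherit the Monte Carlo prior pull described in section 5.
Non-parabolic eyelid curves (cubics, splines) and iris tracking are out
of scope.
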