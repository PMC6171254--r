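---
title: "Methods: normalized hemodynamics, image redness, and their comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized hemodynamics, image redness, and their comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twachp)
```

This vignette is the package's own account of the science it implements:
the surface-side hemodynamic scoring, the image-side redness metric, the
statistical protocol, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the problem left
them open.

## 1. The problem

Cerebral aneurysms rupture preferentially at thin-walled areas (TWAs),
which surgeons recognize intraoperatively as reddish, translucent patches.
Two independent routes point at candidate TWAs:

* **hemodynamics** — wall regions exposed to chronically low wall shear
  stress (WSS) and oscillating shear direction (high OSI) undergo
  degenerative remodeling and thinning;
* **intraoperative appearance** — thin walls transmit the blood column and
  look redder than normally perfused vessel wall.

The package quantifies both and checks whether they designate the same
surface site. Everything upstream of the wall fields (angiographic
reconstruction, CFD solution of the flow) and the manual alignment of a 3-D
model to the surgical view are out of scope: the inputs are a triangulated
surface with a per-face WSS vector time series over one cardiac cycle, and
an RGB image with circular region annotations.

## 2. Surface side: OSI, normalized WSS, CHP

**OSI.** For each face, with `wss_i` the instantaneous WSS vector and `t`
the cycle duration,

\[
\mathrm{OSI} \;=\; \frac12\left(1 -
  \frac{\lVert \int_0^{t} \mathbf{wss}_i\,dt \rVert}
       {\int_0^{t} \lVert \mathbf{wss}_i \rVert\,dt}\right)
  \in [0, 0.5],
\]

0 for unidirectional shear, 0.5 for complete reversal. The discretization
is not dictated by the definition; the package uses the trapezoidal rule on
the sample grid with **periodic closure** (the final sample pairs with the
first across the cycle boundary), which preserves the two analytic limits
exactly: a constant-direction series gives OSI = 0 and a symmetric
half-cycle reversal gives OSI = 0.5 to machine precision. Faces whose total
shear exposure \(\int \lVert \mathbf{wss} \rVert dt\) falls below a
tolerance (default 1e-12 Pa·s) are assigned OSI 0: without flow there is no
oscillation, and this avoids a 0/0.

**Normalized WSS.** Raw WSS (Pa) and OSI (dimensionless) cannot be
averaged meaningfully. WSS is normalized onto [0, 1] through a quartic
"ellipse" relation anchored to the sac extremes at the diastolic time,

\[
(\mathit{WSS}_{norm} - 1)^4 + u^4 = 1,\qquad
u = \frac{\mathit{WSS} - \mathit{WSS}_{max}}
         {\mathit{WSS}_{max} - \mathit{WSS}_{min}} \in [-1, 0],
\]

with \(\mathit{WSS}_{min},\mathit{WSS}_{max}\) the extremes over the sac
faces above the neck. The quartic has two real roots
\(1 \pm (1-u^4)^{1/4}\); the branch in [0, 1],
\(\mathit{WSS}_{norm} = 1 - (1-u^4)^{1/4}\), is the one consistent with a
0-to-1 range. It maps the sac minimum to 1, the maximum to 0, and — unlike
a linear rescale — stays near 1 over a broad low-shear band, deliberately
over-weighting the dangerous end. Choices the definition leaves open:

* *element-wise extremes*: \(\mathit{WSS}_{min/max}\) are taken over
  individual faces, not small-area averages;
* *clamping*: outside the sac the diastolic WSS may leave
  \([\mathit{WSS}_{min}, \mathit{WSS}_{max}]\); `u` is clamped to
  \([-1, 0]\) so the field stays in [0, 1] (the relation is only defined on
  the sac range);
* *degenerate range*: \(\mathit{WSS}_{max}-\mathit{WSS}_{min}\) must exceed
  1e-12 Pa, otherwise the normalization is undefined and an error is
  raised;
* *diastolic time*: if the series does not carry one, it is estimated as
  the time index minimizing the sac-area-weighted mean WSS magnitude (the
  low-flow phase), overridable in `run_config()`.

**OSI normalization and CHP.** OSI already spans [0, 0.5] with 0.5 the
dangerous end, so \(\mathit{OSI}_{norm} = 2\,\mathit{OSI}\). The combined
hemodynamic parameter is the weighted average

\[
\mathrm{CHP} = w_1\,\mathit{WSS}_{norm} + w_2\,\mathit{OSI}_{norm},
\qquad w_1 + w_2 = 1,
\]

again in [0, 1] and exactly linear in \(w_1\) for fixed fields — a property
the tests exploit, since published group means at two weightings determine
the means at every other weighting. The default is \(w_1 = 1\) (pure
normalized WSS), the setting reported to discriminate best.

**Peak patch.** TWAs are areas, not single elements, so the predicted TWA
is the sac patch (default geodesic radius 0.5 mm, approximated by Euclidean
centroid distance) whose area-weighted mean CHP is maximal; ties break to
the lowest face index for determinism.

## 3. Image side: ΔE and the redness projection

Pixels are converted from 8-bit sRGB to CIELAB under the D65 illuminant and
2° observer (the industry defaults; the underlying protocol names neither),
and each pixel is compared with the mean Lab color of the annotated
normal-vessel reference patch using the full CIEDE2000 formula with
parametric factors \(k_L = k_C = k_H = 1\). Conversion and CIEDE2000 come
from the `farver` library; the implementation is pinned by the 19 published
CIEDE2000 verification pairs, reproduced to 1e-4 in the tests.

Raw ΔE rewards any deviation from the reference — a glare highlight scores
as well as a red patch. The modified metric projects ΔE onto the redness
axis using the reference patch's lightness \(L_2\) and redness \(a_2\):

\[
\Delta E_m = \Delta E \cdot \frac{a_2^2}{L_2^2 + a_2^2}.
\]

The printed squared form is the default; the geometric cosine reading
\(a_2 / \sqrt{L_2^2 + a_2^2}\) is available behind
`run_config(delta_e_variant = "projection")` but is never silently
substituted. Both factors lie in [0, 1] and are constant per image, so
\(\Delta E_m \le \Delta E\) everywhere and the within-image pixel ranking
is unchanged; the modification matters when comparing regions *across*
differently lit images, not for locating the peak within one image. ΔE is
computed per pixel and then patch-averaged (not on region-mean colors). The
reddest region is the ΔE_m peak after disk-mean smoothing (default radius
5 px) restricted to the annotated region of interest, with row-major
tie-breaking. `b_2` is carried in the reference color but unused by the
formula, matching its printed form.

## 4. Statistical protocol

Group values (one per case, at the more-dangerous = max-ΔE_m site and the
less-dangerous site) are compared with a normality-gated two-sided test:
Shapiro–Wilk on *both* groups at \(\alpha = 0.05\) (the same threshold as
the significance level); only if both pass is the t-test used, otherwise
the Mann–Whitney U. Further choices:

* groups are treated as **independent** by default, matching the generic
  protocol description, with a `paired` option (the data are in fact
  paired per aneurysm);
* the t-test is the **Welch** unequal-variance form — reported group SDs
  differ by factors of ~3;
* Mann–Whitney U uses the exact distribution for small samples (an exact
  permutation enumeration when ties block the closed form, both sides at
  most 8 cases) and the normal approximation with tie correction
  otherwise;
* SDs are sample SDs (n−1); no multiple-testing correction is applied,
  matching the original protocol.

The weighting sweep recomputes per-case CHPs on a \(w_1\) grid (default
0.5–1.0 by 0.1) and compares the groups per row. Because the gate can
switch between t and U tests across rows, the p-value need not decrease
monotonically in \(w_1\) even as the group contrast widens; the tests
therefore assert the widening contrast and the endpoint ordering rather
than strict row-wise monotonicity.

## 5. What the synthetic generator emulates

`make_case()` builds a desk-scale stand-in for one patient case, fully
determined by one seed:

* **geometry** — a spherical dome (default radius 2.5 mm, matching a
  ~5 mm aneurysm) meshed to just past the equator; faces above the neck
  plane form the sac (default mesh 2256 faces);
* **pulsatile wall shear** — tangential vectors whose magnitude follows a
  two-term raised-cosine waveform (32 samples/cycle, systolic peak
  mid-cycle, diastolic minimum at the first sample) scaled by a per-face
  lognormal spatial modulation (SD 0.25 on the log scale) around a 1.6 Pa
  base; inside the planted thin-wall patch the magnitude is multiplied by
  `wss_deficit` (default 0.2, the ratio of reported thin-wall to
  normal-wall WSS) and the direction is reversed for `reversal_fraction`
  of the cycle (default 15%, placed in the low-flow segment);
* **pressure** — constant per case (≈15.75 kPa) plus small per-face noise:
  wall pressure is nearly uniform over an aneurysm, so it carries no
  spatial signal by construction;
* **image** — an orthographic Lambertian rendering of the dome under
  gentle near-vertical lighting (L\* amplitude 5), base wall color
  Lab ≈ (52, 28, 22); the pixels over the planted patch are shifted by
  +15 in a\* and −5 in L\* (a thin translucent wall reads redder and
  slightly darker), then per-channel Lab noise (SD 2) is added and the
  result encoded to sRGB. Annotations are generated on the dome: reference
  at 90° azimuth from the patch, less-dangerous opposite the patch,
  more-dangerous at its center, and a circular ROI at 88% of the dome disk
  (the clinical ROI excludes the rim);
* **cohorts** — `make_cohort()` jitters geometry and effect sizes per case
  from truncated-normal/lognormal distributions whose defaults plant the
  reported clinical contrast: a strong WSS deficit, a mild noisy OSI
  excess (patch reversal 0.15 ± 0.07 vs background 0.08 ± 0.05), and no
  pressure effect.

What it does **not** emulate: secondary flow structures and impingement
patterns (no CFD), wall-thickness variation from atherosclerosis (the
known failure mode of the image comparison), specular glare and white
balance drift in the surgical image, or any mesh/image misalignment —
the synthetic mesh-to-image mapping is exact by construction. Passing
tests therefore demonstrate the correctness and stability of the scoring
and comparison machinery under the assumed signal structure, not clinical
performance on real data.

## 6. Numerical choices and problem sizes

* Quadrature: periodic trapezoid; quartic root taken in closed form (no
  iteration); all peak searches deterministic with index-order
  tie-breaking.
* Tolerances: zero-flow threshold 1e-12 Pa·s, degenerate sac range
  1e-12 Pa, scalar-field range snap 1e-9.
* The test suite runs cohorts of 21 cases at the default mesh (2256
  faces, 32 time samples, 320×240 images); the 100-cohort Monte-Carlo
  suite uses a coarser 992-face mesh, which changes only the surface
  resolution, not the signal model. The type-I-error suite uses 2000 null
  replicates of 21-vs-21 comparisons.
* The 16-bit PNG heatmap writer is in-package (the `png` library writes
  only 8-bit), storing values scaled by the map maximum.

## 7. Correspondence of the two predictions, and a known limitation

A case counts as a **correspondence** when the peak-CHP patch center lies
within 1.5 mm (configurable) of the surface point under the reddest pixel,
using the case's mesh-image mapping. With the default generator this is a
demanding definition: the planted patch is *flat* — a uniform deficit with
iid spatial noise — so the exact argmax location of each side is close to
uniformly distributed within the ~1.25 mm-radius patch, and two such draws
land within 1.5 mm of each other only about three quarters of the time
even though both sides recover the patch itself essentially always (the
mask-membership recovery rate is ≈100%). Measured cohort correspondence
fractions run ≈0.6–0.86 across cohort seeds. A graded (center-peaked)
deficit profile would concentrate both peaks and raise the fraction, but
the flat profile is retained as the generator's defining contract; users
comparing against region-scale expectations should either enlarge the
correspondence tolerance toward the expected TWA diameter or compare patch
overlap rather than centers.

## 8. Other limitations

* The sac mask is an input; no automatic neck detection is attempted.
* Geodesic distances are approximated by Euclidean centroid distances,
  adequate at patch scales well below the sac curvature radius.
* OSI is evaluated over the whole mesh while the WSS normalization
  extremes are sac-restricted (the definition of the extremes is explicit
  about the sac; the OSI domain is not restricted anywhere).
* Printed p-values of the original patient tables are not a reproduction
  target: the exact test variants behind them (paired vs independent,
  Welch vs pooled, exact vs approximate U) are not recoverable, and the
  patient data are not deposited.
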