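---
title: "Curvature-based measurement of gingival recession: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based measurement of gingival recession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Gingival recession depth is the distance between the cemento-enamel
junction (CEJ) and the gingival margin (GM) on the mid-buccal tooth
profile. On a digital model both landmarks are shape features of a planar
cross-section: the CEJ is the concavity where the convex enamel crown
gives way to the root surface, the GM the concave fold where the root
surface meets the free gingiva. `gingrec` operationalises this with signed
curvature.

A bucco-oral slicing plane (normal = mesio-distal x-axis of a per-tooth
local frame; the tooth long axis is z, so the section contains it) cuts the
arch mesh into an ordered polyline. The polyline is fitted with a cubic
spline on the chord-length parameter, resampled at uniform arc length
$h = 0.01$ mm, and the curvature

$$\kappa(s) \;=\; \pm\,\frac{y' z'' - z' y''}{(y'^2 + z'^2)^{3/2}}$$

is evaluated from the analytic spline derivatives at every sample — not
from finite differences of the resampled points, which at $h = 0.01$ mm
would amplify point noise quadratically. The sign is fixed so that, with
the chain ordered coronal to apical and the tissue on its right, convex
surface features are positive and concave ones negative (the curvature-comb
colouring convention). Note that with this orientation the raw parametric
formula yields the opposite sign, so the implementation negates it; the
operative contract is "concavities are negative", which the landmark logic
depends on.

Landmark recognition scans the sign pattern of $\kappa$:

* **CEJ** — first convex-to-concave transition scanning coronal to apical;
* **GM** — first convex-to-concave transition scanning apical to coronal;
* each landmark is the sample of extreme concave curvature inside its
  concave run; exact ties break to the most coronal sample.

A transition qualifies only if both adjoining runs span at least `min_run`
(default 0.05 mm) and the concave extremum magnitude reaches
`min_prominence` (default 0.1 mm⁻¹). These gates are this package's
addition: the transition definitions alone are ambiguous on real root
surfaces with extra concavities (surface defects), and the gates make the
failure modes explicit — the detection report lists every candidate
segment, and undetectable sites are flagged, never silently dropped.

Depth is the in-plane Euclidean distance between the two landmark points —
a digital ruler between two picked points, not a z-projection. Full
precision is kept internally; 0.01 mm rounding belongs to display only.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `h` | 0.01 | mm | working resolution of the curvature profile; matches the 0.01 mm reading precision of digital calipers |
| `smoothing` | 0.005 | mm | max allowed deviation of the spline from the input points, half of `h`; 0 interpolates. Mesh sections are chorded polygons, so pure interpolation rings at the chord kinks — the bound buys noise immunity without visibly moving the curve |
| `min_run` | 0.05 | mm | suppresses sign-flip blips from residual noise |
| `min_prominence` | 0.1 | mm⁻¹ | below the 5th percentile of clinically observed CEJ curvature (0.32 mm⁻¹), with margin |
| `boundary_n` | 5 | samples | spline end conditions distort curvature; the flagged ends are excluded from landmark search |
| `kappa_threshold` | 1.0 | mm⁻¹ | stratification threshold for deviation analyses; the clinically observed reliability knee |
| `plane_offset` | 0 | mm | mesio-distal site position; site selection is an explicit input (it was an operator choice in the manual workflow), not automated |

`refine_mesh` (longest-edge bisection to a minimal edge length) is provided
for parity with mesh-refinement preprocessing but is off by default: the
arc-length spline resampling already fixes the sampling density, so
refinement changes nothing downstream (a property the tests check).
Neighbouring faces that split different edges can leave T-vertices; these
lie exactly on the surface and are harmless to per-triangle sectioning.

## The synthetic world

`profile_spec()`/`generate_profile()` build cross-sections as a chain:
convex crown arc (+0.3 mm⁻¹, 3 mm), CEJ concavity, near-straight root
(+0.02 mm⁻¹, length solved), GM concavity, convex gingiva (+0.5 mm⁻¹,
2 mm), with tangent continuity throughout. Cohort draws follow log-normal
distributions moment-matched to the clinically reported summaries: CEJ
curvature magnitude median 0.99 mm⁻¹ (5th–95th percentile 0.32–2.30), GM
median 4.39 (1.98–9.14), depth median 1.90 mm (IQR 1.25–2.62). Those
figures are the stated world; they are inputs, not tuning knobs.

One construction choice deserves its rationale. A landmark concavity built
as a single circular arc has *constant* curvature, so every sample in it is
an exact extremum tie and "the extremum" degenerates to the tie-break rule —
mid-arc ground truth then cannot be recovered to sub-hundredth-millimetre
accuracy even in principle. Each concavity is therefore built from two
linear-curvature ramps (clothoid-like) meeting at the peak: curvature at
the ground-truth landmark equals the specified magnitude exactly, the
extremum is unique, and the analytic curvature oracle (piecewise linear in
arc length) remains exact. Crown, root and gingiva stay circular arcs with
the classic ±1/r oracle. The root length is solved (to 1e−10 mm) so the
CEJ–GM distance equals the requested depth; infeasible span/depth
combinations raise a construction error naming the violated constraint,
and cohort depth draws are floored at the minimal feasible separation
(rarely active; recorded per site).

Point noise, when enabled, is Gaussian on the sampled points (measurement
noise), not on the arc parameters (anatomy). The examiner model places a
manual pick at the true landmark plus a draw from
$\mathcal{N}(0, \sigma_0 / \max(|\kappa|, \kappa_{floor}))$ along the
curve: the straighter the local profile, the larger the scatter. Neither
source states $\sigma_0$; it is set once to 0.2 mm so that at the median
CEJ curvature (≈1 mm⁻¹) simulated pick scatter produces depth
limits-of-agreement ranges of order 1 mm, the magnitude reported for human
examiners. With `kappa_floor` = 0.1 mm⁻¹ the scatter saturates at 2 mm for
nearly flat profiles. Both mechanism findings — CEJ picks scatter more than
GM picks, and variability jumps below |κ| = 1 mm⁻¹ — follow from this
model for any positive $\sigma_0$; the tests count them over 100 cohort
seeds.

**What a green test establishes, and what it does not.** The synthetic
profiles are smooth, single-valued, noise-controlled chains; real
intraoral-scan sections carry scanner noise, mesh artefacts, plaque and
soft-tissue irregularities, and root-surface defects that add extra
concavities. Green tests establish that the geometry pipeline is correct
and that the observer-variability mechanisms are reproduced; they do not
certify clinical accuracy on scanned dentitions, and no dataset-level
numbers are asserted anywhere in the suite.

## Numerical choices

* Arc length by composite 16-point Gauss–Legendre quadrature of the
  parametric speed; inversion per sample by safeguarded Newton iteration to
  1e−9 mm.
* Smoothing is specified in millimetres (a max point-to-curve deviation
  bound) and realised by bisection on the log penalty of a smoothing
  spline — an interpretable contract instead of an opaque penalty value.
* Interpolation uses not-a-knot-style end cubics rather than natural end
  conditions (which force zero curvature at the ends); the first and last
  five samples are still flagged and excluded from landmark search.
* A spline interpolating a chain whose curvature *jumps* (G1 arc
  junctions) overshoots the jump by roughly 13% in the second derivative,
  independent of sampling density. Mid-arc curvature is accurate to the
  stated tolerances; run extrema at such junctions are deeper than ±1/r.
  The generator's ramped concavities avoid this where ground-truth recovery
  is asserted.
* ICC(A,1) from the two-way ANOVA mean squares with the
  F/Satterthwaite confidence interval; the estimate is oracle-tested
  against an independent `aov()`-based computation and agrees with
  `pingouin.intraclass_corr` to machine precision. Degenerate inputs
  (identical raters) return estimate 1 with a collapsed interval.
* Bland–Altman uses the literal 1.96 multiplier and the classical
  $\sqrt{3/n}$ approximation for the limits' confidence intervals;
  zero-variance differences flag the t-test as undefined rather than
  producing NaN.
* Bonferroni is the default multiplicity adjustment (conservative,
  software-independent); the method is configurable and recorded in the
  output.

## Design decisions taken where the procedure was open

* **Config is JSON only** (no YAML parser among the dependencies kept).
* **ICC form**: the sources report inter- and intra-examiner reliability
  without naming the ICC variant; ICC(A,1) is the standard choice for
  agreement of interchangeable raters and is applied to sites × examiners
  per round (inter) and sites × rounds per examiner (intra), with the form
  recorded in the output.
* **Manual picks** are accepted either as arc-length positions or as 2D
  points snapped to the nearest curve sample (snap distances above 0.05 mm
  are recorded; beyond 0.5 mm is an error).
* **Landmarks are reported at sample resolution** (no sub-sample
  interpolation), matching the 0.01 mm working grid.
* **GM orientation check**: the GM must lie apical to the CEJ. In profiles
  truncated before the gingival fold the CEJ concavity itself matches the
  apico-coronal transition pattern, so the absence of a GM surfaces as this
  orientation error rather than a not-found error.

## Known limitations

* Tooth segmentation and long-axis estimation are out of scope: the local
  frame and slicing offset are inputs.
* Teeth with cervical restorations or unidentifiable CEJ are outside the
  validated domain, as they were for the manual reference workflow.
* The cross-section is a single measuring site; whole-surface (2D
  curvature) analysis is not attempted.
* Clinical probing data can be ingested as tabular records but no claim is
  made about probe-vs-digital agreement beyond the Bland–Altman machinery
  provided.
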