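---
title: "Algorithm-guided programming of directional DBS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algorithm-guided programming of directional DBS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsteer)
```

This vignette documents the models behind `dbsteer`, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what a green test does and does not establish.

## The coordinate system of a 1-3-3-1 lead

The package fixes a coordinate system the hardware does not define. The
vertical position `p` runs over `[0, 3]` level units with integers at
level centers (0 = ring E1, 1 = segments E2–E4, 2 = segments E5–E7,
3 = ring E8); one level unit corresponds to the contact-plus-spacing
pitch (2 mm by default, used only by the volume model). The rotation
angle `theta` places the first segment of each level at 0° and the others
at 120° and 240°; the datum is arbitrary but fixed, since absolute lead
rotation is patient-specific and outside our scope.

A ring-stage point splits cathodic current linearly between the two
adjacent levels; a directional-stage point additionally splits each
segmented level's share linearly between the two segment directions
adjacent to `theta`. Ring contacts (E1/E8) always receive their share
undirected, so a directional point whose carried-over `p` is fractional
naturally spans two levels — patterns such as
`E2: -8%, E4: -22%, E5: -18%, E7: -52%` arise from a single `(p, theta)`
pair. Percents are rounded to integers by largest remainder with ties to
the lowest electrode index, which reproduces the conventional
`-34/-33/-33` equal-thirds pattern. Rounding keeps every per-electrode
error below one percentage point; the inverse mapping (share-weighted
level centroid; sector-wise inversion of the angular interpolation)
recovers lattice coordinates within ±0.02 level units and ±3° wherever a
segmented level carries at least half the current.

## Symptom weighting

The raw weight of a symptom with baseline scores `b_off` (no therapy)
and `b_on` (reference therapy) is

\[ w = \frac{\Delta}{4}\cdot\frac{\Delta}{b_\mathrm{off}}
     = \frac{\Delta^2}{4\,b_\mathrm{off}},\qquad
   \Delta = b_\mathrm{off}-b_\mathrm{on}, \]

quantized to 0.001, zero when there is no severity or no improvement.
This product of untreated severity (`Δ/4`) and relative improvement
(`Δ/b_off`) is an assumption: the clinically deployed rule is
proprietary, and this is the unique simple separable form consistent
with its three published worked examples (4→0 gives 1.0, 2→0 gives 0.50,
2→1 gives 0.125). Weights from clinician and sensor sources are treated
identically — both live on the same 0–4 scale — and at most four
symptoms per hemisphere are kept (ties: clinician before sensor, then
lexical), renormalized to sum to one.

## Score maps and side-effect boundaries

Each stage keeps observations on a regular lattice domain (default
31 vertical positions × 26 amplitudes for the ring stage, 30 angles × 26
amplitudes for the directional stage, amplitudes 0.5–5.5 mA). Predicted
scores use inverse-distance weighting with power 2 in normalized
coordinates; IDW was chosen because it is parameter-light, exact at
observations, order-independent, and bounded by the observed score
range. Distances normalize each axis to span one: `p/3`,
`(A - A_min)/(A_max - A_min)`, and circular angular distance divided by
180° so that maximal angular disagreement equals one. That last choice
deserves emphasis: scaling angles by 360° instead would make one
angular lattice cell 0.033 normalized units while the convergence
threshold is 0.08, structurally preventing the directional stage from
ever resolving below three cells. A repeat observation within half a
lattice cell replaces the older score rather than accumulating.

A side-effect observation at amplitude `A` caps the admissible amplitude
at `A − 0.1` mA (one amplitude step) for all first-coordinate values
within 0.5 level units (ring) or 60° (directional) of the observation,
circularly on the directional stage. Caps only ever tighten, so the
admissible region shrinks monotonically. The true clinical boundary
shape is not published; this rectangular cap is the simplest rule with
the stated behavior.

## The two-stage loop

Both stages first test fixed predefined points — `(p, A)` =
(0.5, 1.5), (1.5, 2.5), (2.5, 1.5) mA for the ring stage and
`theta` = 0°, 90°, 180°, 270° at 3.0 mA for the directional stage. These
coordinates are package defaults (the published workflow shows three and
four such points but not their coordinates): they span the space
symmetrically and keep the seed amplitudes conservative. Afterwards the
next setting is the admissible lattice node minimizing

\[ \mathrm{acq}(x) = \hat S(x) - \beta(t)\,d(x),\qquad
   \beta(t)=\beta_0\,\mathrm{decay}^t, \]

where `Ŝ` is the IDW prediction and `d` the normalized distance to the
nearest explored point; ties prefer lower amplitude, then lower
coordinate. This acquisition is an explicit stand-in for a proprietary
weighting method, chosen to reproduce the described behavior —
exploration of mutually distant regions first, then focus on the best
region — with two interpretable parameters. The defaults
`beta0 = 4`, `decay = 0.9` were frozen after sweeping both against the
two desiderata of ~10–25 total steps per hemisphere and recovery of the
ground-truth optimum on simulated patients; they favor a thorough
exploration phase because the IDW surrogate can never predict a value
below the best observation, so unexplored ground is only ever visited
while `β` is substantial.

A stage converges when the suggested node lies within 0.08 normalized
units of an explored point (~0.24 level units, ~14.4°, or ~0.4 mA). The
directional stage runs only when the best ring setting puts cathodic
current on a segmented electrode (E2–E7), at that setting's vertical
position; the final recommendation is the admissible explored setting
with the lowest total weighted score across both stages, with ties to
the lower amplitude (battery-sparing convention). Steps that triggered a
side effect, or that lie above a cap learned later in the stage, are
never recommended.

## The in-silico patient

Each simulated symptom follows

\[ s(p,\theta,A) = \mathrm{clip}_{[0,4]}\Big( b_\mathrm{off}
   - I\,G_p(p)\,G_\theta(\theta)\,f(A) + \varepsilon \Big), \]

quantized to 0.1: a Gaussian vertical kernel `G_p` (scale 0.6–1.0 level
units), an angular kernel `G_theta` (wrapped Gaussian, scale 50–80°), a
saturating amplitude response `f` anchored so `f(0) = 0` (logistic with
midpoint 1.5–2.5 mA, slope 0.5 mA), a maximal improvement `I` of 60–95%
of the baseline, and Gaussian noise (sd 0.3 for clinician scores, 0.15
for sensor scores, zero in the `easy` preset). Only the cathodic share
on segmented electrodes is angularly steered; the remainder sees the
circular average of the angular kernel. This matters: integer-percent
rounding can leave a ±1% imbalance between the segments of a nominally
symmetric ring setting, and without the blending rule that imbalance
would be decoded as full steering at 0°, producing a cliff in the
response. Side effects fire when the amplitude reaches a threshold
surface that dips (by 1–2.5 mA from a 5 mA base) near one sector of the
lead, emulating current spread towards a neighboring structure such as
the internal capsule; angularly symmetric settings are evaluated at the
worst angle.

The presets state three worlds: `easy` (all symptoms share one sweet
spot, no noise, no side effects — the oracle-agreement world),
`clinical` (jittered sweet spots, noise, a side-effect sector), and
`adversarial` (at least two symptoms with sweet spots ≥1.2 level units
apart, so the best compromise setting differs from every single-symptom
optimum). The generator emulates the *shape* of per-symptom response
maps and their disagreement across symptoms; it does not emulate
medication state, wash-in kinetics, rater drift, lead placement
variability, or any biophysics of activation — so a green optimizer test
establishes correct loop mechanics on smooth unimodal worlds, not
clinical effectiveness.

## Similarity metrics and the volume stand-in

Setting similarity multiplies the amplitude ratio `min/max` by one minus
the electrode-configuration distance, which is the Euclidean distance of
the signed 9-entry fraction vectors (cathodes negative summing to −1,
anodes positive summing to +1, case last) divided by √8 — the distance
of a full single-cathode polarity swap, so the result lies in `[0, 1]`.
The case entry is carried (+1 for every monopolar setting) and cancels
in monopolar comparisons. Score similarity is `1 − ‖s₁−s₂‖/√(16N)`.

The voxel volume model is a deliberately simple geometric stand-in:
spheres of radius `1.3·√(fraction·A)` mm around each active electrode's
centroid, minus the lead body plus a 0.1 mm encapsulation shell,
voxelized at 0.25 mm on a fixed global grid so volumes from different
settings share indices. It preserves monotonicity in amplitude and
rough clinical magnitudes but is **not** a field or axon model, and
Jaccard overlaps computed from it are not comparable with values from
finite-element activation models.

## Numerical choices and degenerate inputs

* Largest-remainder rounding, ties to the lowest electrode index;
  cathodic percents always sum to exactly 100.
* Zero-amplitude settings carry an all-zero fraction vector; responding
  to them returns each symptom's baseline.
* An empty score map refuses to predict; a fully capped lattice raises
  "stimulation space exhausted".
* Duplicate explorations replace rather than average (the newer score
  wins), keeping the IDW interpolant single-valued.
* All randomness flows from explicit seeds: patients rebuild exactly
  from their seed, responder noise uses a private per-step stream, and
  neither touches the caller's RNG state.

## Known limitations

The convergence rule stops a stage as soon as the suggestion lands
within 0.08 normalized units of explored ground, so no session can
refine below roughly a quarter level unit, 14°, or 0.4 mA around its
best explored setting. On simulated patients with the steeper admissible
kernel scales, the noise-free score can change by 0.3–0.4 points across
that resolution; consequently the optimizer's final score lands within
0.2 points of the exhaustive grid optimum in roughly 80–90% of easy
(noise-free, unimodal) seeds rather than always. Tightening the
threshold would buy accuracy at the cost of the ~20-step session length
that motivated it; we keep the threshold and report the trade-off rather
than hide it. The acquisition rule, predefined coordinates and threshold
are behavioral stand-ins for a proprietary method — sessions reproduce
the described explore-then-exploit pattern and burden, not the clinical
algorithm's exact suggestions.
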