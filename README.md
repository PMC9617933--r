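# dbsteer — algorithm-guided programming of directional DBS leads

Programming a directional deep brain stimulation (DBS) system means
choosing, for each hemisphere, a stimulation amplitude and a current
*fractionalization* across the eight electrodes of a 1-3-3-1 segmented
lead (one bottom ring E1, two levels of three segments E2–E4 and E5–E7,
one top ring E8). Multiple independent current control makes this space
far too large for the classical monopolar review, in which a clinician
tests electrodes one at a time. `dbsteer` implements an iterative,
algorithm-guided programming (AgP) loop for this problem, aimed at
researchers studying semi-automatic DBS parameter optimization: it is the
kind of tool one wraps around either a real assessment workflow or — as
shipped and tested here — an in-silico patient simulator.

## What the package computes

**Symptom weighting.** Each candidate symptom is scored 0–4 (0.1
resolution) without therapy (`b_off`) and under reference stimulation
(`b_on`). Its raw weight is the product of untreated severity and
relative improvement,

    w = (Δ/4) · (Δ/b_off),   Δ = b_off − b_on,

quantized to 0.001. Up to four symptoms per hemisphere are kept, their
weights renormalized to sum to one, and each tested setting is collapsed
into the *total weighted score* `S = Σ w̄_i s_i ∈ [0, 4]` (lower is
better), the scalar feedback driving the optimizer.

**Two-stage exploration.** Stage 1 ("ring mode") explores a vertical
position `p ∈ [0, 3]` (level units along the lead axis) crossed with
amplitude; stage 2 ("directional mode") explores a rotation angle
`θ ∈ [0°, 360°)` at the vertical position of the best ring setting.
Continuous coordinates map to concrete integer-percent
fractionalizations by linear interpolation between adjacent levels and
between adjacent segment directions (largest-remainder rounding). Each
stage seeds fixed predefined points (three ring, four directional),
maintains an inverse-distance-weighted score map with side-effect
amplitude boundaries, and repeatedly suggests

    x* = argmin over admissible lattice nodes of
         predicted_score(x) − β(t) · dist_to_nearest_explored(x),
    β(t) = β₀ · decay^t,

which explores far-apart regions first and exploits the best region as
β decays. The stage converges when the suggested point falls within a
normalized distance threshold (default 0.08) of an explored point.

**Similarity metrics.** Two settings are compared by
`SetSim = AmpRat · (1 − NormElcConfDist)` with
`AmpRat = min(A₁,A₂)/max(A₁,A₂)` and `NormElcConfDist` the Euclidean
distance of the signed 9-entry fraction vectors (E1..E8 + case) divided
by √8; outcomes by `ScrSim = 1 − ‖s₁ − s₂‖/√(16N)`; and activated
volumes by the Jaccard index of a deliberately simplified voxel VTA
stand-in (current-scaled spheres, 0.25 mm voxels — *not* a
finite-element activation model).

**In-silico patients.** `make_patient()` draws per-symptom response
fields (Gaussian sweet spot in `p × θ` times a saturating amplitude
response, additive noise, 0.1-score quantization) and a side-effect
threshold surface, in `easy`, `clinical` and `adversarial` presets, so
the whole loop is testable without clinical data; `brute_force_optimum()`
is the exhaustive noise-free oracle used in validation.

## Worked example

```r
library(dbsteer)

pat  <- make_patient(seed = 42, preset = "clinical")
spec <- patient_spec(pat)
spec
#> <weighted_score_spec>
#>   bradykinesia_left            clinician raw 0.810  normalized 0.692
#>   rigidity_left                clinician raw 0.361  normalized 0.308

rec <- run_hemisphere(patient_responder(pat), spec)
rec
#> <session_record> 20 steps (ring + directional), final score 2.44 at 4.7 mA [E1: -50%, E2: -50%]
burden_report(rec)
#> steps to convergence: 20 | steps to best: 19
```

Two symptoms were selected (bradykinesia dominating with normalized
weight 0.69); the loop tested 20 settings across both stages and ended
on a two-level steered setting at 4.7 mA whose total weighted score is
2.44, found at step 19 — like the clinical workflow, the best setting
often precedes formal convergence.

Comparing a standard-of-care against an algorithm-derived setting:

```r
soc <- setting_from_config("E1: -100%", 3.8)
agp <- setting_from_config("E1: -70%, E2, E3, E4: -10%", 3.7)
setting_similarity(soc, agp)
#> [1] 0.85
```

A published settings table in the same dialect ships at
`system.file("extdata", "table1_settings.csv", package = "dbsteer")`;
`compare_settings_tables()` scores all of its hemispheres at once. A
command-line surface is exposed through `dbs_cli()` with the
subcommands `simulate`, `optimize`, `compare`, `export` and `report`.

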