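---
title: "Methods: plate statistics for COPAS SpH RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate statistics for COPAS SpH RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphscreen)
```

This vignette is the package's own account of the statistics it
implements: the measurement model, the normalization and hit-calling
procedure, the choices made where the design was genuinely open, and
what the synthetic-data tests do and do not demonstrate.

## The measurement model

A COPAS large-particle sorter scans worms one at a time and reports, per
object, a time-of-flight (TOF, length), an extinction integral (EXT,
optical density — a worm-size proxy) and an integrated green
fluorescence. For a pan-neuronally expressed synapto-pHluorin (SpH)
reporter, green brightness reads the exo/endocytosis balance of synaptic
vesicles: SpH is quenched in the acidic vesicle lumen and bright at the
plasma membrane.

Brightness scales with the amount of scanned tissue, so the per-worm
signal is normalized by size and log-transformed:

$$\mathrm{RFS} = \log_2 \frac{\text{green}}{\text{EXT}}.$$

The model behind this: green ≈ (SpH signal per unit tissue) × (tissue
amount), EXT ≈ tissue amount, so the ratio isolates the biology and the
log2 makes multiplicative RNAi effects additive. One well of a 96-well
plate holds the progeny of a few RNAi-fed animals; the well's signal is
the **median** RFS of its worms (robust against the occasional
mis-scanned object, air bubble, or larva). Wells with fewer than
`min_worms = 5` worms carry no signal — below that, a "median" is
mostly noise, and very low counts usually mean the clone was sterile or
lethal anyway.

### Plate normalization

Plates differ in incubation time, bacterial density and sorter gain, so
well signals are only comparable within a plate. Each plate is
normalized with the robust Z-score over its experimental wells' medians:

$$rZ_i = \frac{x_i - \mathrm{median}(x)}{\mathrm{MAD}(x)},
\qquad \mathrm{MAD}(x) = \mathrm{median}\,|x - \mathrm{median}(x)|.$$

Mean and SD would be dragged around by the very hits the screen is
looking for; median and MAD are not. Two deliberate details:

- **The MAD is unscaled.** No 1.4826 normal-consistency factor is
  applied by default — the score is a ratio to the plate's own typical
  deviation, not an estimate of σ. `mad_scaled = TRUE` switches the
  factor on for users who want σ-comparable units; it rescales every
  score by the same constant and changes no ranking.
- **Per plate, from experimental wells only.** Estimating the
  median/MAD per plate removes plate offsets exactly (adding a constant
  to one plate changes nothing downstream — this is a property test in
  the suite). Control wells are scored against the plate statistics but
  excluded from estimating them: their planted 6-fold and 0.5-fold
  effects would otherwise inflate the MAD on every plate. Whether a
  single pooled normalization across plates would be preferable is a
  genuine alternative (`normalize_plates(pool = TRUE)` provides it), but
  pooling re-imports plate offsets into the scores, so per-plate is the
  default.

A clone appears on two repeat plates; its score is the mean rZ over
repeats, defined only when both repeats are usable.

## Screen quality control

Three rules, all reported per plate by `plate_qc()`:

- **Controls.** Each plate carries two empty-vector baseline wells, one
  up-regulated control (knockdown of an endocytosis gene, expected ~6×)
  and one down-regulated control (knockdown of the reporter itself,
  expected < 0.5×). The control fold change is
  `2^(median RFS(control) − mean(median RFS(empty)))`. Pass thresholds
  default to 2.0 (up) and 0.7 (down) — deliberately far inside the
  expected 6× and 0.5× magnitudes, so they trip on genuinely failed
  RNAi induction, not on noise. A plate whose controls miss these gates
  gets verdict `fail`.
- **Repeatability.** A clone's between-repeat fold change is
  `2^|RFS_1 − RFS_2|`. Clones above 1.5-fold are flagged; a plate with
  more than 25% flagged clones gets verdict `redo` (re-measure it). The
  flag threshold, like every threshold, is config, and the inequality is
  strict: exactly 1.5-fold passes. Flagged clones are *reported*, not
  silently dropped — in the original screening workflow low-repeatability
  plates are re-run rather than discarded, so by default the pipeline
  does not remove flagged clones from candidacy
  (`exclude_low_repeat_primary = TRUE` restores the harsher behaviour).
  Clone-level removal belongs to the validation round: candidates whose
  two primary repeats disagreed by more than 2-fold are dropped before
  the secondary t-test.
- **Sterile/lethal wells.** A well with strictly fewer worms than 20% of
  its plate's mean experimental-well count is flagged sterile: the F1
  readout is invalid (such clones are re-screened in the parental
  generation instead). The mean includes the candidate well itself —
  with 92 experimental wells the difference is negligible and the
  simpler rule is easier to state exactly. Boundary cases (exactly 20%)
  are not flagged; dedicated fixtures in the test suite pin this.

The screen-wide repeatability report gives the Pearson correlation of
the two repeats' log2 median RFS and the fraction of clones within
2-fold (the band between `y = x ± 1` on the scatter from `plot()`).

## Hit calling

1. **Tails.** Usable clones (not sterile, both repeats present) are
   ranked by mean rZ; the top and bottom `ceiling(tail_fraction/2 × N)`
   become up/down candidates. Ties at a cut break by clone identifier,
   so the candidate set is deterministic even on degenerate inputs (a
   fully tied distribution additionally warns). The default
   `tail_fraction = 0.05` (2.5% per side) encodes a "two tails, 5%"
   design rule; the rule's phrasing is ambiguous between 5% total and 5%
   per side, and the package treats the parameter as total mass. The
   end-to-end demonstrations in this package use 0.06: their generator
   plants effects in 5.43% of clones, and a candidate net narrower than
   the prevalence cannot contain the planted set by construction, so the
   demonstrations widen the design value minimally to cover it. A wider
   net costs precision directly — every extra null candidate
   false-validates at rate α — which is why the net is widened no
   further than the prevalence requires.
2. **Secondary validation.** Each candidate is re-measured on four
   replicate plates; its four well medians are compared to the pooled
   empty-vector medians of the same plates (2 wells × 4 plates = 8
   values) by a **one-tailed** Welch t-test, with the alternative fixed
   by the primary-screen direction. Locking the direction prevents
   post-hoc tail switching; Welch is the default because well replicate
   variances have no reason to be equal (`var_equal = TRUE` gives the
   pooled test). No multiple-testing correction is applied by default —
   the multi-round design (tails, then p < α, then counterscreen)
   controls false calls structurally; `p_adjust = "BH"` is available.
3. **Counterscreen.** The same machinery runs on a strain expressing
   cytoplasmic GFP from a neuronal promoter. A clone that changes that
   signal (p < α, same locked direction) changes expression or
   fluorescence nonspecifically and is excluded. Candidates missing from
   the counterscreen stay `candidate` — never silently validated. This
   rule has an irreducible cost: a genuine hit whose (null)
   counterscreen test lands below α by chance is lost, so expected
   sensitivity is bounded near 1 − α even with huge effects.

## The synthetic screen generator

`simulate_screen()` emulates exactly the features the pipeline must
cope with, each with a planted, recorded truth:

- per-worm EXT is log-normal (`meanlog = log(250)`, `sdlog = 0.3`,
  instrument arbitrary units); green is `base_green_per_ext × EXT ×
  effect × 2^(plate offset + well noise)`. Because green is proportional
  to EXT, the RFS cancels worm size by construction — which is the point
  of the EXT normalization;
- well noise is one N(0, `noise_sd`) draw per well on the log2 scale,
  default 0.25. This default is a free choice: the screening literature
  constrains replicate scatter only loosely, and 0.25 puts ~99% of
  between-repeat fold changes under 2-fold with repeat correlations
  around 0.7–0.8 once ~5% of clones carry control-sized effects —
  realistic for a well-behaved liquid-culture screen;
- plate offsets are N(0, `plate_offset_sd`), default 0. Offsets are
  removed exactly by per-plate normalization but *do* enter the
  between-repeat fold change; the default keeps the two noise sources
  orthogonal in tests, and the plate-offset invariance is exercised by
  planting explicit offsets;
- sterile wells emit Binomial(nominal, 0.1) worms — safely below the
  20% rule, with boundary behaviour pinned by dedicated fixtures rather
  than random draws;
- every clone appears on exactly two repeat plates; every plate carries
  the standard four control wells; a master seed streams into per-plate
  substreams so any plate regenerates independently and the whole run is
  byte-reproducible.

What the generator does **not** emulate: axial fluorescence profiles
along the worm (one integrated green value per object is assumed),
RNAi penetrance biology, spatial plate artifacts (row/column/edge
effects), and developmental stage mixtures. Passing the recovery tests
therefore shows the *statistics* are implemented correctly and
calibrated — not that real screens are free of edge effects or stage
confounds, which would need spatial corrections this package
deliberately omits.

`simulate_paralysis()` draws cumulative paralysis counts from a
discrete-time survival process (per-interval hazard), and
`simulate_tracks()` draws signed velocities from a three-state
forward/backward/immobile Markov chain with specified stationary
fractions and mean dwell time.

## Numerical and degenerate-input choices

- **Even-count medians** are the mean of the central pair (the standard
  convention; it matters for 4-worm wells near `min_worms`).
- **MAD = 0** (a plate whose experimental medians are majority-identical)
  is an error by default — on instrument data it means a failed read or
  a constant-value export, and silently scoring it would be worse. For
  strictly noise-free data (the zero-noise generator limit, where MAD is
  0 on *every* plate), `zero_mad = "center"` scores wells by their
  centred deviations instead, with a warning; this is the only
  meaningful score in that limit and is what the noiseless end-to-end
  tests use.
- **Zero-variance t-tests**, likewise a noise-free-limit artifact, get
  the limiting p-value: 0 if the means differ in the alternative's
  direction, 1 if opposite, 0.5 if equal.
- **Strict inequalities** everywhere a rule has a boundary (20% progeny,
  1.5-fold and 2-fold repeats, p < α): values exactly at a threshold
  pass. The test suite pins each boundary with exact fixtures.
- **Determinism**: ties in candidate selection break by clone
  identifier; a clone cannot enter both tails; hit tables are written in
  a fixed sort order with 6-significant-digit reals, so identical inputs
  give identical bytes.

## Problem sizes in the test suite

The recovery and calibration tests run a duplicated 10-plate screen (92
clones per plate, 920 clones, 50 worms per well) with 50 planted effects
at 6-fold and 0.5-fold — large enough that tail selection, QC and both
validation rounds are all exercised at realistic well counts, and small
enough that the full suite completes in well under a minute per
scenario. The t-test calibration uses 2000 simulated null
candidate/control replicate sets, which bounds the type-I estimate's
standard error at about 0.005; the noisy-recovery checks pool five
generator seeds. These sizes are the package's chosen trade-off between
statistical resolution and test runtime.

## Known limitations

- No spatial (B-score / median-polish / loess edge) correction: the
  plate design this package targets relies on randomized clone placement
  and in-plate controls instead.
- The secondary t-test pools empty-vector wells across the replicate
  plates of a validation set; with only two empties per plate the
  control estimate is shared by all candidates on those plates, so false
  calls arrive correlated (an unlucky control set inflates one
  direction's calls together). More empty wells per validation plate
  would shrink this; the layout is taken as given.
- The counterscreen join is by clone identifier only; clones absent from
  the counterscreen are reported as undecided rather than guessed.
- Paralysis curves are summarized nonparametrically (mean ± SEM per
  timepoint, t-test at a chosen timepoint); no survival-model fitting of
  the hazard is attempted.
- Locomotion analysis consumes signed velocities; head-orientation
  inference from video is upstream of this package, and the immobility
  cutoff (default 0.02 mm/s) has no instrument-independent definition —
  it is a required, explicit configuration choice.
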