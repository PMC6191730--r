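---
title: "Methods: simulating and benchmarking scintigraphic reflux studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and benchmarking scintigraphic reflux studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement being modelled

A scintigraphic reflux study swallows 40–60 MBq of Tc-99m DTPA in water and
images the torso with a gamma camera: 8 upright frames of 15 s (64×64),
then 60 supine frames of 30 s, then — after an oral colloid tracer — a
delayed 256×256 static image two hours later to look for pulmonary
aspiration of refluxate. Time-activity curves (TACs) over the pharynx and
the oesophageal thirds are graded *declining* (grade 1), *flat* (grade 2)
or *rising* (grade 3); a rising curve means refluxate reaches the region
faster than the oesophagus clears it. Aspiration is called from a line
profile through the hilar regions when peak lung count density exceeds
twice the background level.

The package implements the analysis side of this protocol and, because raw
patient images for such studies are not publicly available, a kinetics
simulator detailed enough that every analysis stage can be validated
against known ground truth.

## The compartment model

Six compartments: `stomach`, `lower`/`mid`/`upper` oesophagus, `pharynx`,
`lungs`, plus an `emptied` accumulator for gastric outflow. Dynamics, all
first-order between events:

* The swallowed bolus reaches the stomach within the first frame. A small
  fraction (`transit_residue_fraction`, default 2% of the bolus) remains as
  an adherent mucosal film, split distally-weighted over the four upper
  compartments (50/30/16.5/3.5% from lower oesophagus to pharynx). The film
  is cleared to the stomach by salivary washout at `residue_clearance_rate`
  (default 0.08 min⁻¹, i.e. over tens of minutes) — much slower than bolus
  transit. This film is what makes a healthy, non-refluxing pharyngeal TAC
  *decline* rather than sit at zero, as real normal studies do.
* The stomach empties first-order with half-time `gastric_half_time`
  (default 25.2 min, a typical patient value).
* Reflux events arrive as a Poisson process at a posture-specific rate
  (`reflux_event_rate_upright` / `_supine`, events · min⁻¹). Each event
  instantaneously moves `reflux_fraction` (default 5%) of current gastric
  activity up to the patient's `max_reflux_height`, spread equally over the
  traversed compartments.
* Refluxed activity clears back to the stomach at `clearance_rate`
  (min⁻¹), the kinetic face of oesophageal motility: 0.5 for normal
  motility down to 0.05 for severe ineffective oesophageal motility (IOM),
  with per-patient lognormal jitter.
* During pharyngeal events a fraction `aspiration_fraction` of the
  pharyngeal share is trapped irreversibly in the lungs. It is forced to 0
  unless the reflux height is the pharynx.
* The colloid administration at the end of supine imaging re-labels the
  gastric compartment with fresh activity; only its aspirated fraction
  matters for the delayed image, which is timed two hours after the
  colloid.
* Everything decays with the Tc-99m physical half-life (6.0067 h).

Between events the system is linear and is advanced analytically
(piecewise exponentials), with the `emptied` pool computed as the exact
balance, so decay-corrected activity is conserved to machine precision —
the test suite asserts 1e-6 but observes ~1e-15.

## Rendering and calibration

Compartments are painted into fixed rectangular zones of a schematic
anatomy (pharynx at the top, oesophageal thirds stacked, stomach lower
left, two hilar airway zones flanking the mediastinum, a lateral-chest
background strip), scaled proportionally between the 64×64 dynamic and
256×256 delayed matrices. Expected pixel counts are activity × camera
sensitivity × frame duration / zone pixels, plus a uniform body background;
realized counts are Poisson. The schematic layout means region-of-interest
placement is exactly reproducible without registration.

Two calibration constants matter:

* `sensitivity` = 100 counts·MBq⁻¹·s⁻¹, a typical planar low-energy
  high-resolution collimator figure.
* `background_rate` = 0.3 counts·pixel⁻¹·s⁻¹ at 64×64, scaled by pixel
  area at other matrix sizes (the same soft-tissue activity spreads over
  more pixels), with a 600 s delayed static acquisition.

With these values an aspirated lung burden of roughly 0.15 MBq crosses the
2× background threshold — consistent with the clinical observation that of
the order of 0.1 MBq of aspirated tracer is detectable — while a
never-refluxing patient essentially never false-positives (the per-pixel
exceedance probability is below 1e-8 after 3-row band averaging).

The mucosal-film split deserves a note, because it is pinned from two
sides. The pharyngeal share must be large enough that a no-reflux supine
pharyngeal TAC declines *significantly* (slope z ≈ −6 at these count
rates, so grade 1 in ≥99% of studies), yet small enough that the
uncorrected pharynx-to-background ratio stays below 1.5 in ≥95% of
no-reflux studies. The 3.5% share sits in the window where both hold;
doubling it breaks the ratio bound, halving it breaks grading reliability.

## Curve grading

The published grades are qualitative; the package makes them operational
with one tunable: fit a least-squares line to the TAC, let z =
slope / SE(slope), and call grade 3 if z > z_crit, grade 1 if z < −z_crit,
grade 2 otherwise (z_crit = 2 by default, exposed everywhere). Upright and
supine segments are graded separately. TAC values are mean counts per
pixel per second (so ROI size cancels), background-corrected per frame and
decay-corrected to segment start; the decay correction is ≤6% over the
supine segment but is applied for bit-exact reproducibility.

The z statistic is Student-t, not normal: on 60-point supine curves the
true-flat rejection rate is 2·P(t₅₈ > 2) ≈ 5.0%, close to the normal
2·Φ(−2) ≈ 4.6%; on 8-point upright curves it is ≈9%. Calibration checks of
the type-I rate therefore use supine-length curves.

Gastric half-clearance is log(2)/rate from a log-linear fit to the supine
stomach TAC, returning `Inf` ("not reached") when the fitted rate is not
positive. In a *refluxing* patient the estimate is confounded by activity
returning from the oesophagus (errors up to ~20% at default rates); the
recovery check in the test suite therefore uses a non-refluxing patient,
where the estimate lands within a few percent of the true 25.2 min at
default count rates.

## Cohort generation

`cohort_config()` defaults encode the benchmark study population: 250
patients, 72 GORD / 178 LPR, aspiration probabilities 10/72 and 58/178,
severe IOM 17% / 35% and normal motility 49% / 27% by class (the remainder
split equally between mild and moderate), 24-h pH categories 25/78/147,
LOS pressure lognormal with location ln(2.3) and scale
√(2·ln(6.3/2.3)) ≈ 1.42 — the unique lognormal with median 2.3 and mean
6.3 mmHg. Its SD (~15 mmHg) exceeds the reported 8.4; matching all three
moments would need a different family, and mean/median were preferred as
the quantities that define the reported skew. pH categories are drawn
directly from the configured probabilities (the study does not say how its
categories were derived from the 24-h traces), while `classify_ph()`
implements the episode rule itself: minimum pH < 4 acid, [4, 7) weakly
acid, ≥ 7 non-acid.

Couplings go through a Gaussian copula with rank-preserving marginals:
proximal–distal acid exposure targets Pearson r = 0.32 (gamma marginals
attenuate the latent correlation slightly; the realized mean over seeds is
≈ 0.30, within ±0.05 of target), and the severe-IOM/aspiration phi
coefficients (0.54 LPR, 0.21 GORD) are hit by numerically inverting the
tetrachoric relation for the latent correlation. A latent IOM–reflux-rate
coupling (0.45) plus the IOM→clearance map makes the IOM versus
rising-curve association *emergent* rather than assigned. Aspirators are
forced to pharyngeal reflux height with a positive aspiration fraction
(Beta, mean 0.05); everything else about their images is emergent.

Randomness policy: one master seed; patient *i* draws from a substream
seeded by a documented counter scheme (`patient_seed()`), so enlarging a
cohort never reshuffles existing patients, and every pipeline stage is
bit-reproducible given the seed.

## Statistics

Fisher's exact two-sided p uses the sum-of-small-p convention (sum of all
hypergeometric probabilities ≤ the observed one, with a 1e-7 relative tie
tolerance — the common software convention; other two-sided definitions
exist). It is validated against exhaustive enumeration on every 2×2 table
of total ≤ 12 and against `stats::fisher.test`. AUC is the tie-corrected
rank concordance (equal to the trapezoidal area, asserted to 1e-12), with
the Hanley–McNeil SE and a two-sided normal test of AUC = 0.5; ordinal
markers such as curve grades enter as scores with ties counted ½.
Predictive values follow the convention row 1 = test positive (rising
curve), column 1 = outcome (aspiration); undefined cells are returned as
`NA`, never silently 0. No multiplicity correction is applied, matching
the original analysis (each test at 0.05); the report footer says so.

```{r, eval = FALSE}
library(refluxscint)
pl <- run_pipeline(cohort_config(), seed = 1)
pl$report
```

## What the simulator does and does not establish

Passing tests show the *analysis chain* is correct and well calibrated for
data generated by this kinetic model: grades track true reflux burden and
clearance (balanced accuracy ≥85% on 200-patient cohorts), aspiration
detection operates at ≥0.9 sensitivity and specificity against ground
truth, and a declining supine pharyngeal curve has high negative predictive
value for aspiration (≈0.91 on average over cohorts). They do not certify
performance on real images: the schematic anatomy has no scatter,
attenuation, collimator blur, patient motion or overlap of structures, the
event model ignores bolus transit times and swallow-triggered clearance
waves, and the published predictive values (97–98%) were obtained by human
readers on real studies. One study-level figure is known not to replicate
under the model's own sampling assumptions: with aspiration labels drawn
binomially at the study's class rates, the power of Fisher's test for the
class contrast is ≈0.88 at n = 250 (≈0.79 at n = 200), so the class
difference is *not* significant in every simulated cohort, and the test
suite reports the measured fraction rather than forcing it.

## Problem sizes used in the checks

The test suite simulates 200-patient cohorts for end-to-end operating
points (5 seeds, pooled), 100–200 cohort draws for calibration and
correlation checks, 1000 replicates for type-I-rate and coverage checks,
and exhaustive enumeration for the small-table oracles. The acceptance
script runs one full 250-patient default cohort. These sizes were chosen so
the whole suite completes in minutes while keeping Monte-Carlo error well
inside the asserted tolerances.
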