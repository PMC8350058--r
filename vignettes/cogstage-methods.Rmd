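---
title: "Methods: actuarial cognitive staging and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actuarial cognitive staging and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogstage)
```

## The problem

Subtle cognitive decline precedes a clinical diagnosis of mild cognitive
impairment (MCI) or dementia by years. Longitudinal ageing cohorts
therefore distinguish, among cognitively unimpaired (CU) participants,
those who are *stable* (CU-S) from those who are *declining* (CU-D):
performing below demographic expectation, or below their own history,
without meeting clinical criteria. `cogstage` implements an operational
version of that staging — robust internal norms, a deliberately
over-sensitive flagging algorithm, and a deterministic actuarial
assignment — together with the statistical analyses used to argue that
CU-D is a valid risk marker: concurrent group separation, within-person
change, progression/reversion dynamics, and amyloid/tau PET biomarker
contrasts.

Because the motivating cohort's records are not publicly deposited, the
package carries a first-class synthetic-cohort generator. Its defaults
are the package's *study conditions*: they are calibrated once (see
below) and all tests run against them.

## Robust internal norms

For each test, an OLS model of the oriented raw score on age, sex and
literacy (reading standard score) is fitted over a *robust subsample* —
visits from participants believed cognitively stable — so impaired
observations do not distort expectations. Scores on "lower is better"
instruments (Trail Making B time, error counts, completion times) are
sign-flipped *before* fitting, so `z = (score - prediction) / residual SD`
always reads "higher is better".

The exact robust-subsample construction of the internal-norms literature
is not restated in our sources, so the package fixes a two-pass scheme
(`robust_norms()`): pass 1 flags on norm-free criteria only (raw clinical
cut-offs, informant cut-offs) and fits preliminary norms on never-flagged
participants; pass 2 stages every visit with those norms and refits on
participants never assigned CU-D/MCI/dementia. The scheme iterates once
and stops — further iterations change little and a fixed procedure keeps
the pipeline deterministic.

Five composites are built from the battery: immediate learning, delayed
recall, executive function, a three-test PACC (AVLT Total, Logical
Memory II, Digit Symbol), and a four-test computerized global composite
(CPAL, GML-MPS, GML-CT, OCL) that tolerates one missing member; the
pencil-and-paper composites require all members. A composite is the mean
of its contributing z-scores converted to a standard score. Converting
"to mean 100, SD 15" requires a divisor: the mean of correlated-but-not-
identical z-scores has SD below 1, so the plain affine map
`100 + 15 * mean(z)` cannot have SD 15. `composites()` therefore accepts
a per-composite scale divisor. With the default `scale = 1` the affine
formula holds exactly (all z at −1 gives 85); the pipeline supplies
divisors fitted as the SD of the mean z over the robust subsample, so
*reported* composites genuinely have mean 100, SD 15 there. Flagging
(below) uses the unscaled mean domain z, keeping the flag thresholds on
the natural z scale.

## Two-tier staging

**Tier 1 — flagging** (`flag_visits()`). A visit is flagged when any
criterion fires:

* raw clinical cut-offs: Clock Draw ≤ 7, MMSE ≤ 26, AVLT Delayed
  Recall ≤ 5, Logical Memory II ≤ 16;
* informant cut-offs: CDR ≥ 0.5, QDRS ≥ 0.5, Lawton IADL < 14
  (0–16 scale), IQCODE > 52 (16–80 scale, 48 = no change);
* any staging-domain composite (immediate, delayed, executive) at mean
  z ≤ −1.5. The computerized battery is excluded from staging to keep a
  non-circular outcome.

Ties follow the printed inequality directions exactly, with no tolerance
band. Missing inputs never fire a criterion.

**Tier 2 — assignment** (`assign_status()`). The original process sends
flagged records to a human consensus conference; no deterministic code
can reproduce clinical judgement. The package substitutes explicit
actuarial rules in the Jak/Bondi tradition, stated openly as the largest
modelling gap: the *cognitive criterion* holds when ≥ 2 tests within one
staging domain fall at z ≤ −1.5 or any raw clinical cut-off fired; a
flagged visit is **MCI** when the cognitive criterion holds with
preserved instrumental functioning (IADL ≥ 14), **DEMENTIA** when it
holds with functional loss (IADL < 14) and CDR ≥ 1, and **CU-D**
otherwise. Unflagged visits are CU-S by definition, so CU-S is exactly
"empty fired set". `IMPAIRED_NON_MCI` exists only as an exclusion label
for ingested data; the assignment never produces it.

**Outcomes.** Primary progression is MCI/dementia at some visit ≥ 2 *and*
at the most recent visit; any-visit progression drops the second
condition; next-visit events give the transition pairs used for
reversion. Reversion denominators are status-visits with a follow-up,
allowing repeat statuses within person.

## Statistical machinery

* `cliffs_delta()` — midrank computation of
  P(X > Y) − P(X < Y); magnitude bands 0.147 / 0.33 / 0.474 from the
  conventional effect-size literature.
* `exact_binomial_ci()` — Clopper–Pearson by default (beta quantiles;
  coverage is at least nominal), plus `wilson_cc` (the score interval
  with continuity correction, which is what reproduces printed clinical
  intervals such as 17.7–46.3 for 13/43) and `wald` for large-n
  proportions (44–52 for 269/558).
* `bh_fdr()` — Benjamini–Hochberg step-up via `p.adjust`.
* `two_proportion_power()` — two-sided two-proportion z-test power,
  normal approximation without continuity correction (pooled variance
  under the null, unpooled under the alternative).
* `change_ancova()` — change on group + baseline + interval, adjusted
  means at covariate means, pairwise Wald contrasts, and a
  Kruskal–Wallis check on residuals from the covariates-only fit.
* `logistic_progression()` — IRLS logistic fit; Wald CIs on odds
  ratios; complete separation raises an error rather than returning
  diverged estimates. With no covariates it reproduces the closed-form
  2×2 cross-product ratio to numerical precision.
* `group_compare()` — ANOVA / Kruskal–Wallis / Fisher omnibus with
  pairwise follow-ups (Welch t, Wilcoxon rank-sum, pairwise Fisher) only
  when the omnibus is significant, optionally BH-corrected.

## PET biomarkers

`logan_dvr()` implements reference-region Logan graphical analysis with
k2′ = 0.149 min⁻¹, trapezoid integration from time zero, and an OLS slope
over frames with mid-time ≥ t\* = 35 min (the sources do not state the
linear window or quadrature; 35 min is comfortably past equilibration
for the simulated kinetics, and the identity and proportional-curve
cases are exact by construction). PiB positivity is DVR ≥ 1.2 (a
configuration constant, not recomputed). Chronicity is assessment age
minus estimated onset age; onset is estimated by anchoring a population
DVR-versus-age sigmoid through the observation (shifting its midpoint)
and solving for the threshold crossing with root-finding to 1e-6 years.
The cited group-based trajectory model is external, so this single
shifted-sigmoid inversion is a functional substitute, not a
reproduction. Tau positivity thresholds are mean + 2 sample SD of the
PiB-negative subset per region, with strict `>` for positivity; the
published cut-offs (1.27 / 1.12) depend on that cohort's PiB-negative
sample and only the rule is reproducible. Status at PET is taken from
the assessment nearest the scan, earlier visit winning exact ties.

## The synthetic cohort and its calibration

`generate_cohort()` draws, per participant: baseline age N(54, 6.6²),
70% female, literacy N(106, 9²), 2–6 visits (weights mirroring the
observed most-recent-visit distribution; median 5) at truncated-normal
intervals (mean 2.3 y, SD 0.3, minimum 1). Latent states CU_S, CU_D,
MCI, DEMENTIA evolve as a first-order Markov chain per interval — the
simplest structure that produces both progression and reversion — with
baseline mass only on CU_S (90.3%) and CU_D (9.7%), mirroring enrollment
exclusions.

Raw scores are generated exactly as the norming module assumes:
prediction from the demographic model, plus a state shift, plus unit
noise scaled by the test's residual SD. Two structural features matter:

* **Trait persistence.** Test noise splits into a stable
  participant-test trait (78% of variance) and fresh visit noise — a
  2-year test–retest correlation in the realistic range for
  demographically adjusted scores. Persistence is what makes assigned
  CU-D sticky enough to revert at realistic rates, and it concentrates
  false flags in the same people, which the baseline conditioning then
  largely removes.
* **A focal CU-D deficit.** Each CU-D participant has one affected
  memory domain and within it one focal test at −3.6 z (other tests of
  the domain −0.15, other domains −0.35 to −0.4). An isolated deep
  deficit is the phenotype the domain-composite flag detects *without*
  tripping the two-test MCI rule; a uniform CU-D shift deep enough to
  flag reliably would be classified MCI by the actuarial rules almost as
  often as CU-D. Focal tests are restricted to instruments without raw
  clinical cut-offs so a subclinical deficit does not cross a clinical
  threshold by construction. MCI and dementia use uniform domain shifts
  (memory ≈ −2 and −3 z).

Informant ratings come from per-state models (abnormal CDR/QDRS
probabilities 3.1 / 12.4 / 42 / 90%; binomial IADL deficits; Poisson
IQCODE excess over 48) driven by participant-level propensities with
persistence 0.90, so informant concerns recur across visits. Amyloid is
a mixture of non-accumulators (DVR ≈ N(1.05, 0.045²)) and accumulators
whose DVR follows the trajectory sigmoid of age with onset-age
distributions tied to the final latent state; tau SUVRs are state- and
region-specific normals. One global seed drives every draw in fixed
order, so identical configurations give byte-identical outputs.

**Calibration.** The published aggregate rates — primary progression
2.9% from a CU-S baseline and 13.5% from CU-D, per-visit CU-D→CU-S
reversion 48.2% — are properties of *assigned* statuses, after
misclassification by flagging and the actuarial rules. Calibrating the
latent chain to those numbers directly therefore overshoots badly (the
assigned rates came out near 8% and 79% in early calibration runs), so
the default transition matrix was tuned against the full pipeline —
generator, two-pass robust norms, staging — and then frozen:

```{r}
round(default_transition_matrix(), 3)
```

The CU_S→MCI entry is small (0.001) because most assigned progression
arises through the CU-D pool and through detection of latent MCI; the
CU_D→CU_S latent reversion (0.16) is well below the assigned 48% because
assigned reversion also includes transient false flags resolving and
focal deficits slipping under the flag threshold. Fitted norms shrink
residual SDs a few percent relative to truth (the robust subsample is
truncated on the same traits that drive flagging); the calibration was
done against the pipeline as implemented, so this bias is absorbed.

## What the generator does and does not emulate

It emulates the cohort's structure: visit cadence, demographics, latent
progression/reversion dynamics whose assigned rates fall inside the
published confidence intervals, state-separated composites, informant
behaviour, and state-separated biomarkers. It does **not** emulate the
original test-score distributions or floors/ceilings (scores are
continuous and unbounded), missingness mechanisms, practice effects,
family structure or genetics, or the judgement of a consensus panel.
Passing tests on this cohort show the pipeline is internally coherent
and recovers known ground truth under realistic dynamics — not that it
reproduces any particular cohort's tables. One known divergence: the
direction of next-visit reversion *from MCI* skews toward CU-S rather
than CU-D (the published split is 30.2% to CU-D, 20.9% to CU-S), because
a memoryless actuarial rule re-labels a transiently false-positive MCI
visit as CU-S the moment its flag clears, where a consensus panel
remembering last year's discussion would more often step down to CU-D.

## Numerical choices and problem sizes

Tolerances: transition-matrix row sums to 1e-12; Logan identity and
proportionality exact to 1e-9; onset-age root-finding to 1e-6 years;
odds-ratio closed-form agreement to 1e-6. Degenerate inputs error
loudly: constant predictors name the predictor, zero-variance robust
scores refuse to fit, empty samples and invalid counts are rejected,
complete separation in the logistic model is an explicit error. The test
suite uses cohorts of 500–5,000 participants (30,000 for the
transition-frequency property, giving > 10⁵ transitions), 10⁵
Monte-Carlo replicates for the power cross-check, and 1,000 random
samples for the Cliff's-delta enumeration check — sizes chosen so the
whole suite runs in well under a minute while keeping Monte-Carlo error
far below the tested tolerances.
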