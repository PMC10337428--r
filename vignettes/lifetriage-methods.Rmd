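---
title: "Anticipatory triage ranking: model, generator, and analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipatory triage ranking: model, generator, and analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetriage)
```

## The problem

In a mass casualty incident, classic field triage (START, T-RTS banding)
assigns each casualty one of four categories — green (minimal), yellow
(delayed), red (immediate), black (deceased/expectant) — from a snapshot of
vital signs. Two casualties in the same category can have very different
prognoses: a walking patient with a severe internal injury is START-green
today and critical in two hours. `lifetriage` implements an anticipatory
alternative: a dynamic model of each casualty's expected health state over
time, from which a *ranking* by anticipated survival time without treatment
is derived. Categories can still be produced (by banding the survival
time), but the ranking preserves within-category variability.

## The LIFE time-course model

The expected health state ("LIFE percentage", 100 % = unharmed) of an
untreated casualty follows a modified Boltzmann sigmoid,

$$L(t) = L_0\,\frac{B(t)}{B(0)}, \qquad
  B(t) = \frac{1}{1 + e^{(t - t_{50})/\tau}},$$

with

* $L_0 = 100\cdot\mathrm{RTS}/\mathrm{RTS}_{max}$ — the plateau is set by
  the current vital signs through the weighted Revised Trauma Score
  ($\mathrm{RTS}_{max} = 7.8408$);
* $t_{50} = t_{ref}\,(1 - \mathrm{NISS}/75)\,(f + (1-f)\,
  \mathrm{RTS}/\mathrm{RTS}_{max})$ — the decompensation midpoint shrinks
  with injury severity (New Injury Severity Score) and, damped by the
  floor fraction $f$, with deteriorating vitals;
* $\tau = \tau_{ref}\,(1 - \mathrm{NISS}/75) + \tau_{min}$ — severe
  injuries decompensate faster.

Normalising by $B(0)$ pins $L(0) = L_0$ exactly, which yields the three
clinically motivated phases: a compensation plateau (vegetative
counter-regulation), a near-linear decompensation around $t_{50}$, and a
prolonged asymptotic fatal tail. The model is deliberately *ordinal in
time*: it has not been calibrated against real survival data, so absolute
times should be read as a ranking device, not as predictions.

The survival time without treatment solves $L(t) =$ `death_threshold_pct`
in closed form,

$$t^\ast = t_{50} + \tau\,\ln\!\left(\frac{1}{B_t} - 1\right),
  \qquad B_t = \frac{\theta\,B(0)}{L_0},$$

clamped to $[0,\,t_{horizon}]$. Casualties are ranked by ascending
$t^\ast$ (`rank_cohort()`), ties broken lexicographically by patient id so
the ranking is a deterministic total order.

### Parameters, defaults, and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `death_threshold_pct` | 5 | % | the sigmoid never reaches 0; a small positive threshold keeps the crossing time finite and represents the irreversibly moribund state |
| `t_ref_min` | 10080 | min | midpoint scale = the 7-day horizon, so only a near-unhurt casualty with perfect vitals stays compensated for the whole week; an untreated severe polytrauma decompensates within hours |
| `tau_ref_min` | 120 | min | decompensation of a minor injury unfolds over a few hours |
| `tau_min_min` | 10 | min | floor so the NISS = 75 curve still declines at finite speed |
| `rts_floor_frac` | 0.25 | — | even with the worst measurable vitals, a quarter of the NISS-determined compensation time remains; prevents the vitals term from zeroing the midpoint |
| `t_horizon_min` | 10080 | min | ranking must be total: "stable for a week without treatment" is the sentinel replacing an infinite survival time |

Two boundary conventions matter: RTS = 0 means $L_0 = 0$ — dead at
assessment, survival time 0; NISS = 75 (or any AIS-6 injury, which forces
NISS 75) zeroes the compensation phase, so the curve declines immediately.

Monotonicity — survival time nonincreasing in NISS at fixed RTS and
nondecreasing in RTS at fixed NISS — is not assumed but *verified
exhaustively* over the complete admissible input space (125 RTS code
triples × NISS 1–75) in the acceptance suite.

## Triage comparators and threshold calibration

`start_triage()` implements the START cascade (walking → green; not
breathing after an airway maneuver → black; RR > 30, capillary refill
> 2 s or absent radial pulse, or not obeying commands → red; else
yellow). `rts_triage()` bands the unweighted code sum (12 green, 11
yellow, 4–10 red, ≤ 3 or not breathing black). `life_triage()` bands the
survival time: ≤ 30 min black, ≤ 7200 min red, ≤ 8500 min yellow, longer
green.

Two deliberate design choices:

* **Breathing override.** LIFE triage applies the same first rule as the
  other two algorithms (no breathing after the airway maneuver → black).
  Without it, an apnoeic casualty with measurable blood pressure would be
  "red" by survival time alone while START and T-RTS call them black; the
  override keeps the black category commensurable across algorithms.
* **Threshold calibration.** The red/yellow bounds are not free knobs;
  they were fixed once by calibrating against the default generator so
  that three constraints hold by construction and with margin (≈ 215 min
  below the red bound, ≈ 700 min above the yellow bound, verified over
  the exhaustive band × integer-vitals space, not just sampled cohorts):
  no casualty with NISS > 25 can be green, every yellow casualty has
  NISS 10–25, every green casualty has RTS > 7.5. The bounds live in
  `life_thresholds()` and can be re-calibrated if the generator tables
  are replaced.

## The synthetic cohort: a stated world

`generate_cohort()` emulates a semisupervised build of an artificial
casualty database:

1. a catalog of 67 realistic (trauma type × body location) pairs over 14
   types and 13 locations, each with a fixed AIS severity
   (`default_trauma_catalog()`);
2. full enumeration of all 1–3 injury subsets (45 785 combinations with
   the default catalog), minus anatomically impossible ones: three
   same-type injuries confined to two paired extremities, or two injuries
   in one unpaired ("azygos") region;
3. NISS from the AIS triple; 4. vitals drawn uniformly from one of seven
   NISS bands partitioning 1–75 (`default_vital_sets()`), then dependency
   rules: no palpable radial pulse below 80 mmHg, capillary refill
   prolonged by 1 s per 20 mmHg below 100 (capped at 10 s), commands
   obeyed only at GCS ≥ 13, walking only if the band's Bernoulli draw
   succeeds *and* GCS ≥ 13, RR > 0, and no lower-extremity injury of
   AIS ≥ 2.

The catalog AIS mix was chosen once so the enumerated NISS histogram is
right-skewed with its mode at 14 (most casualties lightly injured); the
vital bands encode the intended correlation "low NISS → near-normal
vitals". Everything is seed-deterministic, bit for bit.

**What the generator does *not* model** — and therefore what a green test
does not establish: age and comorbidity, treatment effects and re-triage,
time-staggered casualty arrival, measurement noise in the field, and any
empirical NISS–vitals joint distribution (the bands are stipulated, not
fitted). Tests against this cohort validate internal consistency of the
algorithms, not external clinical validity. The catalog and band tables
are synthetic stand-ins and fully replaceable by CSV tables of the same
shape.

## Mixed-data cohort analytics

The 27 clustering features (`default_feature_spec()`) are the six
measured vitals, four binary assessments, 13 per-location maximum AIS
values, injury count, NISS, RTS, and the survival time. The T-RTS is
excluded (exactly collinear with the RTS codes), as are the triage
categories themselves — clustering on the labels being compared would be
circular.

* **Gower dissimilarity** (`gower_matrix()`): numeric features contribute
  $|a-b|/\mathrm{range}$, binary/categorical contribute 0/1, missing
  values drop out with weight renormalisation; constant features are
  skipped. Verified against a loop-written oracle and `cluster::daisy`.
* **PAM** (`pam_cluster()`): BUILD + best-improvement SWAP on the
  precomputed matrix, all ties to the lowest index, hence fully
  deterministic without a seed. On 8-point instances it matches
  exhaustive k-medoids except where the BUILD+SWAP local optimum is
  genuinely not global (one such instance is pinned in the unit tests;
  `cluster::pam` lands on the same local optimum there).
* **Silhouette selection** (`silhouette_select_k()`): mean silhouette
  width per k, singletons contribute 0, ties to the smaller k.
* **t-SNE** (`embed_2d()`): a visualisation adapter around `Rtsne` on the
  precomputed distances. Its contract is structural only — finite n × 2
  output, reproducible per seed, blobs separate; no geometric claim
  beyond that is made or tested.
* **Consensus comparison** (`consensus_compare()`): the consensus subsets
  are the casualties all three algorithms label identically; a focus
  cluster is adjudicated by nearest consensus means in NISS, RTS and
  survival time, majority over the three variables, ties toward the more
  urgent category. Under the default bands the three-way *yellow*
  consensus is structurally empty (LIFE-yellow implies NISS 16–22, whose
  vitals band reaches T-RTS 11 only via GCS 12, which makes START red);
  the function warns and excludes empty subsets.

Clustering memory scales as n²: the full default cohort (≈ 46 k) would
need a ≈ 17 GiB distance matrix, so the pipeline subsamples (the CLI
default is 2000; analyses in the test suite use seeded subsamples of a
few thousand).

## Numerical choices and degenerate inputs

* Closed-form survival times agree with a root-finding oracle on the
  sampled curve to < 0.1 min; $|L(t^\ast) - \theta| \le 10^{-6}$ whenever
  the crossing is interior.
* RTS values are kept at full double precision internally; 4-decimal
  rounding is display-only (the worked value 6.8174 is exact).
* Empty injury lists, AIS outside 1–6, out-of-range vitals, non-monotone
  time grids, overlapping or gapped NISS bands, unknown algorithm names,
  and inconsistent declared scores in input files are all validation
  errors that name the offending field or patient.

## Known limitations

The model is a proof-of-concept ranking device: survival times are not
calibrated to outcome data; the default catalog, vital bands, scenario
roster and feature list are documented synthetic stand-ins; and the
comparator set is limited to START and T-RTS banding (no SALT, Sieve, or
resource-constrained policies).
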