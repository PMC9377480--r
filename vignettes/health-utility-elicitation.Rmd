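---
title: "Adaptive health-utility elicitation for ESKD transplant decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive health-utility elicitation for ESKD transplant decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huassess)
```

## The problem

Patients with end-stage kidney disease (ESKD) face a consequential choice:
wait years for an HCV-unexposed donor kidney, or accept a much shorter wait
for a kidney from an HCV-viremic donor.  Decision models for this choice
need *utilities* — preference weights on a scale anchored by full health
("Well", 100) and "Dead" (0) — for three health states: chronic
hemodialysis, transplantation with an HCV-unexposed kidney, and
transplantation with an HCV-viremic kidney.  `huassess` implements the
computational core of a platform for eliciting those utilities at the
dialysis chair, together with a simulated-respondent model, a calibrated
synthetic-cohort generator, and the statistical analyses such a feasibility
study reports.

## The three instruments and their common scale

All three instruments resolve to a fraction $p^\* \in [0, 1]$ on an anchor
pair $(\text{best}, \text{worst})$, converted to the 0–100 scale by linear
interpolation $u = p^\* u_{best} + (1 - p^\*)\, u_{worst}$:

* **Standard gamble (SG).** The respondent chooses between the sure
  intermediate state and a gamble between the best anchor (probability
  $p$) and death.  The indifference probability is the utility.  Read the
  other way around, an SG utility $u$ implies a maximum acceptable risk of
  immediate death of $100 - u$ percent (`implied_death_risk()`).
* **Time trade-off (TTO).** The respondent trades a full horizon $H$ of
  remaining life in the target state against $t \le H$ years in the best
  anchor; the utility is $t/H$ at indifference.  $H$ is the remaining life
  expectancy for the patient's age and sex, looked up in a period life
  table (`tto_horizon()`, rounded to the nearest whole year, floor 1).  A
  synthetic life table ships under `extdata`; any CSV with columns
  `age,sex,ex` drops in.
* **Visual analog scale (VAS).** A single "feeling thermometer" placement
  on 0–100; not adaptive.

### Chained assessment of the HCV-viremic state

The HCV-viremic transplant state is assessed in a second part whose *best
anchor is itself an intermediate state*: transplantation with an
HCV-unexposed kidney, at the utility just elicited for that patient.  The
chained raw fraction is mapped back to the common scale by multiplying it
by the anchor's utility (`normalize_chained_utility()`), so a chained
result can never exceed its anchor.  This design makes the gamble a direct
measure of the risk a patient would accept to avoid the HCV-viremic organ.

```{r chained}
normalize_chained_utility(0.80, 90.7)
implied_death_risk(75.5)
```

## The titration engine

SG and TTO sessions are driven by a "ping-pong" ladder of probe fractions
(default 0.95, 0.05, 0.85, 0.15, 0.75, 0.25) followed by bisection, all
configurable via `titration_config()`.  The engine maintains a nested
bracket $[low, high] \subseteq [0, 1]$ that never widens:

* a **SURE/STAY** response at probe $p$ records the indifference point at
  or below $p$ (`high <- p`);
* a **GAMBLE/TRADE** response records it above $p$ (`low <- p`).

Ladder probes outside the current bracket are skipped; the first response
reversal ends the ladder and starts bisection; the session is DONE when
the bracket width reaches the resolution (default 0.005, i.e. half a point
on the 0–100 scale), and the indifference point is the final bracket
midpoint.  This bound-update convention is fixed jointly with the
simulated respondent (which answers SURE/STAY exactly when the offered
fraction is at or above its threshold), so a deterministic threshold
respondent is always recovered to within the resolution; the nested
design also makes outright contradictory response sequences
unrepresentable — noisy answers mis-place the bracket rather than
corrupting the state.

TTO trades are posed in whole months on the $12H$-month grid and converted
back to years, which keeps offers realistic to read aloud.  The month grid
caps precision at $1/(12H)$, so the half-point recovery guarantee holds
for horizons of roughly 17 years and up; at the study's typical remaining
life expectancies (around 25 years at the median age) the month grid is
finer than the titration resolution.  The exhaustive-grid test runs at
horizon 25 for this reason.

```{r engine}
r <- respondent_profile(c(HEMODIALYSIS = 0.825, TX_UNEXPOSED = 0.89,
                          TX_HCV_VIREMIC = 0.755))
u <- run_auto_session("SG", "HEMODIALYSIS", respondent = r)
u
attr(u, "session")$n_questions
```

## The simulated respondent

`respondent_profile()` holds latent utilities on $[0, 1]$ (Well fixed at
1, Dead at 0), an additive per-method bias, and an optional Gaussian
per-question perturbation of the comparison threshold
(`response_noise_sd`, with ties resolving to the sure/stay option and a
seeded noise stream for reproducibility).  For a chained session the
latent target is re-expressed on the chained scale by dividing by the
respondent's latent anchor utility and clamping to $[0, 1]$.

The additive SG bias is the simplest mechanism that reproduces the
well-documented tendency of SG utilities to sit above TTO and VAS values
for risk-averse respondents; it is a property of the simulator's
configuration, not an estimate from data, and a probability-weighting
mechanism could replace it behind the same interface.  Magnitudes are free
parameters (the default is 0).

## Calibrating the synthetic cohort

The generator's job is to produce cohorts whose *observable* summary
statistics match the published study tables: a 63-patient cohort with 44
African American and 19 European American patients, 33 men and 30 women,
the education mix, ages 21–80 with mean 57.8 (SD 12.3), pretest knowledge
79.0 (17.3) on a 10-item test with mean change 10.0 (SD 13.8), nine
patients with a prior transplant, and the nine (state, method) utility
means and SDs.  Categorical counts are matched exactly per cohort (seeded
permutations of the configured multiset); continuous targets are matched
in distribution by moment-matching calibrators solved once and cached.

Three distributional families are used, each chosen for what the
observable actually is:

* **Censored (clamped) normal for utilities.**  A normal on an unbounded
  scale clamped to $[0, 100]$, i.e. with point mass at the bounds.  This
  matters: the truncated-normal family has a hard ceiling on the SD it can
  reach at a given mean (its $\sigma \to \infty$ limit is an exponential
  tilt; at mean 82.5 the ceiling is about 16.8 points, at mean 89 about
  10.9), and most of the study's utility rows — e.g. 82.5 (SD 23.1) — lie
  *above* that ceiling.  Real rating data achieve such spreads by piling
  up at 100, which is exactly what censoring produces.
  `calibrate_censored_normal()` attains any SD below the two-point bound
  $\sqrt{(m - low)(high - m)}$; `calibrate_truncated_normal()` is also
  provided and raises a calibration error naming the binding bound when a
  target is unattainable.
* **Truncated normal for age**, where the $[21, 80]$ window is a hard
  inclusion criterion rather than a measurement floor/ceiling.
* **Discrete grid models for the knowledge test.**  Scores are multiples
  of 10 on a 10-item test, and the posttest is capped at 100.  Naively
  drawing the change from a normal with the target moments would
  undershoot the realized mean change, because patients already at the
  ceiling can only stay or fall.  The calibrator instead solves the
  realized-moment equations exactly (discrete sums over the grid, nested
  root-finding): the raw change draw ends up with a substantially higher
  mean than 10 so that the *realized* rounded, clamped change score has
  mean 10.0 and SD 13.8.

All solvers verify both moments to $10^{-6}$.  Within a patient, a single
shared uniform rank is pushed through every calibrated marginal, so
within-patient orderings across states and methods are coherent (a
patient who rates hemodialysis high tends to rate everything high) while
every marginal stays exactly moment-matched; the study publishes no joint
distribution, so this rank coupling is a modeling choice.  Dialysis
vintages are lognormal per race (means 7.3 and 2.79 years with a common
coefficient of variation approximating the overall SD of 8.1): a
normal-family model cannot reach that spread at a mean of 2.79 on a
nonnegative support, while the lognormal matches any mean/SD pair and its
right skew matches how vintages actually look.

One edge case is handled explicitly: a censored latent transplant utility
can be exactly 0 (about 0.1% of draws), which makes the chained scale
degenerate.  Such patients are recorded with a chained HCV-viremic
utility of 0 on the common scale and a missing raw fraction.

```{r cohort}
cohort <- generate_cohort(default_calibration(), seed = 1)
cohort
table(cohort$patients$race)
```

`simulate_study()` runs the full two-part protocol per patient — the two
Well/Dead-anchored states first, then the chained HCV-viremic state
anchored on that patient's just-elicited transplant utility — and with
noise-free respondents every elicited utility lands within the titration
resolution of its latent target, so replicate grand means converge on the
configured table values.  What those calibration round trips show is that
the elicitation engine and the calibrators are mutually consistent under
the generator's assumptions; synthetic cohorts do not reproduce features
the generator does not model (item-level response patterns, joint
demographic–utility dependence, COVID-era cohort shifts), so passing round
trips are not evidence about real patients.

## Study statistics

* `change_scores()`, `cronbach_alpha()` (the usual
  $\frac{k}{k-1}\bigl(1 - \sum s_i^2 / s_T^2\bigr)$ with sample
  variances; undefined for zero total variance).
* `rank_sum_test()` and `signed_rank_test()` use midranks for ties and
  are **exact by full enumeration** for total $n \le 12$ (rank-sum) and
  nonzero $n \le 15$ (signed-rank, zeros dropped first) — caps at which
  enumeration stays well under a second — and otherwise use the
  tie-corrected normal approximation with continuity correction.  Exact
  two-sided p-values count arrangements at least as far from the null
  mean as observed.  Each result records which method produced it.
* `ranking_proportions()` counts patients rating the HCV-viremic
  transplant strictly below hemodialysis; prose-style outputs round
  percents to the nearest integer (half up), table-style outputs keep one
  decimal — both conventions appear in study reports.
* `vintage_correlation()` and `subgroup_decrement()` analyze the
  per-patient SG decrement $U_{SG}(\text{HCV}) - U_{SG}(\text{HD})$
  against dialysis vintage and prior-transplant status.
* `sample_size_two_sample_t()` returns the smallest integer n per arm
  achieving the target power under the noncentral-t distribution; with a
  12-point detectable difference and SD 16.3 it returns the study's
  design size of 30 per arm (the SD behind the published design is not
  stated; 16.3 is the value consistent with it, used here as a fixture
  constant).

```{r stats}
sample_size_two_sample_t(delta = 12, sd = 16.3, alpha = 0.05, power = 0.80)
rank_sum_test(c(1, 2), c(3, 4))
```

## Randomization and files

`randomize_arm()` assigns the race-matched/mismatched video arms in seeded
permuted blocks (default size 4; complete blocks are balanced 1:1, and
`block_size = 0` gives simple randomization — the published 33/30 split is
compatible with either).  The mismatched arm flips race and preserves
gender when selecting one of the 12 exemplar clips
(`select_exemplar()`); the study specifies the race flip explicitly, and
preserving gender in the mismatched arm is this package's reading of the
design.  Cohort results round-trip through a flat CSV (utilities stored
to 0.1, chained raw fractions to 4 decimals), session transcripts stream
as JSON lines, and calibrations serialize to JSON.  A command-line
interface (`hua_cli()`, wrapper script in `inst/scripts/hua`) exposes
`simulate`, `analyze`, `power` and an interactive plain-text `elicit`.

## Problem sizes and reproducibility

Every random quantity is a pure function of an explicit integer seed;
cohort generation, study simulation, randomization and noisy response
streams are all bit-reproducible.  The calibration round-trip checks use
500 replicate cohorts of 63 noise-free respondents through the SG engine
(about 95,000 adaptive sessions), the threshold-recovery property sweeps
the exhaustive 0.005-spaced grid for SG and TTO, and the power routine is
checked against a 10,000-replicate simulation at its returned n — sizes
chosen so the Monte-Carlo error is a small fraction of each tolerance.

## Known limitations

* Utilities are clamped to $[0, 100]$: states worse than dead are not
  representable, matching a design whose scales bottom out at Dead.
* The respondent model is a threshold responder with additive bias;
  probability weighting, anchoring and fatigue are out of scope.
* The generator matches published marginals, not joint structure;
  arm/race differences beyond the configured effects are null by
  construction.  The shared-rank coupling in particular imposes *perfect*
  rank dependence across states, so simulated within-patient ranking
  proportions are far more concordant than a real cohort's (nearly every
  simulated patient orders the states the same way); analyses of ranking
  proportions on simulated cohorts characterize the generator, not
  patients.
* TTO precision is bounded by the whole-month grid at short horizons.
* The platform's real question schedule is not public; the ping-pong
  ladder and 0.005 resolution are conventions, exposed in
  `titration_config()`.
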