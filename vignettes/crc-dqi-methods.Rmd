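---
title: "Scoring and evaluating colorectal cancer screening decision quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and evaluating colorectal cancer screening decision quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Colorectal cancer screening is a preference-sensitive decision: guidelines
recommend that adults aged 50 and older be screened, but several tests are
reasonable (colonoscopy every 10 years, annual stool blood testing, and
others), and the right choice depends on what the patient cares about —
detection certainty, invasiveness, cost, frequency. A *high-quality*
decision in this setting has two components: the patient understands the
key facts, and the test they receive is the one their own goals point to.
`crcdqi` implements the scoring rules and the evaluation protocol of a
survey instrument built around that definition, together with a
synthetic-cohort generator so every estimator in the package can be
validated by parameter recovery with no access to patient data.

```{r setup}
library(crcdqi)
bank <- default_item_bank()
bank
```

## The instrument

The item bank defines the instrument: ten multiple-choice knowledge items
with keyed correct answers (start age, lifetime incidence and mortality,
test frequencies, complication rates, sensitivity, interpretation of
normal/abnormal results), and eight goals and concerns rated on an
importance scale from 0 ("not at all important") to 10 ("extremely
important"). Respondents also name the three goals most important to
their decision, and report who made the screening decision and how
involved they were. Knowledge responses are stored as option *labels*,
never positions, so reordering options in a questionnaire revision cannot
silently change scoring. The bank ships as a YAML file
(`system.file("extdata", "crc_dqi_bank.yaml", package = "crcdqi")`) and
round-trips losslessly through `write_item_bank()`/`load_item_bank()`.

Two bank fields are conventions rather than published facts, and are
flagged as such wherever they surface. The five-item brief subset was
evaluated in the field test but its membership was never published; the
default is the first five items. The preference model uses seven of the
eight retained goals as covariates; the eighth (willingness to take
sedating medication before the test) was retained in the instrument but
not in the published model. Both are configurable.

## The knowledge score

Each correct response scores one point. Missing responses count as
incorrect, and the score is standardized to 0–100% by dividing by the
*full* item count. A respondent who answered fewer than half of the items
receives no score at all; with an odd item count "at least half" is read
strictly, so the five-item brief score requires three answered items.
Undefined scores are excluded from cohort means. These rules make the
cohort mean obey a useful conservation identity: when every respondent
has a defined score, the cohort mean equals 100 times the mean per-item
difficulty (proportion correct), whatever the joint distribution of
correctness across respondents. That identity is what lets published
per-item correct-count tables stand in for respondent-level data when
checking the scoring arithmetic — `cohort_from_item_counts()` builds a
cohort from a count column, and its mean is invariant to how the correct
answers are shuffled across respondents.

Percentages are carried unrounded internally; display rounding uses
round-half-up (`round_half_up()`), the convention of published survey
tables, and only at the reporting layer.

## The goal-concordance score

Whether a test "matches" a patient's goals is operationalized through a
preference model fitted to the respondents who actually chose: a
maximum-likelihood logistic regression of screening group (colonoscopy
vs. some other test) on the raw 0–10 importance ratings of the model
goals, restricted to respondents aged 50+ with a screening history.
Ratings enter unstandardized, so `exp(beta)` is the odds ratio of
colonoscopy per rating point. Respondents who have never been screened
are excluded from the fit but not from the score: they receive a
predicted probability and an implied preference, and count in the
denominator as non-matches, since no test at all cannot match goals that
favor one.

The match rule is deliberately asymmetric at the boundary: a respondent
matches when the predicted probability of colonoscopy exceeds 0.5 and
they had a colonoscopy, or is *at most* 0.5 and they had some other
test. The tie at exactly 0.5 therefore classifies as an other-test
preference, and the package enforces that bit-exactly.

Numerical choices, all surfaced in the fitted object: convergence
tolerance 1e-8 on the deviance with at most 100 iterations; zero-variance
covariates dropped with coefficient 0 (they are collinear with the
intercept — this also covers the degenerate cohort whose ratings are
constant, where the intercept reduces to the log-odds of the base rate);
complete or quasi-complete separation detected (diverging coefficients or
fully saturated fitted probabilities) and reported as an error suggesting
fewer covariates or penalization, never silently penalized. Missing
model-goal ratings are handled complete-case in the fit; at
classification time a single missing rating is imputed with the
fit-subset median, and two or more leave the respondent unclassified and
out of the denominator, with a warning. Imputation can therefore never
drive the fit, while keeping realistic denominators reachable.

## The composite decision-quality indicator

A respondent made a high-quality decision when both conditions hold:
*informed* — unrounded knowledge score at or above a threshold, with the
boundary inclusive and compared before any display rounding — and
*matched*. The threshold is a parameter whose documented default rule is
the mean knowledge score of a designated decision-aid reference cohort
(the arm that saw the full educational material); it is a derived
quantity, not a hard-coded constant, and `dqi_threshold()` accepts an
explicit override. The high-quality rate is bounded above by both the
informed rate and the match rate, and can only fall as the threshold
rises; both properties are tested.

## The psychometric protocol

**Retest reliability.** The instrument's measures are continuous-ish
scores from a single instrument administered twice, so the ICC form is
the two-way random-effects, absolute-agreement, single-measurement
coefficient (ICC(A,1)), with the F-distribution confidence interval of
McGraw & Wong (1996). The form is recorded in every result row. The
decomposition is computed directly from sums of squares, and the test
suite checks it against an independently fitted ANOVA to 1e-9. The
conventional adequacy target of 0.7 is reported alongside every
estimate. Zero between-subject variance makes the coefficient
unidentified; the package reports 0 with a warning rather than NaN.

**Validity contrasts.** Knowledge contrasts (decision-aid vs control,
providers vs patients) use the Welch two-sample t-test — the paper-style
analysis does not specify pooling, and unequal variances are the safe
default. The construct-validity hypothesis (more involved patients make
higher-quality decisions) is a Fisher exact test on the 2×2 table of
high-quality status by doctor-made decision; the test suite validates
`fisher.test` p-values against full hypergeometric enumeration on small
tables.

**Feasibility and mode effects.** Missingness is summarized as the mean
per-respondent fraction of missing items per scale, overall and by
administration mode; with exactly two modes each scale is compared by a
Welch t-test on the respondent-level fractions (the original analysis
does not name its test; this choice respects the respondent as the unit).

**Item retention.** The screen reproduces the retention review as
deterministic flags: knowledge items with difficulty above 0.85 are
too easy; goals with more than 50% of responses at the scale maximum
show a ceiling effect, but are retained when frequently named top-three
(high stated importance arbitrates in their favor, as it did in the
field test); goals named top-three by fewer than 10% are drop
candidates; item pairs correlated beyond |r| = 0.8 are redundant. All
four thresholds are arguments. Flags are recommendations — deletion is a
user action.

## The synthetic-cohort generator

`cohort_spec()`/`generate_cohort()` draw cohorts with the statistical
structure the analyses assume, so that every downstream statistic has a
known truth: knowledge responses independent per item at specified
per-item correctness probabilities (presets carry the field-test
difficulty columns for the decision-aid, control, provider and clinic
samples); goal ratings from a discretized truncated normal plus a point
mass at 10, calibrated so the three ceiling-prone goals sit at roughly
56–64% maximum ratings while the sedation goal is named top-three by
only a few percent; screening history generated from the true preference
model. Respondents name their three highest-rated goals as top-three,
with random tie-breaks.

Two screening-assignment regimes are available. The default draws the
observed test Bernoulli from the true model probability — exactly the
data-generating process the fitted logistic model assumes, which is what
makes coefficient recovery meaningful (the suite checks recovery of odds
ratios 1.83 and 0.70 within 10% at n = 2000, unbiasedness within 5% and
Wald-interval coverage within [90%, 99%] over 100 cohorts of n = 500).
Setting `decision_noise` instead thresholds the true probability at 0.5
and flips the implied choice with the given probability; with noise 0
and no never-screened respondents, concordance under the generating
model is exactly 100% — and the *fitted* model on such a cohort
correctly refuses with a separation error, since a deterministic rule
perfectly separates the outcome. The default generating coefficients are
the published per-point odds ratios; the intercept (−0.5) was chosen
once to give roughly a 60:40 colonoscopy:other split among screened
respondents and a colonoscopy-leaning implied preference among the never
screened, matching the field-test pattern.

Randomness is organized as one base seed with fixed per-stage substreams
(demographics, goals, screening, knowledge, top-three, involvement,
missingness, retest), so toggling missingness cannot perturb earlier
draws; identical specs produce byte-identical cohorts.

`generate_retest()` produces the second administration with occasion
noise calibrated to a target population ICC per measure: for target
`rho`, the retest value is `mu + rho*(x - mu) + sqrt(1 - rho^2)*sigma*z`
(cohort mean `mu`, SD `sigma`), which preserves the marginal and sets
the test–retest correlation to `rho`, then is discretized back to the
measure's scale — item patterns for the knowledge score (keeping
test-correct items correct first), integers 0–10 for goals. A target of
1 reproduces the test administration exactly. Discretization makes the
calibration approximate: rounding attenuates mildly, and for wide rating
distributions with low targets the bounded scale's clipping can push the
realized coefficient *above* the target. Recovery is therefore asserted
at the documented targets where the construction is accurate — 0, 0.67
(knowledge score, mean estimate within ±0.05 at n = 1000) and 0.87 (the
narrow-scale early-detection goal) — and the per-goal defaults for wide,
low-reliability goals should be read as qualitative.

What the generator does *not* emulate, and what passing tests therefore
do not establish about real data: knowledge items are independent given
the arm (real items share method variance and content clusters); goals
are mutually independent (real goal ratings correlate, and the published
mean-importance plots suggest structure the generator does not place);
missingness is completely at random; demographics do not confound
knowledge. Parameter-recovery results validate the estimators, not the
instrument.

## Problem sizes and runtime

The shipped tests run the simulations at the field-test sizes (cohorts
of 94–175, retest pairs around 71–163) and use 100–200 replicates for
distributional claims, 1000–2000 respondents for single-fit recovery
claims; the whole suite completes in well under a minute on one CPU, and
`scripts/acceptance.R` in a few seconds.

## Known limitations

The instrument content is fixed at the field-test item set; the package
scores and evaluates it but does not calibrate new items. The preference
model is binary (colonoscopy vs any other test) and silent on the choice
among non-colonoscopy tests. The concordance score treats never-screened
respondents as non-matches by definition, a conservative convention that
penalizes informed refusal. Published denominators in this literature
are occasionally internally inconsistent (150 vs 151 eligible
respondents, 52 vs 53 never screened); the package sidesteps the
ambiguity by always reporting the exact denominators it used in every
result object and report.
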