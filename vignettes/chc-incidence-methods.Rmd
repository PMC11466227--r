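---
title: "Methods: cumulative incidence of childhood chronic conditions from linked records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative incidence of childhood chronic conditions from linked records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chcincidence)
```

## The estimation problem

Administrative hospital data record every inpatient episode in a country but
have no reliable denominator: children emigrate without telling the hospital
system, immigrate without a recorded birth, and sometimes fail to link
between their birth record and later activity. This package implements two
complementary designs for estimating the cumulative incidence of a first
hospital-recorded chronic health condition (CHC) from birth to age 16 under
those conditions, together with the machinery to ascertain CHCs from ICD-10
codes, and a synthetic-data generator that makes all of it testable against
analytic ground truth.

## Phenotype ascertainment

CHCs are defined by a code list: one row per ICD-10 code, grouped into nine
body-system subtypes (cancer/blood; cardiovascular; respiratory;
neurological; mental health/behavioural; metabolic and other — spanning
metabolic, endocrine, digestive, renal and genitourinary conditions;
musculoskeletal/skin; chronic infections; non-specific). Codes are
normalised to upper case with dots stripped and at most four characters.

Matching semantics were a genuinely open design choice, since phenotype
lists mix 3- and 4-character codes. We adopted the standard phenotype-list
convention: a record code matches a list entry exactly, or matches a
3-character list entry by prefix (so `A123` in a record hits a whole-category
entry `A12`); a 3-character record code never matches a 4-character-only
entry, because the data do not support the extra specificity. When both an
exact 4-character entry and a 3-character prefix entry match, the more
specific entry's subtype wins. The reader accepts single codes only, not
code ranges; ranges must be expanded upstream.

Every diagnosis position (up to the 20 allowed per episode) is treated
identically — a table with more than 20 diagnosis columns is rejected as a
contract violation rather than silently truncated. The first matching
episode per child and subtype, including the birth episode at day 0, is the
incident event. Ascertainment is order-invariant and insensitive to
non-matching codes by construction, and both properties are tested.

## Closed birth cohorts

Children with a hospital-recorded live birth enter at birth and are followed
until the earliest of: first CHC record (event), death, first episode with
non-England domicile, the 16th birthday, or the administrative end of the
data (default 31 August 2019). Cohorts are academic years of birth
(1 September–31 August). The estimator is one minus the product-limit
survival function; at each distinct event time events are evaluated before
same-time censorings are removed from the risk set. Greenwood standard
errors and normal-approximation intervals are computed but are reporting
extras, not part of any headline estimate.

Two boundary conventions needed fixing:

* **Same-day ties.** An event on the same day as death, emigration or the
  administrative end counts as an event — otherwise birth-episode CHCs at
  time 0 could never be counted. The 16th birthday is the exception: the
  follow-up window is [0, 16th birthday), so an event on the birthday itself
  is out of window. Tests pin both sides of this boundary.
* **Age arithmetic.** Time is integer days from birth; an age in years maps
  to `floor(years * 365.25)` days, and completed age is `floor(days /
  365.25)`. This makes all cutoffs reproducible integer comparisons.

Records dated after a child's death are rejected at assembly with an error
naming the children involved: they are impossible by construction, and
surfacing the contradiction beats silently repairing it.

The competing-risk variant is an in-repo Aalen–Johansen estimator (increment
`S(t-) d1/n` with `S` the all-cause survival). Both estimators are written
in the package rather than delegated, so that the test suite can compare
them against independent oracles — an exhaustive risk-set enumeration over
all small datasets, and `survival::survfit` (including its multi-state
form) as an external cross-check. With no deaths the two estimators
coincide; the suite asserts identity to 1e-10, which is what accumulated
floating-point products over thousands of event times support.

### Eligibility variants

Eight inclusion definitions are implemented: the main analysis (birth record
plus any later hospital activity before 16 *or* a school-record link) and
seven sensitivity variants ranging from "birth record only" to "birth record
plus activity before 5 plus activity 5–<16 plus school link". The variants
are logically nested where the definitions imply it, and the suite verifies
the nesting exhaustively on a truth table and on synthetic data. The
interesting scientific property — tested on a fixed-seed scenario with
unrecorded emigration and activity-correlated inclusion — is directional:
the loosest variant is biased low (emigrants stay in its denominator) and
stricter variants rise (they require contact, which both trims emigrants and
selects sicker children).

## Open cohorts

The open design replaces the birth-cohort denominator with an external
mid-year population series per financial-year birth cohort (1 April–31
March), used as printed without person-year adjustment. The per-age hazard
is the incident case count over the population discounted by the cumulative
number of prior cases, and the cumulative incidence is `1 - exp(-IH)` with
`IH` the integrated hazard.

The discount's boundary was underdetermined: we exclude cases incident *at*
the current age from the discount (a child becoming a case mid-year
contributed risk time during that year); the alternative — subtracting
through the current age — is available behind `discount = "inclusive"`. A
discounted denominator that reaches zero or goes negative is an error naming
the age, not a clamped value: it signals incompatible inputs. The estimator
is scale-invariant (cases and populations multiplied by a common factor
leave the curve unchanged) and agrees with the crude ratio `sum(cases/pop)`
to second order when hazards are small; both properties are tested, the
latter at the 5e-5 bound implied by the exponential expansion.

## Multimorbidity

Multimorbidity is the number of *distinct* body-system subtypes with a first
record strictly before a landmark birthday (5, 11, 16), summarised as the
proportion with more than one among children with at least one. The
denominator is restricted to the main-analysis eligible population. Repeat
records within a subtype are invisible — a documented limitation of
body-system counting, not something the package tries to repair. Chronic
infections count toward multimorbidity by default even where their incidence
curve is too sparse to report (the reporting exclusion is presentational);
`include_unreported = FALSE` flips this.

## The synthetic generator

`sim_chc_data()` draws, per child, independent competing exponential clocks
on yearly age bands 0–15: one per body-system subtype, one for death, one
for emigration. Because independent exponential clocks superpose, the
ground-truth cumulative incidence of any subtype (treating death and
emigration as censoring) is exactly `1 - exp(-cumulative hazard)`, which
`truth_curve()` returns — this is what makes parameter-recovery tests sharp.
Event times are uniform in days within their band.

What it emulates, beyond event times:

* **Record structure**: a birth episode at day 0 for every born child;
  CHC episodes carrying a subtype's ICD-10 code; background (non-CHC)
  admissions at a Poisson rate; outpatient and emergency contacts; annual
  school enrolments from age 4; death records.
* **Emigration**: all records cease at the emigration day; with probability
  `domicile_record_p` one final episode carries non-England domicile
  (otherwise the departure is invisible — the central bias the closed-cohort
  sensitivity analyses probe).
* **Immigration**: children with no birth record who accrue risk only from
  their arrival age (conditions acquired before arrival are invisible,
  mimicking left truncation in real data).
* **Linkage failure**: with probability `linkage_failure_p` a born child's
  post-birth records are all dropped, leaving a birth-only child.
* **Selection**: `chc_activity_multiplier` scales all activity rates for
  children with a CHC, switching on the "sicker children are more likely to
  be included" mechanism.
* **Staggered data availability**: optionally, outpatient activity exists
  only from April 2004 and emergency activity from April 2007.

Defaults were chosen once as plausible study conditions and are not tuning
knobs: subtype hazards giving an any-CHC cumulative hazard of about 0.32 by
16 (cumulative incidence ≈ 27%, the order of magnitude the closed-cohort
sensitivity range spans), infancy-heavy profiles for congenital-dominated
subtypes, a mental-health hazard concentrated at school ages, infant
mortality of 4 per 1000 falling to 0.2 per 1000 per year, emigration 5 per
1000 per year, 5% linkage failure, 97% school-enrolment coverage, and a
background admission rate of 0.10 per person-year. No quantitative
migration or linkage-error rates are published for the real data, so these
are demonstration values, and the scenario-specific configurations used in
tests (e.g. heavy mortality, forced emigration) override them explicitly.

What it does **not** emulate: realistic ICD-10 code frequencies, correlation
between subtypes (multimorbidity arises from independent hazards only, so
observed multimorbidity proportions are a lower bound on what correlated
conditions would produce), seasonality, geography below country level, and
duplicate or contradictory records. Passing tests therefore demonstrate
estimator correctness under the assumed data-generating structure, not
robustness to every pathology of real administrative data.

## Problem sizes and tolerances

Parameter-recovery checks use cohorts of 50 000 children with a constant
any-CHC hazard of 0.02/yr (truth `1 - exp(-0.32)` = 27.39% at 16) and assert
recovery within ±1.5 percentage points — roughly seven Monte-Carlo standard
deviations, so failures indicate bias, not noise. The product-limit oracle
comparison enumerates all 3002 multisets of up to eight follow-ups over a
3-point time grid with event/censoring marks, and requires exact agreement.
The multimorbidity closed form is checked within one percentage point at
n = 50 000; directional (ordering) properties use fixed seeds at n = 20 000.
Exact hand-computable fixtures (the open-cohort formula, the published
linkage percentages) are asserted at 1e-9 and exactly, respectively.
Published-table percentages use half-up rounding to one decimal, which
reproduces all thirty printed cells from the printed counts; base R's
round-half-to-even does not.

## Known limitations

Incidence is of the *first recorded* condition: severity, recovery and
within-subtype multiplicity are out of reach. Hospital inpatient data
under-ascertain conditions managed in primary or community care, so all
estimates are lower bounds for community incidence — the package reproduces
the estimators, not a correction for that. The open estimator treats
population denominators as exact, and its uncertainty is not quantified.
Confidence intervals for the closed estimator are Greenwood-based and
pointwise only.
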