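---
title: "Model and methods: diagnostic strategies for postmenopausal bleeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: diagnostic strategies for postmenopausal bleeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmbcea)
```

## The decision problem

About 9% of women presenting with postmenopausal bleeding (PMB) harbour
endometrial cancer (EC). The usual work-up triages bleeding women with
transvaginal ultrasound (TVU) at a 4 mm endometrial-thickness cut-off and
follows a positive scan with a pipelle aspiration biopsy, falling back on
hysteroscopy when the pipelle fails at insertion or yields too little
tissue. `pmbcea` models this pathway against an augmented pathway that adds
molecular testing on minimally invasive samples: a cervicovaginal Pap-brush
test when the TVU is negative or pipelle insertion fails, and a molecular
test on the endometrial sample when morphology is negative or the sample is
insufficient. The package quantifies what the added detection buys — and
costs — over a cohort's remaining lifetime.

Three layers make up the model, mirroring the package's modules:

1. **Decision trees** (`build_current_strategy()`, `build_molecular_strategy()`)
   turn each diagnostic algorithm into per-episode quantities: the
   probability that one work-up ends in hysterectomy given the woman's true
   disease status, and the expected work-up cost.
2. **A Markov cohort engine** (`build_transition_model()`, `run_cohort()`)
   propagates a closed cohort of 50-year-old PMB women through annual
   cycles to age 85.
3. **Economic accounting and sensitivity analysis** (`accumulate_outcomes()`,
   `icer()`, `one_way_dsa()`, `psa()` and friends) convert traces into
   discounted QALYs, costs and incremental comparisons.

## Work-up trees

Each tree node is either a diagnostic test with a sensitivity/specificity
operating point, a disease-independent success split (pipelle insertion,
probability 0.92; tissue adequacy, 0.87), or a terminal action
(hysterectomy / no action). Evaluation enumerates every root-to-leaf path:
branch probabilities use the sensitivity when the woman truly has EC and
the specificity complement when she does not. Successive tests are treated
as conditionally independent given disease status — the standard
decision-tree assumption; no correlation data exist for these test pairs.
Endometrial thickness enters only through the printed TVU operating point
(sensitivity 0.906, specificity 0.235 at 4 mm); it is not modelled as a
continuous variable.

Two readings of the molecular algorithm are possible where a molecular
test is positive: direct hysterectomy, or hysteroscopy confirmation first.
The package defaults to the conservative confirmation variant — it keeps
the existing diagnostic steps in place and is the reading under which the
molecular arm performs *fewer* false-positive hysterectomies, which is the
qualitative behaviour the augmented pathway is designed for. Because trees
serialise to YAML (`write_tree()`/`read_tree()`), the direct-to-surgery
variant can be explored without code changes.

Cost attachment: the initial gynaecological visit and the TVU tariff are
charged once per episode at the root; every other node charges its
procedure tariff when it executes (the Pap-brush node charges the smear
collection plus the molecular test). Successive-visit and telephone-visit
tariffs are carried as parameters but attached to no node by default; with
annual re-presentation the work-up already recurs every cycle, and the
printed per-episode cost decomposition leaves no unambiguous place for
them. They can be added to any node via the YAML tree definitions.

## Cohort model

Sixteen implementation substates partition six conceptual health states:
the PMB state splits into bleeding women and women after a benign
(false-positive) hysterectomy — the latter can no longer develop EC and
exit the bleeding loop — and undetected EC, detected EC and EC-survivor
states are expanded by FIGO stage I–IV. Death from EC and death from other
causes are absorbing.

Within each annual cycle five events apply in a documented order, each a
stochastic matrix so cohort mass is conserved exactly:

1. death from other causes (0.017/year from every alive state),
2. EC death in undetected, detected and survivor states, at the
   constant-hazard annualisation of stage-specific 5-year survival,
   `1 - s5^(1/5)` (`annual_prob_from_5yr_survival()`),
3. stage progression of undetected disease (I→II 0.30, II→III 0.40,
   III→IV 0.55 per year),
4. new EC incidence among bleeding non-EC women,
5. the bleeding episode and its work-up: every eligible woman bleeds with
   probability 1 in the entry cycle and 0.80 thereafter (non-recurring
   women skip that cycle only); the episode triggers the strategy's
   work-up, moving undetected cases to detected EC and false positives to
   the post-benign-hysterectomy state. Detected women spend exactly one
   cycle in detected EC, then become survivors; survivors relapse to
   detected EC at the annualised recurrence rate (see below).

The order is a modelling choice the data do not pin down; it is exposed as
the `cycle_order` setting and covered by tests. It matters quantitatively:
with deaths first, a share of prevalent cancers dies before any work-up in
the entry cycle, which caps how much any detection improvement can reduce
never-detected cancers.

**Incidence and obesity.** The population incidence (53.5 per 100,000
women-years) is partitioned across obesity strata so the weighted average
reproduces the population rate with an obese:non-obese hazard ratio of 3
at obesity prevalence 0.213: `r_nonobese = r_pop / (1 + p_ob (HR - 1))`,
`r_obese = HR * r_nonobese`. Since strata differ only in incidence and
never mix, the engine runs them separately and weights the traces. New
cases take the prevalent FIGO stage split (0.705/0.062/0.149/0.084) — a
stand-in for an incident-stage distribution the inputs do not provide.
The prevalence of bleeding among EC cases (0.91) is carried in the
parameter set but does not enter the default incidence construction.

**Recurrence.** The published stage-specific recurrence risks (0.065 to
0.667) are implausibly large as annual probabilities at the upper stages;
they are read as cumulative risks over the five-year survivor horizon and
annualised as `1 - (1 - R)^(1/5)`, the same exponential convention used
for survival. The literal-annual reading is available via
`recurrence_rate_mode = "annual"`. Recurrent survivors re-enter detected
EC at their original stage (no re-staging rule is available).

**Age dependence.** All inputs are cycle-constant by default (the printed
overall values). Any scalar parameter can be made age-dependent through an
`age_tables` config entry (attained age = 50 + cycle); exact reproduction
of analyses built on age-specific curves requires those curves.

## Economic accounting

QALYs weight each cycle's occupancy by state utilities: bleeding 0.95,
undetected EC 0.68, detected EC 0.68/0.56/0.56/0.48 and survivors
0.88/0.72/0.72/0.62 by stage, death 0. The benign-hysterectomy decrement
(utility 0.70) is *temporary* by default: applied for the surgery cycle,
with 0.95 thereafter; the permanent reading is a config switch
(`benign_hyst_utility_mode`). Costs per cycle combine work-up costs for
every bleeding episode (priced by true disease status), treatment on
detection (stage I: the 5,367 EUR hysterectomy tariff; stages II–IV:
10,607 EUR plus 4,326 EUR adjuvant treatment), the stage-I tariff for
benign hysterectomies (no dedicated benign tariff is printed; simple
hysterectomy is the shared procedure), and adjuvant-level re-treatment for
survivor recurrences (a second hysterectomy is anatomically impossible;
`recurrence_cost_mode = "full"` charges the full tariff instead).
Undetected EC accrues no treatment cost. Everything is discounted at 3%
per year with cycle 0 undiscounted; accrual is at cycle start with no
half-cycle correction by default (`half_cycle_correction` enables the
averaged-occupancy variant for exploration). The perspective is the
national healthcare system: no productivity or travel costs.

The ICER is `delta cost / delta QALY` (molecular minus usual care),
classified against the 22,000–25,000 EUR/QALY willingness-to-pay band;
the upper bound decides below/above when the comparator sits off the
dominance quadrants.

## Sensitivity analysis

One-way analysis re-solves the full model at each parameter's range
bounds. Ranges marked as assumed are base ± 5% (capped at 1 for
probabilities); the rest are published ranges. For probabilistic analysis
each parameter's distribution is moment-matched to mean = base and
sd = (high − low)/3.92, treating the range as a 95% interval — the
divisor is an assumption and is overridable per draw via the `sd`
argument. Probabilities and utilities draw from beta distributions, costs
and positive ratios from gamma; draws are independent, and the FIGO stage
split is renormalised after drawing so it remains a distribution. With a
zero sd the draw degenerates to the base value, which is what makes the
zero-variance PSA reproduce the deterministic base case exactly — a
property the tests enforce.

The multivariate analysis jointly redraws the most influential inputs
(TVU sensitivity, hysteroscopy specificity, and the stage I EC, stage IV
EC and bleeding utilities) with sd equal to a stated fraction of each
base value. One numerical guard applies: a beta with mean 0.992
(hysteroscopy specificity) cannot have sd 0.992/6 — the requested variance
exceeds `m(1-m)` — so deviations are capped at 95% of the feasible bound
for beta draws. Cost-effectiveness of a draw means positive incremental
net monetary benefit at 25,000 EUR/QALY unless another willingness-to-pay
is given; dominant draws count as cost-effective.

The test-cost sweep reruns the PSA across a grid of molecular test unit
costs with the same seed at every grid point, so the cost-effective
fraction is non-increasing in the unit cost draw-by-draw, not just in
expectation.

## Synthetic scenarios and what the tests show

`degenerate_scenarios()` ships fixtures whose outcomes are closed-form:
perfect tests (every cancer detected at entry), zero prevalence/incidence
(EC states never occupied), an immortal cohort, a free molecular test, and
undiscounted accounting. `random_parameter_set()` generates internally
consistent random inputs (probabilities within ranges or near-\[0,1\],
costs log-uniform in 0.5–2 × base, stage split renormalised) for
property-based tests; its RNG stream is isolated from analysis seeds.
`run_microsimulation()` re-implements the cohort dynamics by sampling
individual transitions and is used as an independent oracle for the
deterministic engine (agreement within binomial error at n = 200,000).
These scenarios exercise the model's internal consistency; they do not
emulate individual patient records, test-result correlation, open-cohort
entry, or non-bleeding EC presentation, so passing tests bound coding
error, not parameter realism.

## Problem sizes and reproducibility

Deterministic analyses use the full 35-cycle horizon. Probabilistic
results in the package's reproduction script use 1000 Monte-Carlo draws,
the conventional size for this model class; unit tests use smaller draw
counts since they check invariances, not precision. All stochastic entry
points take explicit integer seeds and preserve the caller's RNG state.

## Known limitations

* With all inputs at their defaults the molecular strategy detects more
  cancers earlier (undetected cases fall, cancer hysterectomies rise
  slightly) but *increases* discounted lifetime cost: at 310 EUR per test,
  repeated annual testing of the large TVU-negative, cancer-free majority
  outweighs the savings from avoided false-positive surgery and late-stage
  treatment. The cost sweep shows the strategy only becomes cost-saving
  when the unit cost falls roughly to the 10–15 EUR range. Published
  analyses of this pathway that rest on age-specific input curves and
  additional structural detail unavailable here reach more favourable
  conclusions; reproducing them exactly requires those inputs.
* Undetected EC carries the same stage-specific mortality as detected EC;
  no untreated-mortality table is available.
* The memoryless cohort cannot carry individual history (e.g. number of
  prior negative work-ups); an individual-based model would be needed for
  strategies that depend on it.
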