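---
title: "Methods: a 3-state Markov cohort model for proton versus photon radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3-state Markov cohort model for proton versus photon radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtcea)
```

## The decision problem

Radiotherapy is the mainstay of treatment for paranasal sinus and nasal
cavity cancer, and intensity-modulated proton therapy (IMPT) improves
tumour control over intensity-modulated photon therapy (IMRT) at a much
higher up-front cost. `pbtcea` implements the standard decision-analytic
machinery for that trade-off: a decision tree that settles, per arm, the
probability that treatment eradicates the tumour, followed by a 3-state
Markov cohort (*no cancer*, *alive with cancer*, *death*) evolved over
annual cycles, with costs and quality-adjusted life years (QALYs)
discounted and compared through the incremental cost-effectiveness ratio
(ICER) against a willingness-to-pay (WTP) threshold.

The model's two arms are identical in every respect except the
eradication probability and the radiotherapy cost; in particular,
treatment toxicities are assumed equal between arms and are not
modelled. Consequences of that assumption are discussed under
*Limitations*.

## States, transitions and timing conventions

Let $q(a)$ be the annual probability of background (non-cancer) death at
attained age $a$ from a period life table, $r(t)$ the annual relapse
probability in year $t$ after radiotherapy, and $d$ the annual
probability of cancer death from the *alive with cancer* state. The
cycle-$t$ transition matrix is

* from *no cancer*: death $q$, relapse $r(t)\,(1-q)$, stay
  $(1-r(t))\,(1-q)$;
* from *alive with cancer*: death $1-(1-d)(1-q)$, stay $(1-d)(1-q)$;
* *death* is absorbing.

Background and disease-specific risks are combined multiplicatively
(independent competing risks), with background death taking precedence
in the split of the no-cancer row. This is the conventional choice when
a source publication is silent on the combination rule; any alternative
(e.g. additive hazards) differs only at second order in the small
probabilities involved.

Timing follows the common cohort-software default:

* cycle 0 places the cohort at $(p_{\text{eradicate}},
  1-p_{\text{eradicate}}, 0)$ and charges the one-time radiotherapy and
  chemotherapy costs, undiscounted;
* each cycle $t \ge 1$ applies the transition matrix and then accrues
  state rewards *at cycle end*, discounted by $(1+\rho)^{-t}$;
* no half-cycle correction is applied (a flag for a corrected variant is
  deliberately left out of this version rather than half-supported).

Age during cycle $t$ is `start_age + t - 1`; life-table lookups clamp
to the last tabulated age, and any age of 120 or more is treated as
certain death. A start age at or beyond the life-expectancy endpoint
forces a single cycle with a warning rather than an empty model.

## Parameters

All defaults are the published base case; `base_case_spec()` returns
them assembled.

| Parameter | Default | Units | Role |
|---|---|---|---|
| p_eradicate (IMPT / IMRT) | 0.90 / 0.73 | probability | initial-state split |
| c_radiotherapy (IMPT / IMRT) | 50,000 / 12,000 | US$ once | cycle-0 cost |
| c_chemo | 5,000 | US$ once | cycle-0 cost, both arms |
| r(t) | 0.1 (y 1–3), 0.05 (y 4–5), 0.01 (y 6–10), 0 after | probability/yr | relapse |
| d (p_cancer_death) | 0.3 | probability/yr | cancer mortality |
| u_no_cancer / u_with_cancer | 0.94 / 0.47 | utility | QALY weights from year 2 |
| u_first_year | 0.47 | utility | both alive states, year 1 |
| c_followup / c_palliative | 1,000 / 5,000 | US$/yr | state costs |
| discount_rate | 0.03 | per year | costs and QALYs |
| start_age / horizon | 47 / 30 | years / cycles | run settings |
| WTP λ | 30,828 | US$/QALY | decision threshold |

Two conventions deserve emphasis because they are easy to get wrong:

* the first-year utility 0.47 applies to **both** alive states (the
  first post-radiotherapy year carries the treatment disutility); from
  year 2 utilities are state-specific. The package therefore treats
  `u_first_year` as tied to `u_with_cancer` when parameters are varied
  in sensitivity analyses.
* the relapse schedule follows the narrative form "0.1 for the 1st to
  3rd year"; the tabulated variant that starts the 0.1 interval at year
  2 (and duplicates an interval label) is internally inconsistent and
  not used.
* the chemotherapy cost is charged identically in both arms at cycle 0,
  so it cancels exactly in the incremental cost.

## Background mortality

Background mortality enters only through a `life_table` object (age,
annual death probability). Two sources ship with the package:

* `us_life_table_2016()` — the vendored default, a **synthetic smoothed
  reconstruction** of the sex-combined 2016 US period table built by
  log-linear interpolation through anchor values (the file is labelled
  synthetic; it is not a verbatim copy of the published table). The
  sex-combined choice (unweighted mean of male and female rates) is the
  neutral reading when the sex composition of the modelled population is
  unspecified.
* `synth_life_table()` — a Gompertz–Makeham generator,
  $q(a) = 1 - \exp(-(A + B e^{\theta a}))$ with defaults $A = 5\times
  10^{-4}$, $B = 3\times 10^{-5}$, $\theta = 0.09$, chosen once as a
  roughly human-plausible mortality curve so the test-suite never needs
  the vendored file. It supports exact analytic checks (hazard ratios,
  monotonicity) that a tabulated file cannot.

Lookups are integer-age with no interpolation, which is exact for a
1-year cycle length.

## Sensitivity machinery

**Parameter distributions.** Each uncertain parameter is described by
its mean and 90% interval. The half-width is converted to a standard
deviation through the normal quantile ($sd = (\text{high} -
\text{low})/(2 \times 1.645)$); probabilities and utilities get
moment-matched beta distributions, costs get normal distributions
truncated at zero by resampling. Moment matching reproduces the stated
90% intervals to within ±0.01 for every base-case parameter (the worst
case is the strongly skewed no-cancer utility, whose 5th percentile is
biased upward by just under 0.01); matching quantiles instead of moments
would remove that bias at the price of a nonstandard fit, and was not
adopted. A degenerate interval yields a point mass, which makes
deterministic reruns expressible inside the PSA.

**PSA.** `run_psa()` samples all parameters jointly and independently
(no correlation structure is specified by the sources this model format
follows), reruns both arms per draw through a vectorised cohort engine
that is tested to agree with the reference trace to $10^{-12}$, and
reports the fraction of draws with positive incremental net monetary
benefit. 50,000 iterations run in about a second.

**Tornado.** Each parameter in turn is set to its interval endpoints
with the rest at base case; entries are ranked by ICER spread. The
eradication probabilities and the IMPT cost dominate, which is the
expected structure: the arms differ only in those inputs, so everything
else perturbs both arms nearly symmetrically.

**One-way thresholds.** The threshold where ICER $= \lambda$ is found by
bisection on the *net monetary benefit* rather than on the ICER itself:
the two have the same root when $\Delta E > 0$, but NMB is defined and
monotone (indeed linear in every supported parameter) across the whole
search range, so the bisection cannot step into a region where the ICER
is undefined. The parameter is resolved to a relative tolerance of
$10^{-6}$ and the model is re-evaluated at the returned value as a
self-check (`icer_check`), which is asserted to match $\lambda$ to
$10^{-4}$ relative.

**Age stratification.** The starting age is varied with the horizon
always running to the 77-year life-expectancy endpoint; the ICER rises
monotonically with age because the extra eradication buys fewer
remaining life years. `age_threshold()` scans integer ages and returns
the oldest cost-effective one, reported in whole years.

## Patient-level simulation

Two distinct Monte Carlo tools share the transition rules with the
cohort engine:

* `simulate_patients()` is the **oracle**: independent individual
  trajectories whose sample means estimate the cohort totals without
  bias. Draws come from one RNG stream in a documented order (initial
  state for all patients, then one uniform per patient per cycle, with
  the inverse-CDF category order death → relapse → stay; dead patients
  keep consuming draws so the stream layout is outcome-independent).
  Agreement with the deterministic trace within three standard errors at
  $n = 10^6$ is part of the test-suite.
* `mc_strategy_selection()` is the **trials distribution**: each trial
  simulates one patient under each arm with *common random numbers* —
  the same uniform decides eradication in both arms, the same per-year
  uniform drives both transitions — and the trial favors proton therapy
  when its incremental net monetary benefit is positive (ties count as
  not favoring). Under this coupling most trials have identical
  trajectories in both arms and differ only by the ~$38,000 cost gap,
  so only a small share of trials (about one in seven, essentially those
  whose eradication draw falls between the two eradication
  probabilities) favor the dearer arm even though the *expected* ICER is
  below the threshold. This is the quantity a per-trial
  incremental-cost/incremental-effect scatter and strategy-selection
  chart displays, and it must not be confused with the PSA fraction: the
  same base case gives a paired-trials selection fraction near 14% and a
  parameter-PSA acceptability near 78%. The package computes both and
  names them differently on purpose.

## Numerical choices and degenerate inputs

* Occupancy is propagated in closed form; conservation to $10^{-12}$
  and monotone cumulative mortality are asserted, not assumed.
* Discounted totals are plain sums — no Horner-style rearrangement is
  needed at 30–77 terms.
* Bisection tolerances: parameter $10^{-6}$ relative; verification
  $10^{-4}$ relative on the ICER. Both are far below every reporting
  precision used.
* Zero-width relapse schedules, zero-mortality tables, certain
  eradication and zero discounting are all legal inputs and are used by
  the analytic tests (geometric-sum QALYs; expected survival
  $(1-d)/d$ of a with-cancer cohort; age-independence under zero
  mortality).
* Life-table CSVs are written with 17 significant digits so that
  write → read round-trips are bit-exact.

## Problem sizes

The deterministic model is tiny (a 3×3 matrix over ≤ 77 cycles), so the
test-suite runs everything at full published scale: PSA and paired
Monte Carlo at 50,000 iterations, the microsimulation oracle at
$10^6$ patients, sampler-quantile checks at $10^6$ draws; unit tests
use smaller counts (500–50,000) where only structure is being checked.

## Limitations

* The model has no tunnel states: relapse risk depends on time since
  radiotherapy, not time since relapse, and a relapsed patient's
  prognosis does not depend on when relapse occurred.
* Toxicity differences between arms, salvage-treatment pathways and
  terminal-care costs are not modelled; death accrues nothing.
* The with-cancer state mixes residual disease, recurrence and
  metastasis into one utility and one mortality.
* The synthetic-data tools emulate the model's own stochastic structure
  — they validate the implementation, not the model. Real patient-level
  data would show heterogeneity (sex- and comorbidity-dependent
  background mortality, utility drift with age, correlated parameters)
  that neither the generator nor the PSA's independence assumption
  represents, so passing tests demonstrate internal consistency, not
  clinical validity.
* The vendored life table is a smoothed reconstruction; analyses meant
  to inform decisions should substitute an official national table via
  `read_life_table()`.
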